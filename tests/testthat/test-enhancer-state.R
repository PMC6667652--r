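test_that("TSS-proximal peaks are excluded within 2 kb", {
  genes <- gene_at(10000)
  pk <- peaks_tbl(c(10300, 14800, 40000), c(10700, 15200, 41000), c(1, 2, 3))
  kept <- filter_tss_proximal(pk, genes)
  expect_equal(kept$start, c(14800L, 40000L))  # peak at TSS+500 removed
  expect_equal(nrow(filter_tss_proximal(pk, genes[0, ])), 3L)
  # boundary: a peak starting exactly at TSS+2000 survives
  edge <- peaks_tbl(c(12000, 11999), c(12400, 12399), c(1, 1))
  expect_equal(filter_tss_proximal(edge, genes)$start, 12000L)
})

test_that("cross-sample merge keeps the higher-scoring interval at >= 50% of shorter", {
  ctrl <- peaks_tbl(0, 1000, 5)
  kd <- peaks_tbl(200, 1100, 8)
  enh <- merge_enhancers(ctrl, kd)  # overlap 800 >= 0.5 * 900
  expect_equal(nrow(enh), 1L)
  expect_equal(c(enh$start, enh$end), c(200L, 1100L))  # higher score wins
  expect_equal(c(enh$len_ctrl, enh$len_kd), c(1000L, 900L))
  expect_true(enh$on_ctrl && enh$on_kd)

  # below-threshold overlap: both peaks kept as sample-specific enhancers
  kd2 <- peaks_tbl(640, 1640, 8)  # overlap 360 = 36% of shorter (1000)
  enh2 <- merge_enhancers(ctrl, kd2)
  expect_equal(nrow(enh2), 2L)
  expect_equal(sum(enh2$on_ctrl), 1L)
  expect_equal(sum(enh2$on_kd), 1L)

  # boundary: exactly 50% of the shorter peak merges
  kd3 <- peaks_tbl(500, 1500, 8)  # overlap 500 = 0.5 * 1000
  expect_equal(nrow(merge_enhancers(ctrl, kd3)), 1L)
  kd4 <- peaks_tbl(501, 1501, 8)  # overlap 499 just under
  expect_equal(nrow(merge_enhancers(ctrl, kd4)), 2L)

  # a kd-only peak is off in ctrl, on in kd
  only_kd <- merge_enhancers(ctrl[0, ], kd)
  expect_false(only_kd$on_ctrl)
  expect_true(only_kd$on_kd)
  expect_true(is.na(only_kd$len_ctrl))
})

test_that("merge is order-independent and maps every peak to one enhancer", {
  withr::with_seed(17, {
    ctrl <- peaks_tbl(starts <- sort(sample(seq(0, 50000, 50), 30)),
                      starts + sample(300:1200, 30, TRUE),
                      runif(30, 1, 10))
    kd <- peaks_tbl(starts2 <- sort(sample(seq(0, 50000, 50), 30)),
                    starts2 + sample(300:1200, 30, TRUE),
                    runif(30, 1, 10))
    enh <- merge_enhancers(ctrl, kd)
    expect_lte(nrow(enh), nrow(ctrl) + nrow(kd))
    # every input peak maps to exactly one enhancer
    expect_equal(2 * sum(enh$on_ctrl & enh$on_kd) +
                   sum(xor(enh$on_ctrl, enh$on_kd)),
                 nrow(ctrl) + nrow(kd))
    perm_c <- ctrl[sample(nrow(ctrl)), ]
    perm_k <- kd[sample(nrow(kd)), ]
    enh_perm <- merge_enhancers(perm_c, perm_k)
    expect_equal(enh[, -1], enh_perm[, -1])  # ids aside, identical set
  })
})

test_that("enhancer states follow the contain rules over H3K27ac/H3K27me3 segments", {
  lv <- c("a_only", "b_only", "both", "none")
  enh <- tibble::tibble(enhancer_id = "e1", chrom = "chr1",
                        start = 1000L, end = 2000L, score = 5,
                        len_ctrl = 1000L, len_kd = 1000L,
                        on_ctrl = TRUE, on_kd = FALSE)
  seg <- function(st) tibble::tibble(chrom = "chr1", start = 1200L, end = 1600L,
                                     state = factor(st, levels = lv))
  expect_equal(as.character(assign_enhancer_state(enh, seg("a_only"), "ctrl")),
               "active")
  expect_equal(as.character(assign_enhancer_state(enh, seg("b_only"), "ctrl")),
               "poised")
  expect_equal(as.character(assign_enhancer_state(enh, seg("both"), "ctrl")),
               "intermediate")
  two <- dplyr::bind_rows(seg("a_only"),
                          dplyr::mutate(seg("b_only"), start = 1700L, end = 1900L))
  expect_equal(as.character(assign_enhancer_state(enh, two, "ctrl")),
               "intermediate")
  expect_equal(as.character(assign_enhancer_state(enh, seg("none"), "ctrl")),
               "primed")
  # off in the condition dominates everything
  expect_equal(as.character(assign_enhancer_state(enh, seg("a_only"), "kd")),
               "off")
})

test_that("width change uses a strict 1.5-fold threshold in both directions", {
  enh <- tibble::tibble(len_ctrl = c(300L, 300L, 600L, 300L, NA),
                        len_kd = c(500L, 400L, 300L, 450L, 400L))
  wc <- classify_width_change(enh)
  expect_equal(as.character(wc),
               c("broader", "stable", "shorter", "stable", "undefined"))
  # 450 = exactly 1.5 * 300 is NOT over the threshold
  expect_equal(as.character(wc[4]), "stable")
  expect_equal(as.character(classify_width_change(
    tibble::tibble(len_ctrl = 300L, len_kd = 451L))), "broader")
  expect_error(classify_width_change(tibble::tibble(len_ctrl = 0L, len_kd = 10L)),
               "zero")
})

test_that("binding annotation requires any nonzero peak overlap", {
  regions <- tibble::tibble(chrom = "chr1", start = c(1000L, 50000L),
                            end = c(2000L, 51000L))
  peaks <- peaks_tbl(1400, 1600, 1)
  expect_equal(annotate_binding(regions, peaks), c(TRUE, FALSE))
  expect_equal(annotate_binding(regions, peaks[0, ]), c(FALSE, FALSE))
  # abutting peak (half-open) does not bind
  abut <- peaks_tbl(2000, 2400, 1)
  expect_equal(annotate_binding(regions, abut), c(FALSE, FALSE))
})

test_that("target genes come from the nearest TSS within 50 kb", {
  enh <- tibble::tibble(chrom = "chr1", start = 9500L, end = 10500L)
  genes <- dplyr::bind_rows(gene_at(40000, id = "near"), gene_at(70000, id = "far"))
  expect_equal(enhancer_target_gene(enh, genes), "near")
  expect_true(is.na(enhancer_target_gene(enh, genes[2, ])))
  # boundary: exactly 50 kb away still targets
  g50 <- gene_at(60000, id = "edge")
  expect_equal(enhancer_target_gene(enh, g50), "edge")
  g50b <- gene_at(60001, id = "edge")
  expect_true(is.na(enhancer_target_gene(enh, g50b)))
})
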