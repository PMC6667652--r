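test_that("pairing classifies fixed / shift and dissolves far pairs at the 117-bp bound", {
  fixed <- pair_nucleosomes(nucs_at(1000), nucs_at(1000))
  expect_equal(as.character(fixed$category), "fixed")
  expect_equal(fixed$distance, 0L)

  sh <- pair_nucleosomes(nucs_at(1000), nucs_at(1040))
  expect_equal(as.character(sh$category), "shift")
  expect_equal(sh$distance, 40L)

  # d = 116 is still a shift; d = 117 dissolves into loss + gain
  expect_equal(as.character(pair_nucleosomes(nucs_at(1000), nucs_at(1116))$category),
               "shift")
  far <- pair_nucleosomes(nucs_at(1000), nucs_at(1117))
  expect_setequal(as.character(far$category), c("loss", "gain"))
  expect_true(all(far$dissolved))

  # d = 1 is the smallest shift
  expect_equal(as.character(pair_nucleosomes(nucs_at(1000), nucs_at(1001))$category),
               "shift")
})

test_that("unpaired nucleosomes become losses (ctrl) and gains (kd)", {
  res <- pair_nucleosomes(nucs_at(c(1000, 5000)), nucs_at(1000))
  expect_equal(sum(res$category == "fixed"), 1L)
  expect_equal(sum(res$category == "loss"), 1L)
  res2 <- pair_nucleosomes(nucs_at(1000), nucs_at(c(1000, 5000)))
  expect_equal(sum(res2$category == "gain"), 1L)
})

test_that("mutual-nearest pairing matches the quadratic oracle", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      a <- sort(sample(1:50000, sample(50:200, 1)))
      b <- sort(sample(1:50000, sample(50:200, 1)))
      got <- pair_nucleosomes(nucs_at(a), nucs_at(b))
      want <- oracle_pairs(a, b)
      got_pairs <- got[!is.na(got$dyad_ctrl) & !is.na(got$dyad_kd), ]
      # paired rows (incl. dissolved near-pairs) must equal the oracle pairs
      paired_ctrl <- sort(c(got_pairs$dyad_ctrl,
                            got$dyad_ctrl[got$dissolved & got$category == "loss"]))
      expect_equal(paired_ctrl, sort(a[want[, 1]]))
      # partition: every nucleosome appears exactly once
      expect_equal(sort(got$dyad_ctrl[!is.na(got$dyad_ctrl)]), a)
      expect_equal(sort(got$dyad_kd[!is.na(got$dyad_kd)]), b)
      # category tally covers everything
      expect_equal(sum(got$category %in% c("fixed", "shift")) * 2 +
                     sum(got$category %in% c("loss", "gain")),
                   length(a) + length(b))
    }
  })
})

test_that("NFR occupancy uses the 118-bp (80% of 147) overlap rule", {
  gene <- gene_at(10000)
  none <- nucs_at(integer(0))
  # kd nucleosome at TSS-60: footprint fully inside the window -> lost
  lost <- call_nfr_status(gene, none, nucs_at(10000 - 60))
  expect_equal(as.character(lost$status), "lost")
  # kd nucleosome at TSS+40: overlap 83 < 118 -> still open
  open <- call_nfr_status(gene, none, nucs_at(10000 + 40))
  expect_equal(as.character(open$status), "retained")
  # ctrl occupied, kd empty -> NFR forms (gained)
  gained <- call_nfr_status(gene, nucs_at(10000 - 60), none)
  expect_equal(as.character(gained$status), "gained")
  # occupied in both
  both <- call_nfr_status(gene, nucs_at(10000 - 60), nucs_at(10000 - 75))
  expect_equal(as.character(both$status), "absent_both")
  expect_equal(lost$end - lost$start, 250L)
})

test_that("NFR overlap boundary sits exactly at 118 bp", {
  gene <- gene_at(10000)
  none <- nucs_at(integer(0))
  # footprint [d-73, d+74); with window [9800, 10050) a dyad at
  # 10050 - 74 + k overlaps by 74 - k + ... : place analytically
  # overlap = min(10050, d + 74) - max(9800, d - 73)
  d118 <- 9800 + 118 - 74  # overlap = d + 74 - 9800 = 118
  expect_equal(as.character(call_nfr_status(gene, none, nucs_at(d118))$status),
               "lost")
  expect_equal(as.character(call_nfr_status(gene, none, nucs_at(d118 - 1))$status),
               "retained")
})

test_that("NFR windows are strand-aware", {
  gene_minus <- gene_at(10000, "-")
  # minus-strand NFR spans [tss-50, tss+200); nucleosome upstream (+75)
  lost <- call_nfr_status(gene_minus, nucs_at(integer(0)), nucs_at(10075))
  expect_equal(as.character(lost$status), "lost")
  # a nucleosome at -75 sits mostly outside the minus-strand window
  kept <- call_nfr_status(gene_minus, nucs_at(integer(0)), nucs_at(10000 - 75))
  expect_equal(as.character(kept$status), "retained")
})

test_that("occupancy matrix clusters planted row archetypes and is seed-stable", {
  cs <- tibble::tibble(chrom = "chr1", size = 100000L)
  # two archetypes: occupied left flank vs occupied right flank
  regions <- tibble::tibble(chrom = "chr1",
                            start = seq(10000, 90000, by = 2000),
                            end = seq(10000, 90000, by = 2000) + 200L)
  mid <- (regions$start + regions$end) %/% 2L
  left <- seq_len(nrow(regions)) %% 2 == 0
  pos <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    offs <- if (left[i]) -(400:300) else (300:400)
    mid[i] + offs
  }))
  sig <- binned_rpkm(tibble::tibble(chrom = "chr1", pos = as.integer(pos)),
                     cs, bin = 100)
  om <- occupancy_matrix(regions, sig, flank = 500, k = 2, seed = 9)
  expect_equal(length(unique(om$cluster[left])), 1L)
  expect_equal(length(unique(om$cluster[!left])), 1L)
  expect_true(om$cluster[left][1] != om$cluster[!left][1])
  om2 <- occupancy_matrix(regions, sig, flank = 500, k = 2, seed = 9)
  expect_identical(om$cluster, om2$cluster)
  # k = 1 puts everything in one cluster; too few regions errors
  expect_equal(unique(occupancy_matrix(regions, sig, flank = 500, k = 1)$cluster), 1L)
  expect_error(occupancy_matrix(regions[1:3, ], sig, flank = 500, k = 5),
               "fewer regions")
})
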