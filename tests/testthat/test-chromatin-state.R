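test_that("binarization thresholds the Poisson upper tail", {
  cs <- tibble::tibble(chrom = "chr1", size = 2000L)  # 10 bins of 200
  # uniform input: 1 read per bin, so lambda = mark_total/10 per bin
  input <- tibble::tibble(chrom = "chr1", pos = as.integer(seq(100, 1900, 200)))
  # 10 mark reads piled in bin 1, none elsewhere: lambda = 1, obs = 10
  mark <- tibble::tibble(chrom = "chr1", pos = rep(100L, 10))
  tr <- binarize(mark, input, cs, bin = 200, p_threshold = 1e-4)
  expect_true(tr$on[1])            # P(X >= 10 | 1) ~ 1.1e-7
  expect_false(any(tr$on[-1]))     # observed 0 is never on
  # obs = 2 at lambda = 1 is unremarkable (P ~ 0.264)
  mark2 <- tibble::tibble(chrom = "chr1", pos = c(100L, 100L))
  tr2 <- binarize(mark2, input, cs, bin = 200, p_threshold = 1e-4)
  expect_false(tr2$on[1])
  expect_equal(stats::ppois(1, 1, lower.tail = FALSE), 0.2642411, tolerance = 1e-6)
  # empty mark track: all-off with a warning
  expect_warning(
    tr0 <- binarize(mark[0, ], input, cs, bin = 200),
    "no reads")
  expect_false(any(tr0$on))
})

test_that("mark-pair segmentation follows the four-state truth table and merges runs", {
  a <- track_from_bits(c(1, 1, 0))
  b <- track_from_bits(c(0, 1, 0))
  seg <- segment_mark_pair(a, b)
  expect_equal(as.character(seg$state), c("a_only", "both", "none"))
  expect_equal(seg$start, c(0L, 200L, 400L))
  expect_equal(seg$end, c(200L, 400L, 600L))

  allz <- segment_mark_pair(track_from_bits(rep(0, 6)), track_from_bits(rep(0, 6)))
  expect_equal(nrow(allz), 1L)
  expect_equal(as.character(allz$state), "none")

  alt <- segment_mark_pair(track_from_bits(c(1, 0, 1, 0)),
                           track_from_bits(c(0, 0, 0, 0)))
  expect_equal(nrow(alt), 4L)

  expect_error(segment_mark_pair(track_from_bits(c(1, 0)), track_from_bits(c(1, 0, 0))),
               "grid")
})

test_that("segments tile the genome without gaps or overlaps", {
  withr::with_seed(31, {
    a <- track_from_bits(rbinom(50, 1, 0.3))
    b <- track_from_bits(rbinom(50, 1, 0.3))
  })
  seg <- segment_mark_pair(a, b)
  expect_equal(sum(seg$end - seg$start), 50L * 200L)
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  # no two consecutive segments share a state
  expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
})

test_that("promoter state assignment follows the contain rules", {
  gene <- gene_at(10000)  # window [8000, 11000)
  seg1 <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9400L,
                         state = factor("a_only", levels = c("a_only", "b_only", "both", "none")))
  expect_equal(as.character(assign_promoter_state(gene, seg1)$state), "a_only")
  # both single-mark segment types present -> combined state
  seg2 <- dplyr::bind_rows(seg1, dplyr::mutate(seg1, start = 10000L, end = 10200L,
                                               state = factor("b_only", levels = levels(seg1$state))))
  expect_equal(as.character(assign_promoter_state(gene, seg2)$state), "both")
  # a 'both' segment alone is also combined
  seg3 <- dplyr::mutate(seg1, state = factor("both", levels = levels(seg1$state)))
  expect_equal(as.character(assign_promoter_state(gene, seg3)$state), "both")
  # only none segments overlap
  seg4 <- dplyr::mutate(seg1, state = factor("none", levels = levels(seg1$state)))
  expect_equal(as.character(assign_promoter_state(gene, seg4)$state), "none")
  # a segment outside the window does not count
  seg5 <- dplyr::mutate(seg1, start = 20000L, end = 21000L)
  expect_equal(as.character(assign_promoter_state(gene, seg5)$state), "none")
})

test_that("promoter state is invariant to splitting segments", {
  gene <- gene_at(10000)
  lv <- c("a_only", "b_only", "both", "none")
  whole <- tibble::tibble(chrom = "chr1", start = 8000L, end = 9000L,
                          state = factor("a_only", levels = lv))
  halves <- tibble::tibble(chrom = "chr1", start = c(8000L, 8500L),
                           end = c(8500L, 9000L),
                           state = factor("a_only", levels = lv))
  expect_equal(assign_promoter_state(gene, whole)$state,
               assign_promoter_state(gene, halves)$state)
})

test_that("transition tables preserve marginals and detect universe mismatch", {
  lv <- c("a_only", "b_only", "both", "none")
  mk_states <- function(states) {
    tibble::tibble(gene_id = paste0("g", seq_along(states)),
                   state = factor(states, levels = lv))
  }
  sc <- mk_states(c("a_only", "a_only", "b_only", "none"))
  tt_same <- promoter_transition_table(sc, sc)
  expect_equal(sum(tt_same$n), 4L)
  expect_equal(sum(tt_same$n[tt_same$state_ctrl != tt_same$state_kd]), 0L)

  sk <- mk_states(c("b_only", "a_only", "b_only", "both"))
  tt <- promoter_transition_table(sc, sk)
  row_marg <- tt |> dplyr::group_by(state_ctrl) |> dplyr::summarise(n = sum(n))
  expect_equal(row_marg$n, as.vector(table(sc$state)))
  col_marg <- tt |> dplyr::group_by(state_kd) |> dplyr::summarise(n = sum(n))
  expect_equal(col_marg$n, as.vector(table(sk$state)))

  expect_equal(nrow(promoter_transition_table(sc[0, ], sk[0, ])), 16L)
  sk_bad <- sk; sk_bad$gene_id[1] <- "zz"
  expect_error(promoter_transition_table(sc, sk_bad), "universe")
})

test_that("active/non-active collapse follows the configurable mapping", {
  st <- factor(c("a_only", "b_only", "both", "none"),
               levels = c("a_only", "b_only", "both", "none"))
  expect_equal(as.character(collapse_active(st)),
               c("active", "non_active", "active", "non_active"))
  strict <- collapse_active(st, active_states = "a_only")
  expect_equal(as.character(strict),
               c("active", "non_active", "non_active", "non_active"))
})
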