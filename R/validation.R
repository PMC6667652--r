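#' Measure recovery of planted events at the standard study conditions
#'
#' Runs the full simulate -> call -> classify chain on a synthetic genome
#' and scores each stage only against the recorded truth: the fraction of
#' planted promoter NFR losses (and gains) called, the fraction of planted
#' nucleosome shifts classified as shifts, and the fraction of planted
#' promoter and enhancer state switches whose before and after states are
#' both recovered. Defaults are the standard conditions: 20 fragments per
#' nucleosome with 5-bp dyad jitter, and 10x mark enrichment over
#' background.
#'
#' @param seed Master seed for the synthetic world.
#' @param lambda,jitter_sd MNase depth and dyad jitter (bp).
#' @param background_rate,enriched_rate Mark-track depth per 200-bp bin.
#' @return A tibble with one row per planted event class: `event`,
#'   `recovered`, `planted`, `rate`.
#' @export
planted_recovery <- function(seed = 1, lambda = 20, jitter_sd = 5,
                             background_rate = 2, enriched_rate = 20) {
  truth <- simulate_truth(seed = seed)
  frags <- generate_nucleosome_reads(truth, lambda = lambda,
                                     jitter_sd = jitter_sd)
  nucs <- lapply(frags, function(fr) call_nucleosomes(build_dyad_index(fr)))
  nfr <- call_nfr_status(truth$genes, nucs$ctrl, nucs$kd)
  loss_rec <- sum(nfr$gene_id[nfr$status == "lost"] %in% truth$planted_nfr_loss)
  gain_rec <- sum(nfr$gene_id[nfr$status == "gained"] %in% truth$planted_nfr_gain)

  dyn <- pair_nucleosomes(nucs$ctrl, nucs$kd)
  shift_rec <- planted_shift_hits(truth, dyn)

  mk <- generate_mark_tracks(truth, background_rate = background_rate,
                             enriched_rate = enriched_rate)
  seg <- function(mark_a, cond) {
    a <- binarize(mk$tracks[[mark_a]][[cond]], mk$igg[[cond]], truth$chrom_sizes)
    b <- binarize(mk$tracks$H3K27me3[[cond]], mk$igg[[cond]], truth$chrom_sizes)
    segment_mark_pair(a, b)
  }
  ps <- lapply(c(ctrl = "ctrl", kd = "kd"), function(cond) {
    assign_promoter_state(truth$genes, seg("H3K9ac", cond))
  })
  i <- match(truth$planted_promoter_switches, ps$ctrl$gene_id)
  prom_rec <- sum(
    as.character(ps$ctrl$state[i]) == truth$promoters$state_ctrl[i] &
      as.character(ps$kd$state[i]) == truth$promoters$state_kd[i]
  )

  peaks <- lapply(mk$peaks, filter_tss_proximal, genes = truth$genes)
  enh <- merge_enhancers(peaks$ctrl, peaks$kd)
  enh$state_ctrl <- assign_enhancer_state(enh, seg("H3K27ac", "ctrl"), "ctrl")
  enh$state_kd <- assign_enhancer_state(enh, seg("H3K27ac", "kd"), "kd")
  ti <- match_truth_enhancer(truth, enh)
  in_switch <- truth$enhancers$enhancer_id[ti] %in% truth$planted_enhancer_switches
  ok <- as.character(enh$state_ctrl) == truth$enhancers$state_ctrl[ti] &
    as.character(enh$state_kd) == truth$enhancers$state_kd[ti]
  enh_rec <- sum(ok & in_switch, na.rm = TRUE)

  tibble::tibble(
    event = c("nfr_loss", "nfr_gain", "shift", "promoter_switch",
              "enhancer_switch"),
    recovered = c(loss_rec, gain_rec, shift_rec, prom_rec, enh_rec),
    planted = c(length(truth$planted_nfr_loss), length(truth$planted_nfr_gain),
                nrow(truth$planted_shifts),
                length(truth$planted_promoter_switches),
                length(truth$planted_enhancer_switches))
  ) |>
    dplyr::mutate(rate = .data$recovered / .data$planted)
}

# How many planted shifts produced a shift-classified pair at the shifted
# nucleosome (the +3 slot, 550 bp 3' of the TSS) with the planted distance.
planted_shift_hits <- function(truth, dyn) {
  sh <- truth$planted_shifts
  if (nrow(sh) == 0) return(0L)
  g <- truth$genes[match(sh$gene_id, truth$genes$gene_id), ]
  expect_pos <- g$tss + ifelse(g$strand == "+", 550L, -550L)
  shifts <- dyn[dyn$category == "shift" & !is.na(dyn$dyad_ctrl), ]
  hits <- vapply(seq_len(nrow(sh)), function(k) {
    near <- shifts$chrom == g$chrom[k] &
      abs(shifts$dyad_ctrl - expect_pos[k]) <= 30
    any(near & abs(shifts$distance - sh$shift[k]) <= 10)
  }, logical(1))
  sum(hits)
}

# Map merged enhancer records back to truth rows by proximity of midpoints
# (truth enhancers are >= 20 kb apart, so the match is unambiguous).
match_truth_enhancer <- function(truth, enh) {
  mid <- (enh$start + enh$end) %/% 2L
  vapply(seq_len(nrow(enh)), function(k) {
    j <- which(truth$enhancers$chrom == enh$chrom[k] &
                 abs(truth$enhancers$center - mid[k]) < 5000)
    if (length(j) == 1) j else NA_integer_
  }, integer(1))
}
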