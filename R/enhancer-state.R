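#' Remove peaks near transcription start sites
#'
#' Enhancer candidate peaks overlapping any `TSS +/- excl` window are
#' dropped so that enhancers do not overlap promoters.
#'
#' @param peaks Scored peak tibble (`chrom`, `start`, `end`, `score`).
#' @param genes Gene tibble with `chrom` and `tss`.
#' @param excl Exclusion half-width around each TSS (bp).
#' @return The filtered peak tibble.
#' @export
filter_tss_proximal <- function(peaks, genes, excl = 2000) {
  stopifnot(excl >= 0)
  if (nrow(genes) == 0 || nrow(peaks) == 0) return(peaks)
  tss_split <- split(genes$tss, genes$chrom)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    tss <- tss_split[[peaks$chrom[i]]]
    if (is.null(tss)) return(TRUE)
    !any(overlap_width(tss - excl, tss + excl, peaks$start[i], peaks$end[i]) > 0)
  }, logical(1))
  peaks[keep, ]
}

#' Merge H3K4me1 peaks across two samples into an enhancer set
#'
#' Cross-sample peak pairs whose overlap is at least `min_frac` of the
#' shorter peak are unified into a single enhancer keeping the
#' higher-scoring peak's interval, while recording both original peak
#' lengths. Peaks that overlap less than that, or not at all, each become a
#' sample-specific enhancer. An enhancer is "on" in a sample iff that
#' sample contributed a peak; otherwise it is "off" there.
#'
#' Conflicts (a peak overlapping several candidates) are resolved greedily
#' by descending overlap width with coordinate tie-breaks, so the result is
#' independent of input row order.
#'
#' @param peaks_ctrl,peaks_kd TSS-filtered scored peak tibbles.
#' @param min_frac Minimum overlap as a fraction of the shorter peak.
#' @return Enhancer tibble with `enhancer_id`, `chrom`, `start`, `end`,
#'   `score`, `len_ctrl`, `len_kd`, `on_ctrl`, `on_kd`.
#' @export
merge_enhancers <- function(peaks_ctrl, peaks_kd, min_frac = 0.5) {
  pc <- dplyr::arrange(peaks_ctrl, .data$chrom, .data$start, .data$end)
  pk <- dplyr::arrange(peaks_kd, .data$chrom, .data$start, .data$end)
  # all cross-sample overlapping pairs passing the fraction-of-shorter rule
  cand <- dplyr::inner_join(
    dplyr::mutate(pc, i = dplyr::row_number()),
    dplyr::mutate(pk, j = dplyr::row_number()),
    by = "chrom", suffix = c("_c", "_k"), relationship = "many-to-many"
  ) |>
    dplyr::mutate(
      ov = overlap_width(.data$start_c, .data$end_c, .data$start_k, .data$end_k),
      shorter = pmin(.data$end_c - .data$start_c, .data$end_k - .data$start_k)
    ) |>
    dplyr::filter(.data$ov >= min_frac * .data$shorter) |>
    dplyr::arrange(dplyr::desc(.data$ov), .data$start_c, .data$start_k)
  used_c <- logical(nrow(pc))
  used_k <- logical(nrow(pk))
  merged <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_c[i] || used_k[j]) next
    used_c[i] <- TRUE; used_k[j] <- TRUE
    keep_c <- cand$score_c[r] >= cand$score_k[r]
    merged[[length(merged) + 1]] <- tibble::tibble(
      chrom = cand$chrom[r],
      start = if (keep_c) cand$start_c[r] else cand$start_k[r],
      end = if (keep_c) cand$end_c[r] else cand$end_k[r],
      score = max(cand$score_c[r], cand$score_k[r]),
      len_ctrl = cand$end_c[r] - cand$start_c[r],
      len_kd = cand$end_k[r] - cand$start_k[r],
      on_ctrl = TRUE, on_kd = TRUE
    )
  }
  only_c <- pc[!used_c, ]
  only_k <- pk[!used_k, ]
  out <- dplyr::bind_rows(
    dplyr::bind_rows(merged),
    tibble::tibble(chrom = only_c$chrom, start = only_c$start, end = only_c$end,
                   score = only_c$score, len_ctrl = only_c$end - only_c$start,
                   len_kd = NA_integer_, on_ctrl = TRUE, on_kd = FALSE),
    tibble::tibble(chrom = only_k$chrom, start = only_k$start, end = only_k$end,
                   score = only_k$score, len_ctrl = NA_integer_,
                   len_kd = only_k$end - only_k$start,
                   on_ctrl = FALSE, on_kd = TRUE)
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end)
  out$enhancer_id <- sprintf("enh_%05d", seq_len(nrow(out)))
  out[, c("enhancer_id", "chrom", "start", "end", "score",
          "len_ctrl", "len_kd", "on_ctrl", "on_kd")]
}

#' Assign activity states to enhancers in one condition
#'
#' Enhancers that are off (no H3K4me1 peak) in the condition are `off`.
#' On enhancers are classified from the H3K27ac/H3K27me3 mark-pair segments
#' they overlap: `intermediate` when they contain a combined segment or
#' both single-mark segment types; `active` when exclusively H3K27ac-only;
#' `poised` when exclusively H3K27me3-only; `primed` otherwise (H3K4me1
#' only).
#'
#' @param enhancers Enhancer tibble from [merge_enhancers()].
#' @param segments H3K27ac/H3K27me3 segments from [segment_mark_pair()]
#'   for the condition (`a_only` = H3K27ac-only, `b_only` = H3K27me3-only).
#' @param condition `"ctrl"` or `"kd"` — selects the on/off flag.
#' @param min_overlap Minimum overlap (bp) for "contains".
#' @return Factor of states (active/intermediate/poised/primed/off), one
#'   per enhancer.
#' @export
assign_enhancer_state <- function(enhancers, segments,
                                  condition = c("ctrl", "kd"),
                                  min_overlap = 1) {
  condition <- match.arg(condition)
  on <- if (condition == "ctrl") enhancers$on_ctrl else enhancers$on_kd
  pair <- region_pair_state(enhancers, segments, min_overlap)
  state <- dplyr::case_when(
    !on ~ "off",
    pair == "both" ~ "intermediate",
    pair == "a_only" ~ "active",
    pair == "b_only" ~ "poised",
    TRUE ~ "primed"
  )
  factor(state, levels = c("active", "intermediate", "poised", "primed", "off"))
}

#' Classify enhancer width change between conditions
#'
#' Defined only for enhancers with an H3K4me1 peak in both samples:
#' `broader` when the treated peak is over `fold` times wider than the
#' control peak, `shorter` when the control peak is over `fold` times wider
#' than the treated one, `stable` otherwise, and `undefined` when either
#' length is missing.
#'
#' @param enhancers Enhancer tibble with `len_ctrl`, `len_kd`.
#' @param fold Width-change fold threshold (exclusive).
#' @return Factor (broader/shorter/stable/undefined), one per enhancer.
#' @export
classify_width_change <- function(enhancers, fold = 1.5) {
  lc <- enhancers$len_ctrl
  lk <- enhancers$len_kd
  if (any(!is.na(lc) & lc <= 0) || any(!is.na(lk) & lk <= 0)) {
    stop("zero-length peak")
  }
  cls <- dplyr::case_when(
    is.na(lc) | is.na(lk) ~ "undefined",
    lk > fold * lc ~ "broader",
    lc > fold * lk ~ "shorter",
    TRUE ~ "stable"
  )
  factor(cls, levels = c("broader", "shorter", "stable", "undefined"))
}

#' Flag regions containing at least one binding peak
#'
#' A region (promoter or enhancer) is "bound" iff at least one peak from
#' the supplied binding peak set (e.g. MYCN ChIP-seq peaks) overlaps it by
#' any nonzero amount.
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param peaks Binding peak tibble (`chrom`, `start`, `end`).
#' @return Logical vector, one per region.
#' @export
annotate_binding <- function(regions, peaks) {
  if (nrow(peaks) == 0) return(rep(FALSE, nrow(regions)))
  peak_split <- split(peaks, peaks$chrom)
  vapply(seq_len(nrow(regions)), function(i) {
    p <- peak_split[[regions$chrom[i]]]
    if (is.null(p)) return(FALSE)
    any(overlap_width(p$start, p$end, regions$start[i], regions$end[i]) > 0)
  }, logical(1))
}

#' Assign each enhancer its target gene
#'
#' The nearest TSS within `max_dist` of the enhancer midpoint is the
#' enhancer's target gene; a gene may be targeted by several enhancers.
#'
#' @param enhancers Enhancer tibble.
#' @param genes Gene tibble with `gene_id`, `chrom`, `tss`.
#' @param max_dist Maximum midpoint-to-TSS distance (bp).
#' @return Character vector of `gene_id`s (NA when no TSS within range).
#' @export
enhancer_target_gene <- function(enhancers, genes, max_dist = 50000) {
  idx <- nearest_feature(enhancers, genes, anchor = "tss", max_dist = max_dist)
  genes$gene_id[idx]
}
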