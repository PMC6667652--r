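#' Binarize a histone-mark track against an IgG control
#'
#' Divides the genome into fixed-width bins (200 bp by default), counts mark
#' and control read midpoints per bin, and switches a bin on when the
#' observed mark count is improbably high under a Poisson background. The
#' background mean for a bin is the control count scaled by the ratio of
#' library sizes (mark / control); bins with zero control reads fall back to
#' the genome-wide mean mark count per bin. A bin is set to 1 iff
#' `P(X >= observed | lambda) <= p_threshold`.
#'
#' @param mark_midpoints Tibble of mark read midpoints (`chrom`, `pos`, or
#'   intervals whose midpoints are taken).
#' @param input_midpoints Control (IgG) midpoints, same format.
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param bin Bin width in bp.
#' @param p_threshold Upper-tail Poisson probability cutoff.
#' @return Tibble with `chrom`, `start`, `end`, `count`, `on` (logical);
#'   bins tile each chromosome. Empty mark input gives an all-off track with
#'   a warning.
#' @export
binarize <- function(mark_midpoints, input_midpoints, chrom_sizes,
                     bin = 200, p_threshold = 1e-4) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  as_pos <- function(x) {
    if (!"pos" %in% names(x)) x$pos <- (x$start + x$end) %/% 2L
    x
  }
  mark <- as_pos(mark_midpoints)
  input <- as_pos(input_midpoints)
  if (nrow(input) == 0) stop("control (input) track has no reads")
  grid <- bin_counts(mark, chrom_sizes, bin)
  ctrl <- bin_counts(input, chrom_sizes, bin)
  if (nrow(mark) == 0) {
    warning("mark track has no reads; returning all-off track")
    grid$on <- FALSE
    return(grid)
  }
  ratio <- nrow(mark) / nrow(input)
  mean_mark <- nrow(mark) / nrow(grid)
  lambda <- ifelse(ctrl$count > 0, ctrl$count * ratio, mean_mark)
  # upper tail P(X >= obs) = ppois(obs - 1, lambda, lower.tail = FALSE)
  p <- stats::ppois(grid$count - 1, lambda, lower.tail = FALSE)
  grid$on <- grid$count > 0 & p <= p_threshold
  grid
}

bin_counts <- function(midpoints, chrom_sizes, bin) {
  grid <- chrom_sizes |>
    dplyr::rowwise() |>
    dplyr::reframe(chrom = .data$chrom,
                   start = seq(0L, .data$size - 1L, by = bin),
                   size = .data$size) |>
    dplyr::mutate(end = as.integer(pmin(.data$start + bin, .data$size))) |>
    dplyr::select("chrom", "start", "end")
  counts <- midpoints |>
    dplyr::mutate(start = as.integer((.data$pos %/% bin) * bin)) |>
    dplyr::count(.data$chrom, .data$start, name = "count")
  grid |>
    dplyr::left_join(counts, by = c("chrom", "start")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Segment the genome into four mark-pair chromatin states
#'
#' Combines two binarized tracks (an ordered mark pair A, B) bin-wise with
#' the four-state truth table — `both` (A and B), `a_only`, `b_only`,
#' `none` — and merges runs of equal-state bins into segments. The segments
#' tile the genome exactly.
#'
#' @param track_a,track_b Binarized tracks from [binarize()] on the same
#'   bin grid.
#' @param marks Length-2 character vector naming the pair (metadata only).
#' @return Tibble with `chrom`, `start`, `end`, `state` (factor
#'   a_only/b_only/both/none), with a `marks` attribute.
#' @export
segment_mark_pair <- function(track_a, track_b, marks = c("A", "B")) {
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$chrom == track_b$chrom & track_a$start == track_b$start)) {
    stop("binarized tracks are not on the same bin grid")
  }
  state <- dplyr::case_when(
    track_a$on & track_b$on ~ "both",
    track_a$on & !track_b$on ~ "a_only",
    !track_a$on & track_b$on ~ "b_only",
    TRUE ~ "none"
  )
  seg <- tibble::tibble(chrom = track_a$chrom, start = track_a$start,
                        end = track_a$end, state = state) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(.data$state != dplyr::lag(.data$state,
                                                         default = "<none>"))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     state = .data$state[1], .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end", "state")
  seg$state <- factor(seg$state, levels = c("a_only", "b_only", "both", "none"))
  attr(seg, "marks") <- marks
  seg
}

#' Assign a mark-pair chromatin state to each promoter
#'
#' The promoter window is strand-aware, 2 kb upstream to 1 kb downstream of
#' the TSS by default. A promoter containing (overlapping by at least
#' `min_overlap` bp) a `both` segment, or both an `a_only` and a `b_only`
#' segment, carries both marks (`both`); one exclusively containing
#' `a_only` segments is `a_only` (likewise `b_only`); otherwise `none`.
#' With the conventional pair (A = H3K9ac, B = H3K27me3), `both` is the
#' bivalent promoter class.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param segments State segments from [segment_mark_pair()].
#' @param upstream,downstream Promoter window extent around the TSS (bp).
#' @param min_overlap Minimum overlap (bp) for "contains"; default 1
#'   (any nonzero overlap).
#' @return Tibble with `gene_id` and `state` (factor
#'   a_only/b_only/both/none).
#' @export
assign_promoter_state <- function(genes, segments, upstream = 2000,
                                  downstream = 1000, min_overlap = 1) {
  win <- tss_windows(genes, upstream = upstream, downstream = downstream)
  state <- region_pair_state(win, segments, min_overlap)
  tibble::tibble(gene_id = win$gene_id, state = state)
}

# Shared promoter/enhancer rule: which of the four mark-pair states does a
# region carry, given the segments it overlaps.
region_pair_state <- function(regions, segments, min_overlap = 1) {
  seg_split <- split(segments, segments$chrom)
  vapply(seq_len(nrow(regions)), function(i) {
    s <- seg_split[[regions$chrom[i]]]
    if (is.null(s)) return("none")
    ov <- overlap_width(s$start, s$end, regions$start[i], regions$end[i])
    st <- s$state[ov >= min_overlap]
    has_both <- any(st == "both")
    has_a <- any(st == "a_only")
    has_b <- any(st == "b_only")
    if (has_both || (has_a && has_b)) "both"
    else if (has_a) "a_only"
    else if (has_b) "b_only"
    else "none"
  }, character(1)) |>
    factor(levels = c("a_only", "b_only", "both", "none"))
}

#' Tabulate promoter state transitions between conditions
#'
#' Counts genes in each (state in control, state in treated) cell of the
#' 4x4 transition table — the numeric form of an alluvial plot of promoter
#' histone-modification dynamics. Row sums equal the per-state tallies of
#' the control condition.
#'
#' @param states_ctrl,states_kd Promoter-state tibbles from
#'   [assign_promoter_state()] over the same gene universe.
#' @return Tibble with `state_ctrl`, `state_kd`, `n`, complete over all 16
#'   cells.
#' @export
promoter_transition_table <- function(states_ctrl, states_kd) {
  if (nrow(states_ctrl) != nrow(states_kd) ||
      !setequal(states_ctrl$gene_id, states_kd$gene_id)) {
    missing <- c(setdiff(states_ctrl$gene_id, states_kd$gene_id),
                 setdiff(states_kd$gene_id, states_ctrl$gene_id))
    stop("gene universes differ between conditions; missing: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  lv <- levels(states_ctrl$state)
  dplyr::inner_join(
    dplyr::rename(states_ctrl, state_ctrl = "state"),
    dplyr::rename(states_kd, state_kd = "state"),
    by = "gene_id"
  ) |>
    dplyr::count(.data$state_ctrl, .data$state_kd) |>
    tidyr::complete(state_ctrl = factor(lv, levels = lv),
                    state_kd = factor(lv, levels = lv),
                    fill = list(n = 0L))
}

#' Collapse a mark-pair state to the active / non-active dichotomy
#'
#' For downstream contingency analysis a promoter (or enhancer) state is
#' "active" when it includes the active mark of the pair (the `a_only` or
#' `both` states for pairs ordered active-first) and "non-active"
#' otherwise. The mapping is a documented convention, configurable via
#' `active_states`.
#'
#' @param state Factor of mark-pair states.
#' @param active_states States counted as active.
#' @return Factor with levels `active`, `non_active`.
#' @export
collapse_active <- function(state, active_states = c("a_only", "both")) {
  factor(ifelse(state %in% active_states, "active", "non_active"),
         levels = c("active", "non_active"))
}
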