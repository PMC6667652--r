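#' Build a dyad index from MNase fragment intervals
#'
#' The midpoint of each paired-end fragment estimates the nucleosome dyad
#' (the centre of the ~147 bp wrapped around the octamer). Midpoints are
#' `floor((start + end) / 2)` and identical dyads are aggregated with a
#' multiplicity count.
#'
#' @param fragments Tibble of fragment intervals (`chrom`, `start`, `end`).
#' @return Tibble with `chrom`, `dyad`, `n` (multiplicity), sorted by
#'   chromosome and position. Empty input gives an empty index.
#' @export
build_dyad_index <- function(fragments) {
  if (nrow(fragments) == 0) {
    return(tibble::tibble(chrom = character(), dyad = integer(), n = integer()))
  }
  tibble::tibble(
    chrom = fragments$chrom,
    dyad = as.integer((fragments$start + fragments$end) %/% 2L)
  ) |>
    dplyr::count(.data$chrom, .data$dyad, name = "n") |>
    dplyr::arrange(.data$chrom, .data$dyad)
}

# Gaussian-smoothed dyad profile evaluated on an integer grid covering the
# dyads +/- 4 sigma. Returns list(pos, height). Kernel is the unnormalised
# Gaussian exp(-d^2 / (2 sigma^2)); only relative heights matter.
smooth_dyad_profile <- function(dyad, n, sigma) {
  half <- as.integer(ceiling(4 * sigma))
  lo <- min(dyad) - half
  hi <- max(dyad) + half
  len <- hi - lo + 1L
  counts <- numeric(len)
  idx <- dyad - lo + 1L
  counts[idx] <- counts[idx] + n  # dyads are unique rows already
  kern <- exp(-((-half:half)^2) / (2 * sigma^2))
  height <- stats::filter(counts, kern, sides = 2)
  height[is.na(height)] <- 0
  list(pos = lo:hi, height = as.numeric(height))
}

call_nucleosomes_chrom <- function(dyad, n, sigma, exclusion, min_rc) {
  prof <- smooth_dyad_profile(dyad, n, sigma)
  h <- prof$height
  len <- length(h)
  if (len < 3) return(NULL)
  # strict rise on the left, non-strict fall on the right: a flat-topped
  # plateau yields its leftmost position (deterministic tie-break)
  is_max <- c(FALSE, h[2:(len - 1)] > h[1:(len - 2)] &
                h[2:(len - 1)] >= h[3:len], FALSE) & h > 0
  cand_pos <- prof$pos[is_max]
  cand_h <- h[is_max]
  ord <- order(-cand_h, cand_pos)
  cand_pos <- cand_pos[ord]
  accepted <- integer(0)
  min_gap <- exclusion / 2
  for (p in cand_pos) {
    if (length(accepted) == 0 || all(abs(accepted - p) >= min_gap)) {
      accepted <- c(accepted, p)
    }
  }
  if (length(accepted) == 0) return(NULL)
  accepted <- sort(accepted)
  # dyad is sorted within chrom: binary search for the +/-73 bp members
  res <- lapply(accepted, function(p) {
    i0 <- findInterval(p - 73L - 0.5, dyad) + 1L
    i1 <- findInterval(p + 73L + 0.5, dyad)
    if (i1 < i0) return(NULL)
    member <- i0:i1
    rc <- sum(n[member])
    if (rc < min_rc) return(NULL)
    offs <- rep(dyad[member] - p, n[member])
    list(dyad = p, rc = rc, fuzziness = sqrt(mean(offs^2)))
  })
  res[!vapply(res, is.null, logical(1))]
}

#' Call nucleosome positions from a dyad index
#'
#' Genetrack-style calling: per-chromosome dyad counts are smoothed with a
#' Gaussian kernel (sd `sigma`), local maxima of the smoothed profile become
#' candidate dyads, and candidates are accepted greedily by descending
#' smoothed height while suppressing any candidate closer than
#' `exclusion / 2` bp to an accepted one. For each accepted dyad the read
#' count `rc` sums dyad multiplicities within +/-73 bp (one nucleosome
#' footprint), calls with `rc < min_rc` are dropped to control false
#' discovery, occupancy is `rc` per million indexed dyads, and fuzziness is
#' the population standard deviation of member dyad offsets from the called
#' dyad (0 for a single member; low fuzziness = well-positioned).
#'
#' @param index Dyad index from [build_dyad_index()].
#' @param sigma Gaussian kernel sd in bp.
#' @param exclusion Exclusion-zone width in bp (one nucleosome; accepted
#'   dyads are at least `exclusion / 2` bp apart).
#' @param min_rc Minimum read count for a called nucleosome.
#' @return Tibble with `chrom`, `dyad`, `rc`, `occupancy`, `fuzziness`.
#' @export
call_nucleosomes <- function(index, sigma = 20, exclusion = 147, min_rc = 6) {
  stopifnot(sigma > 0, exclusion > 0)
  empty <- tibble::tibble(chrom = character(), dyad = integer(),
                          rc = integer(), occupancy = numeric(),
                          fuzziness = numeric())
  if (nrow(index) == 0) return(empty)
  total <- sum(index$n)
  out <- index |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      nucs <- call_nucleosomes_chrom(d$dyad, d$n, sigma, exclusion, min_rc)
      if (length(nucs) == 0) return(NULL)
      tibble::tibble(
        chrom = key$chrom,
        dyad = vapply(nucs, `[[`, integer(1), "dyad"),
        rc = as.integer(vapply(nucs, `[[`, numeric(1), "rc")),
        fuzziness = vapply(nucs, `[[`, numeric(1), "fuzziness")
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) return(empty)
  out$occupancy <- out$rc / (total / 1e6)
  out[, c("chrom", "dyad", "rc", "occupancy", "fuzziness")]
}

#' Bin read midpoints and normalise as RPKM
#'
#' Divides each chromosome into non-overlapping bins, counts midpoints per
#' bin and normalises as reads per kilobase per million mapped reads:
#' `count / (bin_kb * total_mapped / 1e6)`. Used both for the 10-kb
#' replicate-reproducibility grid and for 10-bp signal tracks.
#'
#' @param midpoints Tibble with `chrom` and `pos` (or intervals, in which
#'   case midpoints are taken).
#' @param chrom_sizes Tibble with `chrom`, `size`.
#' @param bin Bin width in bp.
#' @param total_mapped Library size; defaults to `nrow(midpoints)`.
#' @return Tibble with `chrom`, `start`, `end`, `count`, `value` (RPKM),
#'   covering every bin of every chromosome.
#' @export
binned_rpkm <- function(midpoints, chrom_sizes, bin = 10000,
                        total_mapped = NULL) {
  if (is.null(total_mapped)) total_mapped <- nrow(midpoints)
  if (total_mapped <= 0) stop("total_mapped must be positive")
  if (!"pos" %in% names(midpoints)) {
    midpoints$pos <- (midpoints$start + midpoints$end) %/% 2L
  }
  grid <- chrom_sizes |>
    dplyr::rowwise() |>
    dplyr::reframe(chrom = .data$chrom,
                   start = seq(0L, .data$size - 1L, by = bin)) |>
    dplyr::mutate(end = pmin(.data$start + bin, NA))
  # recompute end per chrom against its size
  grid <- dplyr::left_join(grid, chrom_sizes, by = "chrom") |>
    dplyr::mutate(end = as.integer(pmin(.data$start + bin, .data$size))) |>
    dplyr::select("chrom", "start", "end")
  counts <- midpoints |>
    dplyr::mutate(start = as.integer((.data$pos %/% bin) * bin)) |>
    dplyr::count(.data$chrom, .data$start, name = "count")
  grid |>
    dplyr::left_join(counts, by = c("chrom", "start")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      value = .data$count / (((.data$end - .data$start) / 1000) *
                               (total_mapped / 1e6))
    )
}

#' Pearson correlation between two binned replicate tracks
#'
#' Measures replicate reproducibility on a shared bin grid. Replicates that
#' pass a correlation threshold are conventionally pooled before calling.
#'
#' @param sig_a,sig_b Binned signal tibbles on the same grid (same
#'   `chrom`/`start` rows, in order), as from [binned_rpkm()].
#' @return Pearson r; `NaN` with a warning when either track has zero
#'   variance.
#' @export
replicate_correlation <- function(sig_a, sig_b) {
  if (nrow(sig_a) != nrow(sig_b) ||
      !all(sig_a$chrom == sig_b$chrom & sig_a$start == sig_b$start)) {
    stop("replicate tracks are not on the same bin grid")
  }
  if (stats::sd(sig_a$value) == 0 || stats::sd(sig_b$value) == 0) {
    warning("zero-variance signal track; correlation undefined")
    return(NaN)
  }
  stats::cor(sig_a$value, sig_b$value)
}
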