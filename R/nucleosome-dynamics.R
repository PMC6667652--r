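#' Classify nucleosome dynamics between two conditions
#'
#' Nucleosomes from the control and treated (e.g. knockdown) samples are
#' paired per chromosome as mutual nearest neighbours by dyad distance, so
#' each nucleosome joins at most one pair. Pairs are classified by dyad
#' (midpoint) distance `d`: `fixed` when `d = 0`; `shift` when
#' `shift_min <= d < shift_max` (defaults 1 and 117 bp, i.e. the two
#' footprints still overlap by more than 30 bp); otherwise the pair is
#' dissolved into one `loss` and one `gain` (flagged `dissolved`). Unpaired
#' control nucleosomes are losses (evicted), unpaired treated nucleosomes
#' are gains (assembled).
#'
#' @param ctrl,kd Nucleosome tibbles from [call_nucleosomes()].
#' @param shift_min,shift_max Dyad-distance bounds (bp) for the shift class;
#'   the upper bound is exclusive.
#' @return Tibble with `chrom`, `dyad_ctrl`, `dyad_kd`, `distance`,
#'   `category` (factor fixed/shift/loss/gain) and `dissolved`. Every
#'   nucleosome from both inputs appears in exactly one row except dissolved
#'   pairs, which occupy two rows (one loss, one gain).
#' @export
pair_nucleosomes <- function(ctrl, kd, shift_min = 1, shift_max = 117) {
  chroms <- union(unique(ctrl$chrom), unique(kd$chrom))
  out <- lapply(chroms, function(ch) {
    a <- sort(ctrl$dyad[ctrl$chrom == ch])
    b <- sort(kd$dyad[kd$chrom == ch])
    pair_chrom(ch, a, b, shift_min, shift_max)
  })
  res <- dplyr::bind_rows(out)
  res$category <- factor(res$category, levels = c("fixed", "shift", "loss", "gain"))
  res
}

# Mutual-nearest-neighbour pairing on sorted dyad vectors of one chromosome.
# Nearest neighbour ties break towards the smaller coordinate.
pair_chrom <- function(ch, a, b, shift_min, shift_max) {
  row <- function(dc, dk, cat, dis = FALSE) {
    tibble::tibble(chrom = ch, dyad_ctrl = dc, dyad_kd = dk,
                   distance = ifelse(is.na(dc) | is.na(dk), NA_integer_,
                                     abs(dk - dc)),
                   category = cat, dissolved = dis)
  }
  if (length(a) == 0 && length(b) == 0) return(NULL)
  if (length(a) == 0) return(row(NA_integer_, b, "gain"))
  if (length(b) == 0) return(row(a, NA_integer_, "loss"))
  nn_ab <- nearest_sorted(a, b)
  nn_ba <- nearest_sorted(b, a)
  mutual <- which(nn_ba[nn_ab] == seq_along(a))
  rows <- list()
  paired_b <- logical(length(b))
  paired_a <- logical(length(a))
  for (i in mutual) {
    j <- nn_ab[i]
    paired_a[i] <- TRUE
    paired_b[j] <- TRUE
    d <- abs(a[i] - b[j])
    if (d == 0) {
      rows[[length(rows) + 1]] <- row(a[i], b[j], "fixed")
    } else if (d >= shift_min && d < shift_max) {
      rows[[length(rows) + 1]] <- row(a[i], b[j], "shift")
    } else {
      rows[[length(rows) + 1]] <- row(a[i], NA_integer_, "loss", TRUE)
      rows[[length(rows) + 1]] <- row(NA_integer_, b[j], "gain", TRUE)
    }
  }
  if (any(!paired_a)) rows[[length(rows) + 1]] <- row(a[!paired_a], NA_integer_, "loss")
  if (any(!paired_b)) rows[[length(rows) + 1]] <- row(NA_integer_, b[!paired_b], "gain")
  dplyr::bind_rows(rows) |> dplyr::arrange(pmin(.data$dyad_ctrl, .data$dyad_kd, na.rm = TRUE))
}

# Index of the nearest element of sorted vector y for each element of x;
# ties towards the smaller coordinate.
nearest_sorted <- function(x, y) {
  hi <- findInterval(x, y) + 1L
  lo <- pmax(hi - 1L, 1L)
  hi <- pmin(hi, length(y))
  dlo <- abs(x - y[lo])
  dhi <- abs(x - y[hi])
  ifelse(dlo <= dhi, lo, hi)
}

#' Call promoter nucleosome-free region status between two conditions
#'
#' The canonical NFR spans 200 bp upstream to 50 bp downstream of the TSS
#' (strand-aware, 250 bp). An NFR is considered occupied in a sample when
#' any called nucleosome footprint (`dyad - 73 .. dyad + 74`) overlaps the
#' window by at least `min_overlap` bp (default 118 = 80% of a 147-bp
#' nucleosome, rounded up). Status per gene: `lost` when the control NFR is
#' open but a nucleosome assembles into it in the treated sample; `gained`
#' when a control nucleosome is evicted so the NFR forms; `retained` when
#' open in both; `absent_both` when occupied in both.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param ctrl_nucs,kd_nucs Nucleosome tibbles from [call_nucleosomes()].
#' @param upstream,downstream NFR window extent around the TSS (bp).
#' @param min_overlap Minimum footprint overlap (bp) for "occupied".
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `status`.
#' @export
call_nfr_status <- function(genes, ctrl_nucs, kd_nucs,
                            upstream = 200, downstream = 50,
                            min_overlap = 118) {
  win <- tss_windows(genes, upstream = upstream, downstream = downstream)
  occ <- function(nucs) {
    vapply(seq_len(nrow(win)), function(i) {
      d <- nucs$dyad[nucs$chrom == win$chrom[i]]
      if (length(d) == 0) return(FALSE)
      any(overlap_width(d - 73L, d + 74L, win$start[i], win$end[i]) >= min_overlap)
    }, logical(1))
  }
  occ_ctrl <- occ(ctrl_nucs)
  occ_kd <- occ(kd_nucs)
  status <- dplyr::case_when(
    !occ_ctrl & occ_kd ~ "lost",
    occ_ctrl & !occ_kd ~ "gained",
    !occ_ctrl & !occ_kd ~ "retained",
    TRUE ~ "absent_both"
  )
  tibble::tibble(gene_id = win$gene_id, chrom = win$chrom,
                 start = win$start, end = win$end,
                 status = factor(status, levels = c("retained", "lost",
                                                    "gained", "absent_both")))
}

#' Occupancy matrix around regions, with K-means clustering
#'
#' Builds a regions-by-bins matrix of signal across `+/- flank` bp around
#' each region midpoint (columns flipped for minus-strand regions so that
#' upstream is always left), then clusters rows with K-means. Intended for
#' heat maps of nucleosome occupancy around NFRs that were lost or gained
#' (the conventional display uses K = 5).
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optional `strand`.
#' @param signal Binned signal tibble (`chrom`, `start`, `end`, `value`)
#'   on a uniform grid, as from [binned_rpkm()].
#' @param flank Flank in bp on each side of the region midpoint.
#' @param k Number of K-means clusters.
#' @param seed RNG seed for K-means (labels are reproducible given a seed).
#' @return List with `matrix` (rows = regions, columns = bins) and
#'   `cluster` (integer labels); class `chromdyn_occupancy`.
#' @export
occupancy_matrix <- function(regions, signal, flank = 1000, k = 5, seed = 1) {
  stopifnot(k >= 1)
  if (nrow(regions) < k) {
    stop("fewer regions (", nrow(regions), ") than clusters (", k, ")")
  }
  bin <- signal$end[1] - signal$start[1]
  nbin <- as.integer(2 * floor(flank / bin))
  mid <- (regions$start + regions$end) %/% 2L
  mat <- matrix(0, nrow = nrow(regions), ncol = nbin)
  sig_split <- split(signal, signal$chrom)
  for (i in seq_len(nrow(regions))) {
    s <- sig_split[[regions$chrom[i]]]
    if (is.null(s)) next
    first_bin <- (mid[i] - flank) %/% bin
    idx <- match(first_bin + seq_len(nbin) - 1L, s$start %/% bin)
    vals <- ifelse(is.na(idx), 0, s$value[idx])
    if ("strand" %in% names(regions) && isTRUE(regions$strand[i] == "-")) {
      vals <- rev(vals)
    }
    mat[i, ] <- vals
  }
  cl <- withr::with_seed(seed, stats::kmeans(mat, centers = k, nstart = 5))
  structure(list(matrix = mat, cluster = cl$cluster, flank = flank, bin = bin),
            class = "chromdyn_occupancy")
}
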