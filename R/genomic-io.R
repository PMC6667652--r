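#' Read a BED file into a tibble
#'
#' Reads BED3/BED5/narrowPeak-style tab-separated files. Coordinates are
#' 0-based half-open and are kept verbatim. With `scored = TRUE` column 5 is
#' returned as `score` (the Homer/MACS peak score convention).
#'
#' @param path Path to a tab-separated BED file (no header).
#' @param scored If `TRUE`, require at least 5 columns and return the score.
#' @return A tibble with columns `chrom`, `start`, `end`, plus `name` and
#'   `score` when present/requested.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t300\tp1\t7.5"), tf)
#' read_bed(tf, scored = TRUE)
#' @export
read_bed <- function(path, scored = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(), end = integer())
    if (scored) out$name <- character()
    if (scored) out$score <- numeric()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  min_cols <- if (scored) 5L else 3L
  bad <- which(ncols < min_cols)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path, ": expected >= ",
         min_cols, " tab-separated columns, got ", ncols[bad[1]])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path, ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop("malformed BED line ", bad[1], " in ", path, ": start >= end (",
         start[bad[1]], " >= ", end[bad[1]], ")")
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end
  )
  if (any(ncols >= 4L) && (scored || all(ncols >= 4L))) {
    out$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  }
  if (scored) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    bad <- which(is.na(score))
    if (length(bad) > 0) {
      stop("malformed BED line ", bad[1], " in ", path, ": non-numeric score")
    }
    if (any(score < 0)) stop("negative peak score in ", path)
    out$score <- score
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` and, when present,
#' `name` and `score` columns as tab-separated BED with no header.
#'
#' @param x Tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  # BED columns are positional: score (col 5) requires a name placeholder
  if ("score" %in% cols && !("name" %in% cols)) {
    x$name <- "."
    cols <- intersect(c("chrom", "start", "end", "name", "score"), names(x))
  }
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with header columns `gene_id`, `chrom`, `strand`, `tss`,
#' `tes`. Coordinates are 0-based by default; tables exported from 1-based
#' tools should be loaded with `one_based = TRUE`, which shifts positions
#' down by one on load.
#'
#' @param path Path to the TSV.
#' @param one_based Set `TRUE` when the table uses 1-based coordinates.
#' @return A tibble of gene models.
#' @export
read_gene_table <- function(path, one_based = FALSE) {
  g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene_id", "chrom", "strand", "tss", "tes")
  missing <- setdiff(req, names(g))
  if (length(missing) > 0) stop("gene table missing columns: ", paste(missing, collapse = ", "))
  if (!all(g$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(g$tss == g$tes)) stop("gene with tss == tes")
  if (one_based) {
    g$tss <- g$tss - 1L
    g$tes <- g$tes - 1L
  }
  g[, req]
}

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (chrom, size), no header.
#' @return Tibble with `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "size"),
                  col_types = "ci", progress = FALSE)
}

#' Write a binned signal track as bedGraph
#'
#' @param x Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Overlap width of two genomic intervals
#'
#' Vectorised over rows. Intervals are 0-based half-open, so abutting
#' intervals overlap by 0 bp; intervals on different chromosomes overlap 0.
#'
#' @param a,b Tibbles with `chrom`, `start`, `end` (recycled row-wise).
#' @return Integer vector of overlap widths in bp.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 300)
#' b <- tibble::tibble(chrom = "chr1", start = 200, end = 400)
#' interval_overlap(a, b)  # 100
#' @export
interval_overlap <- function(a, b) {
  w <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  as.integer(ifelse(a$chrom == b$chrom, w, 0L))
}

overlap_width <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

#' Find the nearest feature to each query interval
#'
#' Distance is measured from the query midpoint to the feature anchor (a TSS
#' column for gene tables, or the interval midpoint). Ties are broken towards
#' the smaller coordinate, so results are deterministic. Features farther
#' than `max_dist` yield `NA`.
#'
#' @param query Tibble of intervals (`chrom`, `start`, `end`).
#' @param features Tibble of features; must carry `chrom` and the anchor.
#' @param anchor `"tss"` (uses `features$tss`) or `"midpoint"`
#'   (uses `floor((start + end) / 2)`).
#' @param max_dist Maximum distance in bp; beyond it no feature is assigned.
#' @return Integer vector of row indices into `features` (NA when none).
#' @export
nearest_feature <- function(query, features, anchor = c("tss", "midpoint"),
                            max_dist = Inf) {
  anchor <- match.arg(anchor)
  if (nrow(query) == 0) return(integer(0))
  if (nrow(features) == 0) return(rep(NA_integer_, nrow(query)))
  pos <- if (anchor == "tss") features$tss else (features$start + features$end) %/% 2L
  qmid <- (query$start + query$end) %/% 2L
  vapply(seq_len(nrow(query)), function(i) {
    on_chrom <- which(features$chrom == query$chrom[i])
    if (length(on_chrom) == 0) return(NA_integer_)
    d <- abs(pos[on_chrom] - qmid[i])
    dmin <- min(d)
    if (dmin > max_dist) return(NA_integer_)
    cand <- on_chrom[d == dmin]
    cand[which.min(pos[cand])]
  }, integer(1))
}

#' Strand-aware windows around gene TSSs
#'
#' Builds `[tss - upstream, tss + downstream)` windows, flipping upstream and
#' downstream for minus-strand genes. With the defaults this is the promoter
#' window (2 kb upstream to 1 kb downstream of the TSS); `upstream = 200,
#' downstream = 50` gives the canonical nucleosome-free region window.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`).
#' @param upstream,downstream Window extent in bp on each side of the TSS.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
tss_windows <- function(genes, upstream = 2000, downstream = 1000) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  tibble::tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = as.integer(pmax(0, start)),
    end = as.integer(end),
    strand = genes$strand
  )
}
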