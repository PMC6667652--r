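#' Associate each enhancer with its nearest promoter
#'
#' Pairs every enhancer with the nearest gene TSS (midpoint-to-TSS
#' distance) within `max_dist`; enhancers with no promoter in range are
#' dropped. Several enhancers may share a promoter.
#'
#' @param enhancers Enhancer tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @param max_dist Maximum association distance in bp.
#' @return The enhancer tibble with an added `gene_id` column, restricted
#'   to associated enhancers.
#' @export
associate_enhancer_promoter <- function(enhancers, genes, max_dist = 100000) {
  idx <- nearest_feature(enhancers, genes, anchor = "tss", max_dist = max_dist)
  out <- enhancers
  out$gene_id <- genes$gene_id[idx]
  out[!is.na(out$gene_id), ]
}

#' Build a 2x2 contingency table from classified pairs
#'
#' Applies a row and a column classifier to each enhancer-promoter pair and
#' tabulates the 2x2 counts. Classifiers return one of exactly two category
#' labels, or `NA` / `"excluded"` to drop the pair.
#'
#' @param pairs Tibble of associated pairs.
#' @param row_class,col_class Character/factor vectors (length `nrow(pairs)`)
#'   or functions of `pairs` producing them.
#' @return A 2x2 integer matrix with category dimnames.
#' @export
build_contingency <- function(pairs, row_class, col_class) {
  if (is.function(row_class)) row_class <- row_class(pairs)
  if (is.function(col_class)) col_class <- col_class(pairs)
  row_class <- as.character(row_class)
  col_class <- as.character(col_class)
  keep <- !is.na(row_class) & !is.na(col_class) &
    row_class != "excluded" & col_class != "excluded"
  r <- row_class[keep]
  cc <- col_class[keep]
  rl <- sort(unique(r))
  cl <- sort(unique(cc))
  if (length(rl) > 2 || length(cl) > 2) {
    stop("classifiers must produce at most two categories")
  }
  tab <- table(factor(r, levels = rl), factor(cc, levels = cl))
  m <- matrix(as.integer(tab), nrow = length(rl), ncol = length(cl),
              dimnames = list(rl, cl))
  m
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Computes the Pearson chi-square statistic without continuity correction,
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, with p-value from the
#' upper tail of the chi-square distribution with 1 df. Fisher's exact test
#' is available as an option for small tables.
#'
#' @param counts 2x2 numeric matrix of counts.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return An object of class `chromdyn_indep` with elements `counts`,
#'   `statistic`, `df`, `p.value`, `method`; supports [generics::tidy()]
#'   and [generics::glance()].
#' @examples
#' chi_square_2x2(matrix(c(361, 494, 169, 241), nrow = 2))
#' @export
chi_square_2x2 <- function(counts, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"  # avoid integer overflow in N(ad-bc)^2
  if (!all(dim(counts) == c(2, 2))) stop("counts must be a 2x2 table")
  if (any(counts < 0)) stop("negative counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("test undefined: a marginal total is zero")
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(counts)
    res <- list(counts = counts, statistic = NA_real_, df = NA_integer_,
                p.value = ft$p.value, method = "fisher")
  } else {
    a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
    n <- sum(counts)
    chi2 <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    res <- list(counts = counts, statistic = chi2, df = 1L,
                p.value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                method = "chisq")
  }
  structure(res, class = "chromdyn_indep")
}

#' @export
print.chromdyn_indep <- function(x, ...) {
  cat("2x2 independence test (", x$method, ")\n", sep = "")
  print(x$counts)
  if (x$method == "chisq") {
    cat(sprintf("chi2 = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p.value))
  } else {
    cat(sprintf("p = %.4g\n", x$p.value))
  }
  invisible(x)
}

#' Tidy an independence-test result
#'
#' @param x A `chromdyn_indep` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `method`.
#' @method tidy chromdyn_indep
#' @export
tidy.chromdyn_indep <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p.value = x$p.value, method = x$method)
}

#' Glance at an independence-test result
#'
#' @param x A `chromdyn_indep` object.
#' @param ... Unused.
#' @return One-row tibble with the statistic, p-value and table total.
#' @method glance chromdyn_indep
#' @export
glance.chromdyn_indep <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 n = sum(x$counts), method = x$method)
}

#' Reference contingency tables for the MYCN-knockdown independence analysis
#'
#' The six published 2x2 tables crossing enhancer chromatin-state change
#' classes against promoter chromatin-state change classes (and vice versa)
#' after MYCN knockdown in BE(2)C neuroblastoma cells. Rows are the grouping
#' element's change class; columns count the associated partner elements by
#' change class. Useful as worked inputs for [chi_square_2x2()].
#'
#' @return Named list of six 2x2 integer matrices with informative
#'   dimnames.
#' @export
mycn_kd_tables <- function() {
  t_ <- function(a, b, c, d, rows, cols) {
    matrix(as.integer(c(a, c, b, d)), nrow = 2,
           dimnames = list(rows, cols))
  }
  prom <- c("prom active -> non-active", "prom non-active -> active")
  enh_oa <- c("enh off -> primed", "enh primed -> off")
  enh_act <- c("enh non-active -> active", "enh active -> non-active")
  enh_w <- c("enh narrow -> wide", "enh wide -> narrow")
  prom_r <- c("prom non-active -> active", "prom active -> non-active")
  list(
    enhancer_onoff_vs_promoter = t_(361, 169, 494, 241, enh_oa, prom),
    enhancer_activity_vs_promoter = t_(143, 80, 193, 100, enh_act, prom),
    enhancer_width_vs_promoter = t_(45, 26, 85, 57, enh_w, prom),
    promoter_vs_enhancer_activity = t_(246, 167, 421, 343, prom_r,
                                       c("enh active -> non-active",
                                         "enh non-active -> active")),
    promoter_vs_enhancer_onoff = t_(671, 421, 1387, 866, prom_r,
                                    c("enh primed -> off",
                                      "enh off -> primed")),
    promoter_vs_enhancer_width = t_(120, 49, 183, 75, prom_r,
                                    c("enh wide -> narrow",
                                      "enh narrow -> wide"))
  )
}

#' Compare expression between promoter state-change groups
#'
#' Groups genes by their promoter-state transition and compares expression
#' values between two groups with a two-sided Wilcoxon rank-sum test.
#'
#' @param expr Tibble with `gene_id` and `value` (expression).
#' @param transitions Tibble with `gene_id`, `state_ctrl`, `state_kd`.
#' @param group_a,group_b Each a list with elements `from` and `to` naming
#'   the transition defining the group (either may be `NULL` to match any).
#' @return List with `values_a`, `values_b`, `p.value` (NaN with a warning
#'   when either group has fewer than 3 genes).
#' @export
expression_by_state_change <- function(expr, transitions, group_a, group_b) {
  pick <- function(g) {
    sel <- rep(TRUE, nrow(transitions))
    if (!is.null(g$from)) sel <- sel & transitions$state_ctrl == g$from
    if (!is.null(g$to)) sel <- sel & transitions$state_kd == g$to
    ids <- transitions$gene_id[sel]
    expr$value[match(ids, expr$gene_id)]
  }
  va <- pick(group_a)
  vb <- pick(group_b)
  if (length(va) < 3 || length(vb) < 3) {
    warning("group with fewer than 3 genes; p-value undefined")
    return(list(values_a = va, values_b = vb, p.value = NaN))
  }
  p <- stats::wilcox.test(va, vb, exact = FALSE)$p.value
  list(values_a = va, values_b = vb, p.value = p)
}
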