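#' Simulate a small genome with planted chromatin-dynamics truth
#'
#' Lays out a desk-scale genome (default 2 chromosomes x 2 Mb with 200
#' evenly spaced genes and one enhancer per gene) and plants a recorded set
#' of two-condition events: promoter NFR losses and gains, nucleosome
#' shifts, promoter mark-pair state switches, enhancer activity-state
#' switches, enhancer width changes, and MYCN-bound subsets. Every planted
#' event is recorded in the returned truth object; downstream recovery is
#' always measured against it, never against the generated reads.
#'
#' Planted gene sets are disjoint (a gene is never both an NFR loss and an
#' NFR gain). Genes sit on alternating strands; enhancers sit 8 kb
#' downstream of their gene's TSS, well clear of the 2-kb TSS exclusion
#' zone and within the 50-kb target-gene range.
#'
#' @param seed Master seed; every derived RNG stream records it.
#' @param n_chroms,chrom_size,n_genes Genome layout.
#' @param n_nfr_loss,n_nfr_gain Genes with planted NFR loss / gain.
#' @param n_shifts Genes whose +3 nucleosome is shifted (1-116 bp).
#' @param n_promoter_switches Genes with a planted promoter mark-pair state
#'   switch (H3K9ac/H3K27me3 pair).
#' @param n_enhancer_switches Enhancers with a planted activity-state
#'   switch.
#' @param n_broader,n_shorter Enhancers with planted H3K4me1 peak width
#'   changes (over 1.5-fold).
#' @param mycn_frac Fraction of promoters/enhancers flagged MYCN-bound.
#' @return A `chromdyn_truth` list: `chrom_sizes`, `genes`, `promoters`
#'   (per-gene state before/after), `enhancers` (per-enhancer state and
#'   width before/after), planted id sets, and `seed`.
#' @export
simulate_truth <- function(seed = 1, n_chroms = 2, chrom_size = 2e6,
                           n_genes = 200, n_nfr_loss = 50, n_nfr_gain = 50,
                           n_shifts = 50, n_promoter_switches = 100,
                           n_enhancer_switches = 100, n_broader = 20,
                           n_shorter = 20, mycn_frac = 0.5) {
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  spacing <- 20000L
  stopifnot(10000 + (genes_per_chrom - 1) * spacing + 10000 <= chrom_size)
  chrom_sizes <- tibble::tibble(
    chrom = paste0("chr", seq_len(n_chroms)),
    size = as.integer(chrom_size)
  )
  idx <- seq_len(n_genes) - 1L
  chrom <- chrom_sizes$chrom[(idx %/% genes_per_chrom) + 1L]
  pos <- 10000L + (idx %% genes_per_chrom) * spacing
  strand <- rep_len(c("+", "-"), n_genes)
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = chrom, strand = strand,
    tss = pos,
    tes = as.integer(pos + ifelse(strand == "+", 4000L, -4000L))
  )
  withr::with_seed(derive_seed(seed, "truth"), {
    pool <- sample(genes$gene_id)
    take <- function(n) {
      out <- utils::head(pool, n)
      pool <<- utils::tail(pool, length(pool) - n)
      out
    }
    nfr_loss <- take(n_nfr_loss)
    nfr_gain <- take(n_nfr_gain)
    shift_genes <- take(n_shifts)
    # magnitudes stay strictly below half the 200-bp array spacing so the
    # shifted nucleosome remains the mutual nearest neighbour of its origin
    # (at exactly spacing/2 it is equidistant from the next array position
    # and the planted pair is no longer identifiable)
    shifts <- tibble::tibble(
      gene_id = shift_genes,
      shift = sample(10:99, n_shifts, replace = TRUE)
    )
    pair_states <- c("a_only", "b_only", "both", "none")
    base_state <- sample(pair_states, n_genes, replace = TRUE,
                         prob = c(0.5, 0.1, 0.1, 0.3))
    promoters <- tibble::tibble(gene_id = genes$gene_id,
                                state_ctrl = base_state,
                                state_kd = base_state)
    switch_genes <- sample(genes$gene_id, n_promoter_switches)
    for (g in switch_genes) {
      i <- match(g, promoters$gene_id)
      promoters$state_kd[i] <- sample(setdiff(pair_states,
                                              promoters$state_ctrl[i]), 1)
    }
    enh_states <- c("active", "intermediate", "poised", "primed", "off")
    n_enh <- n_genes
    base_enh <- sample(enh_states, n_enh, replace = TRUE,
                       prob = c(0.3, 0.1, 0.1, 0.3, 0.2))
    enhancers <- tibble::tibble(
      enhancer_id = sprintf("e%04d", seq_len(n_enh)),
      gene_id = genes$gene_id,
      chrom = genes$chrom,
      center = genes$tss + 8100L,
      state_ctrl = base_enh,
      state_kd = base_enh,
      width_ctrl = 1000L,
      width_kd = 1000L
    )
    enh_switch <- sample(enhancers$enhancer_id, n_enhancer_switches)
    for (e in enh_switch) {
      i <- match(e, enhancers$enhancer_id)
      enhancers$state_kd[i] <- sample(setdiff(enh_states,
                                              enhancers$state_ctrl[i]), 1)
    }
    # width changes need an H3K4me1 peak in both conditions
    on_both <- enhancers$enhancer_id[enhancers$state_ctrl != "off" &
                                       enhancers$state_kd != "off"]
    wide <- sample(on_both, min(n_broader + n_shorter, length(on_both)))
    broader <- utils::head(wide, n_broader)
    shorter <- utils::tail(wide, length(wide) - n_broader)
    enhancers$width_kd[enhancers$enhancer_id %in% broader] <- 2000L
    enhancers$width_kd[enhancers$enhancer_id %in% shorter] <- 500L
    mycn_genes <- sample(genes$gene_id, round(mycn_frac * n_genes))
    mycn_enh <- sample(enhancers$enhancer_id, round(mycn_frac * n_enh))
  })
  structure(list(
    chrom_sizes = chrom_sizes, genes = genes, promoters = promoters,
    enhancers = enhancers,
    planted_nfr_loss = nfr_loss, planted_nfr_gain = nfr_gain,
    planted_shifts = shifts,
    planted_promoter_switches = switch_genes,
    planted_enhancer_switches = enh_switch,
    planted_broader = broader, planted_shorter = shorter,
    mycn_genes = mycn_genes, mycn_enhancers = mycn_enh,
    seed = seed
  ), class = "chromdyn_truth")
}

# Deterministic per-stream seed below 2^31, derived from master seed + tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' @export
print.chromdyn_truth <- function(x, ...) {
  cat("chromdyn synthetic truth (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", nrow(x$chrom_sizes), " chrom(s), ",
      sum(x$chrom_sizes$size), " bp; ", nrow(x$genes), " genes, ",
      nrow(x$enhancers), " enhancers\n", sep = "")
  cat("  planted: ", length(x$planted_nfr_loss), " NFR losses, ",
      length(x$planted_nfr_gain), " NFR gains, ",
      nrow(x$planted_shifts), " shifts, ",
      length(x$planted_promoter_switches), " promoter switches, ",
      length(x$planted_enhancer_switches), " enhancer switches\n", sep = "")
  invisible(x)
}

# Base nucleosome layout for one gene: phased array around the TSS with an
# open NFR (-1 at -300, +1 at +150, then 200-bp spacing, strand-aware).
gene_nucleosome_layout <- function(gene) {
  s <- if (gene$strand == "+") 1L else -1L
  offsets <- c(-700L, -500L, -300L, 150L, 350L, 550L, 750L, 950L)
  tibble::tibble(
    gene_id = gene$gene_id,
    chrom = gene$chrom,
    dyad = gene$tss + s * offsets,
    slot = c("m3", "m2", "m1", "p1", "p2", "p3", "p4", "p5")
  )
}

#' Generate two-condition MNase fragment sets with planted events
#'
#' Places a phased nucleosome array (-3..-1, open NFR, +1..+5) around every
#' TSS and draws, per nucleosome, a Poisson(`lambda`) number of 147-bp
#' fragments centred on normally jittered dyads (sd `jitter_sd`). The
#' treated condition reuses the control condition's fragments and applies
#' only the planted edits: NFR-loss genes gain a nucleosome in the NFR
#' window (dyad 75 bp upstream of the TSS, footprint overlap 147 bp >= the
#' 118-bp occupancy rule), NFR-gain genes carry that NFR nucleosome in the
#' control only, and planted shifts displace the +3 nucleosome's fragments
#' by the recorded amount. With zero planted events the two conditions are
#' therefore identical and every downstream call is `fixed`.
#'
#' @param truth A `chromdyn_truth` object.
#' @param lambda Mean fragments per nucleosome (Poisson); must be >= 1, and
#'   >= 6 is recommended so true nucleosomes survive the read-count filter.
#' @param jitter_sd Dyad jitter sd in bp.
#' @param replicate Replicate tag (own RNG stream per replicate).
#' @return List with `ctrl` and `kd` fragment tibbles (`chrom`, `start`,
#'   `end`).
#' @export
generate_nucleosome_reads <- function(truth, lambda = 20, jitter_sd = 5,
                                      replicate = 1) {
  if (lambda < 1) stop("lambda < 1 gives degenerate coverage")
  genes <- truth$genes
  layout <- dplyr::bind_rows(lapply(seq_len(nrow(genes)), function(i) {
    gene_nucleosome_layout(genes[i, ])
  }))
  # NFR nucleosome slot: present in ctrl for planted gains, in kd for losses
  nfr_nuc <- function(ids) {
    g <- genes[match(ids, genes$gene_id), ]
    s <- ifelse(g$strand == "+", 1L, -1L)
    tibble::tibble(gene_id = g$gene_id, chrom = g$chrom,
                   dyad = g$tss - s * 75L, slot = "nfr")
  }
  draw <- function(nucs, stream) {
    withr::with_seed(derive_seed(truth$seed, stream), {
      counts <- stats::rpois(nrow(nucs), lambda)
      dyads <- rep(nucs$dyad, counts) +
        as.integer(round(stats::rnorm(sum(counts), 0, jitter_sd)))
      tibble::tibble(
        gene_id = rep(nucs$gene_id, counts),
        slot = rep(nucs$slot, counts),
        chrom = rep(nucs$chrom, counts),
        start = dyads - 73L,
        end = dyads + 74L
      )
    })
  }
  base <- draw(layout, paste0("mnase_base_rep", replicate))
  gain_reads <- draw(nfr_nuc(truth$planted_nfr_gain),
                     paste0("mnase_gain_rep", replicate))
  loss_reads <- draw(nfr_nuc(truth$planted_nfr_loss),
                     paste0("mnase_loss_rep", replicate))
  ctrl <- dplyr::bind_rows(base, gain_reads)
  kd <- dplyr::bind_rows(base, loss_reads)
  # planted shifts displace the +3 nucleosome's fragments in the kd sample
  sh <- truth$planted_shifts
  if (nrow(sh) > 0) {
    i <- match(kd$gene_id, sh$gene_id)
    hit <- !is.na(i) & kd$slot == "p3"
    strand <- genes$strand[match(kd$gene_id, genes$gene_id)]
    delta <- ifelse(hit, sh$shift[i] * ifelse(strand == "+", 1L, -1L), 0L)
    delta[is.na(delta)] <- 0L
    kd$start <- kd$start + delta
    kd$end <- kd$end + delta
  }
  keep <- c("chrom", "start", "end")
  list(ctrl = ctrl[order(ctrl$chrom, ctrl$start), keep],
       kd = kd[order(kd$chrom, kd$start), keep])
}

# Mark footprints (bin-aligned intervals) for one condition, per mark.
mark_footprints <- function(truth, condition) {
  g <- truth$genes
  pstate <- if (condition == "ctrl") truth$promoters$state_ctrl else truth$promoters$state_kd
  prom <- tibble::tibble(chrom = g$chrom, start = g$tss - 800L,
                         end = g$tss + 800L, state = pstate)
  e <- truth$enhancers
  estate <- if (condition == "ctrl") e$state_ctrl else e$state_kd
  ewidth <- if (condition == "ctrl") e$width_ctrl else e$width_kd
  enh <- tibble::tibble(chrom = e$chrom,
                        start = bin_floor(e$center - ewidth %/% 2L),
                        end = bin_floor(e$center + ewidth %/% 2L),
                        state = estate)
  list(
    H3K9ac = prom[prom$state %in% c("a_only", "both"), 1:3],
    H3K4me3 = prom[prom$state %in% c("a_only", "both"), 1:3],
    H3K27me3 = dplyr::bind_rows(
      prom[prom$state %in% c("b_only", "both"), 1:3],
      enh[enh$state %in% c("poised", "intermediate"), 1:3]
    ),
    H3K27ac = enh[enh$state %in% c("active", "intermediate"), 1:3],
    H3K4me1 = enh[enh$state != "off", 1:3]
  )
}

bin_floor <- function(x, bin = 200L) as.integer((x %/% bin) * bin)

#' Generate two-condition histone-mark midpoint tracks with planted states
#'
#' Draws per-200-bp-bin read counts at `background_rate` genome-wide and at
#' `enriched_rate` inside each mark's footprints (promoter footprints
#' follow the planted H3K9ac/H3K27me3 promoter states; enhancer footprints
#' follow the planted enhancer activity states), then lays the counted
#' midpoints out within each bin. The treated condition reuses the control
#' condition's background draws and redraws only bins whose rate changed,
#' so planted switches are the only systematic difference. An IgG control
#' track (background everywhere) is generated per condition, and H3K4me1
#' peak intervals are emitted directly per condition (standing in for peak
#' caller output), with widths following the planted width changes and a
#' synthetic peak score.
#'
#' @param truth A `chromdyn_truth` object.
#' @param background_rate,enriched_rate Mean reads per 200-bp bin outside /
#'   inside footprints; enriched must exceed background.
#' @param bin Bin width in bp.
#' @return List with `tracks` (named list: per mark, list of `ctrl`/`kd`
#'   midpoint tibbles), `igg` (list of `ctrl`/`kd`), and `peaks` (list of
#'   `ctrl`/`kd` scored H3K4me1 peak tibbles).
#' @export
generate_mark_tracks <- function(truth, background_rate = 2,
                                 enriched_rate = 20, bin = 200) {
  if (background_rate <= 0 || enriched_rate <= 0) {
    stop("rates must be positive")
  }
  if (enriched_rate <= background_rate) {
    stop("enriched_rate must exceed background_rate")
  }
  grid <- truth$chrom_sizes |>
    dplyr::rowwise() |>
    dplyr::reframe(chrom = .data$chrom,
                   start = seq(0L, .data$size - 1L, by = bin)) |>
    dplyr::mutate(end = .data$start + bin)
  rate_vec <- function(fp) {
    r <- rep(background_rate, nrow(grid))
    if (nrow(fp) > 0) {
      for (k in seq_len(nrow(fp))) {
        hit <- grid$chrom == fp$chrom[k] & grid$start >= fp$start[k] &
          grid$start < fp$end[k]
        r[hit] <- enriched_rate
      }
    }
    r
  }
  fp_ctrl <- mark_footprints(truth, "ctrl")
  fp_kd <- mark_footprints(truth, "kd")
  counts_to_midpoints <- function(counts) {
    pos <- lapply(which(counts > 0), function(i) {
      k <- counts[i]
      grid$start[i] + as.integer(round((seq_len(k) - 0.5) / k * bin))
    })
    tibble::tibble(
      chrom = rep(grid$chrom[counts > 0], counts[counts > 0]),
      pos = unlist(pos, use.names = FALSE)
    )
  }
  marks <- names(fp_ctrl)
  tracks <- lapply(marks, function(m) {
    r_ctrl <- rate_vec(fp_ctrl[[m]])
    r_kd <- rate_vec(fp_kd[[m]])
    withr::with_seed(derive_seed(truth$seed, paste0("mark_", m)), {
      c_ctrl <- stats::rpois(nrow(grid), r_ctrl)
      c_kd <- c_ctrl
      changed <- which(r_kd != r_ctrl)
      c_kd[changed] <- stats::rpois(length(changed), r_kd[changed])
    })
    list(ctrl = counts_to_midpoints(c_ctrl), kd = counts_to_midpoints(c_kd))
  })
  names(tracks) <- marks
  igg <- withr::with_seed(derive_seed(truth$seed, "mark_IgG"), {
    c1 <- stats::rpois(nrow(grid), background_rate)
    c2 <- stats::rpois(nrow(grid), background_rate)
    list(ctrl = counts_to_midpoints(c1), kd = counts_to_midpoints(c2))
  })
  peaks <- lapply(c(ctrl = "ctrl", kd = "kd"), function(cond) {
    e <- truth$enhancers
    state <- if (cond == "ctrl") e$state_ctrl else e$state_kd
    width <- if (cond == "ctrl") e$width_ctrl else e$width_kd
    on <- state != "off"
    sc <- withr::with_seed(derive_seed(truth$seed, paste0("peakscore_", cond)),
                           stats::runif(nrow(e), 1, 100))
    tibble::tibble(
      chrom = e$chrom[on],
      start = bin_floor(e$center[on] - width[on] %/% 2L),
      end = bin_floor(e$center[on] + width[on] %/% 2L),
      name = e$enhancer_id[on],
      score = round(sc[on], 2)
    )
  })
  list(tracks = tracks, igg = igg, peaks = peaks)
}

#' Generate MYCN-style binding peaks for the planted bound subsets
#'
#' Emits one 400-bp peak at each MYCN-bound promoter TSS and each
#' MYCN-bound enhancer centre.
#'
#' @param truth A `chromdyn_truth` object.
#' @return Scored peak tibble.
#' @export
generate_binding_peaks <- function(truth) {
  g <- truth$genes[truth$genes$gene_id %in% truth$mycn_genes, ]
  e <- truth$enhancers[truth$enhancers$enhancer_id %in% truth$mycn_enhancers, ]
  out <- dplyr::bind_rows(
    tibble::tibble(chrom = g$chrom, start = g$tss - 200L, end = g$tss + 200L,
                   name = g$gene_id),
    tibble::tibble(chrom = e$chrom, start = e$center - 200L,
                   end = e$center + 200L, name = e$enhancer_id)
  )
  out$score <- 10
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Generate paired promoter/enhancer state-change labels
#'
#' Simulates `n_pairs` enhancer-promoter pairs whose two binary
#' state-change labels have the given marginal probabilities and a
#' dependence set by an odds multiplier: with `multiplier = 1` the labels
#' are exactly independent (the null model under which chi-square p-values
#' are Uniform(0,1)); larger multipliers induce positive association.
#'
#' @param n_pairs Number of pairs (> 0).
#' @param p_promoter_change,p_enhancer_change Marginal probabilities, in
#'   (0,1), of the first label value.
#' @param multiplier Odds ratio between the two labels.
#' @param seed RNG seed.
#' @return Tibble with factors `promoter` and `enhancer`, each with levels
#'   `active_to_nonactive` / `nonactive_to_active`.
#' @export
generate_contingency_world <- function(n_pairs, p_promoter_change = 0.4,
                                       p_enhancer_change = 0.4,
                                       multiplier = 1, seed = 1) {
  if (n_pairs <= 0) stop("n_pairs must be positive")
  stopifnot(p_promoter_change > 0, p_promoter_change < 1,
            p_enhancer_change > 0, p_enhancer_change < 1, multiplier > 0)
  p <- joint_cell_probs(p_promoter_change, p_enhancer_change, multiplier)
  counts <- withr::with_seed(seed, as.integer(stats::rmultinom(1, n_pairs, p)))
  lv <- c("active_to_nonactive", "nonactive_to_active")
  cells <- expand.grid(promoter = lv, enhancer = lv,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::tibble(
    promoter = factor(rep(cells$promoter, counts), levels = lv),
    enhancer = factor(rep(cells$enhancer, counts), levels = lv)
  )
}

# Joint cell probabilities (p11, p21, p12, p22 in column-major order of a
# 2x2 with rows = promoter label, cols = enhancer label) with given
# marginals and odds ratio theta.
joint_cell_probs <- function(p1, p2, theta) {
  if (theta == 1) {
    p11 <- p1 * p2
  } else {
    s <- 1 + (p1 + p2) * (theta - 1)
    p11 <- (s - sqrt(s^2 - 4 * theta * (theta - 1) * p1 * p2)) /
      (2 * (theta - 1))
  }
  c(p11, p2 - p11, p1 - p11, 1 - p1 - p2 + p11)
}

#' Rejection rate of the independence test over simulated worlds
#'
#' Draws `n_tables` contingency worlds of `n_pairs` pairs each from
#' [generate_contingency_world()]'s model and reports the fraction of
#' Pearson chi-square p-values at or below `alpha`. With `multiplier = 1`
#' this is the empirical type-I error; with `multiplier > 1` it is power.
#' Tables with a zero marginal (where the test is undefined) are counted as
#' non-rejections.
#'
#' @param n_tables Number of simulated tables.
#' @param n_pairs Pairs per table.
#' @param p_promoter_change,p_enhancer_change,multiplier Model parameters.
#' @param alpha Significance level.
#' @param seed RNG seed.
#' @return The rejection rate (numeric scalar).
#' @export
contingency_rejection_rate <- function(n_tables, n_pairs,
                                       p_promoter_change = 0.4,
                                       p_enhancer_change = 0.4,
                                       multiplier = 1, alpha = 0.05,
                                       seed = 1) {
  p <- joint_cell_probs(p_promoter_change, p_enhancer_change, multiplier)
  counts <- withr::with_seed(seed, stats::rmultinom(n_tables, n_pairs, p))
  storage.mode(counts) <- "double"
  a <- counts[1, ]; b <- counts[3, ]; c <- counts[2, ]; d <- counts[4, ]
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ok <- den > 0
  chi2 <- rep(NA_real_, n_tables)
  chi2[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2 / den[ok]
  pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  mean(!is.na(pv) & pv <= alpha)
}
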