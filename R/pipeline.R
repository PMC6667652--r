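#' Pipeline configuration with the standard parameter set
#'
#' Collects every tunable constant of the pipeline with its conventional
#' default: Gaussian smoothing sd and exclusion zone for nucleosome
#' calling, the read-count filter (rc >= 6), the NFR window (-200..+50
#' around the TSS) and its 118-bp occupancy overlap (80% of a 147-bp
#' nucleosome), the promoter window (-2000..+1000), the shift band
#' (1 <= d < 117 bp), the 200-bp binarization grid and its Poisson
#' threshold, the 50%-of-shorter peak merge rule, the 1.5-fold width-change
#' threshold, the 50-kb target-gene and 100-kb association distances, the
#' 2-kb TSS exclusion, and K = 5 for occupancy clustering.
#'
#' @param ... Overrides for any default.
#' @return A named list of parameters (class `chromdyn_config`).
#' @export
chromdyn_config <- function(...) {
  cfg <- list(
    sigma = 20, exclusion = 147, min_rc = 6,
    nfr_upstream = 200, nfr_downstream = 50, nfr_overlap = 118,
    promoter_upstream = 2000, promoter_downstream = 1000,
    shift_min = 1, shift_max = 117,
    bin = 200, p_threshold = 1e-4,
    peak_overlap_frac = 0.5, width_fold = 1.5,
    target_dist = 50000, assoc_dist = 100000, tss_excl = 2000,
    kmeans_k = 5, seed = 1,
    lambda = 20, jitter_sd = 5,
    background_rate = 2, enriched_rate = 20
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "chromdyn_config")
}

#' Run the full two-condition chromatin-dynamics pipeline
#'
#' Orchestrates simulate (optional) -> dyad indexing and nucleosome calling
#' per condition -> dynamics classification and NFR calls -> mark
#' binarization and state segmentation -> promoter states and transitions
#' -> enhancer merge, states, width classes and binding -> enhancer to
#' promoter association and the 2x2 independence tests. Stages communicate
#' through files written under `outdir` in documented TSV/BED formats, so
#' any stage can be re-run or substituted with real-data exports; the
#' configuration (including the seed) is serialized alongside the outputs.
#'
#' @param config A [chromdyn_config()].
#' @param outdir Output directory (created if needed).
#' @param truth Optional `chromdyn_truth`; by default one is simulated from
#'   `config$seed`.
#' @return Invisibly, a list of the in-memory stage results (`truth`,
#'   `nucleosomes`, `dynamics`, `nfr`, `promoter_states`, `transitions`,
#'   `enhancers`, `pairs`, `tests`), with `outdir` attached.
#' @export
run_pipeline <- function(config = chromdyn_config(), outdir, truth = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"))
  if (is.null(truth)) {
    logf("simulating synthetic genome (seed %d)", config$seed)
    truth <- simulate_truth(seed = config$seed)
  }
  genes <- truth$genes
  readr::write_tsv(genes, file.path(outdir, "genes.tsv"), progress = FALSE)

  logf("generating MNase fragments (lambda=%g, jitter=%g)",
       config$lambda, config$jitter_sd)
  frags <- generate_nucleosome_reads(truth, lambda = config$lambda,
                                     jitter_sd = config$jitter_sd)
  nucs <- lapply(frags, function(fr) {
    call_nucleosomes(build_dyad_index(fr), sigma = config$sigma,
                     exclusion = config$exclusion, min_rc = config$min_rc)
  })
  for (cond in names(nucs)) {
    readr::write_tsv(nucs[[cond]],
                     file.path(outdir, paste0("nucleosomes_", cond, ".tsv")),
                     progress = FALSE)
  }
  logf("called %d (ctrl) / %d (kd) nucleosomes",
       nrow(nucs$ctrl), nrow(nucs$kd))

  dyn <- pair_nucleosomes(nucs$ctrl, nucs$kd, shift_min = config$shift_min,
                          shift_max = config$shift_max)
  readr::write_tsv(dyn, file.path(outdir, "dynamics.tsv"), progress = FALSE)
  nfr <- call_nfr_status(genes, nucs$ctrl, nucs$kd,
                         upstream = config$nfr_upstream,
                         downstream = config$nfr_downstream,
                         min_overlap = config$nfr_overlap)
  readr::write_tsv(nfr, file.path(outdir, "nfr_status.tsv"), progress = FALSE)
  logf("dynamics: %s", paste(names(table(dyn$category)),
                             table(dyn$category), sep = "=", collapse = " "))

  logf("generating mark tracks and binarizing (%d-bp bins)", config$bin)
  mk <- generate_mark_tracks(truth, background_rate = config$background_rate,
                             enriched_rate = config$enriched_rate,
                             bin = config$bin)
  conds <- c("ctrl", "kd")
  segments_prom <- lapply(conds, function(cond) {
    a <- binarize(mk$tracks$H3K9ac[[cond]], mk$igg[[cond]], truth$chrom_sizes,
                  bin = config$bin, p_threshold = config$p_threshold)
    b <- binarize(mk$tracks$H3K27me3[[cond]], mk$igg[[cond]], truth$chrom_sizes,
                  bin = config$bin, p_threshold = config$p_threshold)
    segment_mark_pair(a, b, marks = c("H3K9ac", "H3K27me3"))
  })
  names(segments_prom) <- conds
  segments_enh <- lapply(conds, function(cond) {
    a <- binarize(mk$tracks$H3K27ac[[cond]], mk$igg[[cond]], truth$chrom_sizes,
                  bin = config$bin, p_threshold = config$p_threshold)
    b <- binarize(mk$tracks$H3K27me3[[cond]], mk$igg[[cond]], truth$chrom_sizes,
                  bin = config$bin, p_threshold = config$p_threshold)
    segment_mark_pair(a, b, marks = c("H3K27ac", "H3K27me3"))
  })
  names(segments_enh) <- conds
  for (cond in conds) {
    seg <- segments_prom[[cond]]
    seg$name <- as.character(seg$state)
    write_bed(seg, file.path(outdir, paste0("segments_K9ac_K27me3_", cond, ".bed")))
  }

  prom_states <- lapply(conds, function(cond) {
    assign_promoter_state(genes, segments_prom[[cond]],
                          upstream = config$promoter_upstream,
                          downstream = config$promoter_downstream)
  })
  names(prom_states) <- conds
  trans <- promoter_transition_table(prom_states$ctrl, prom_states$kd)
  readr::write_tsv(trans, file.path(outdir, "promoter_transitions.tsv"),
                   progress = FALSE)

  logf("merging enhancer peaks and assigning states")
  peaks <- lapply(mk$peaks, filter_tss_proximal, genes = genes,
                  excl = config$tss_excl)
  enh <- merge_enhancers(peaks$ctrl, peaks$kd,
                         min_frac = config$peak_overlap_frac)
  enh$state_ctrl <- assign_enhancer_state(enh, segments_enh$ctrl, "ctrl")
  enh$state_kd <- assign_enhancer_state(enh, segments_enh$kd, "kd")
  enh$width_class <- classify_width_change(enh, fold = config$width_fold)
  mycn <- generate_binding_peaks(truth)
  enh$mycn_bound <- annotate_binding(enh, mycn)
  enh$target_gene <- enhancer_target_gene(enh, genes,
                                          max_dist = config$target_dist)
  readr::write_tsv(enh, file.path(outdir, "enhancers.tsv"), progress = FALSE)

  logf("associating enhancers with promoters (within %d bp)",
       config$assoc_dist)
  pairs <- associate_enhancer_promoter(enh, genes,
                                       max_dist = config$assoc_dist)
  pairs$prom_ctrl <- prom_states$ctrl$state[match(pairs$gene_id,
                                                  prom_states$ctrl$gene_id)]
  pairs$prom_kd <- prom_states$kd$state[match(pairs$gene_id,
                                              prom_states$kd$gene_id)]
  tests <- independence_tests(pairs)
  if (nrow(tests) > 0) {
    readr::write_tsv(tests, file.path(outdir, "independence_tests.tsv"),
                     progress = FALSE)
  }
  logf("done; outputs in %s", outdir)
  out <- list(truth = truth, nucleosomes = nucs, dynamics = dyn, nfr = nfr,
              segments_promoter = segments_prom, segments_enhancer = segments_enh,
              promoter_states = prom_states, transitions = trans,
              enhancers = enh, pairs = pairs, tests = tests)
  attr(out, "outdir") <- outdir
  invisible(out)
}

# Promoter/enhancer change classifiers over associated pairs, and the
# resulting 2x2 chi-square tests (rows mirroring the published layout).
independence_tests <- function(pairs) {
  prom_change <- dplyr::case_when(
    collapse_active(pairs$prom_ctrl) == "active" &
      collapse_active(pairs$prom_kd) == "non_active" ~ "prom active -> non-active",
    collapse_active(pairs$prom_ctrl) == "non_active" &
      collapse_active(pairs$prom_kd) == "active" ~ "prom non-active -> active",
    TRUE ~ NA_character_
  )
  enh_active <- function(s) s %in% c("active", "intermediate")
  classifiers <- list(
    enhancer_onoff = dplyr::case_when(
      pairs$state_ctrl == "off" & pairs$state_kd == "primed" ~ "enh off -> primed",
      pairs$state_ctrl == "primed" & pairs$state_kd == "off" ~ "enh primed -> off",
      TRUE ~ NA_character_
    ),
    enhancer_activity = dplyr::case_when(
      !enh_active(pairs$state_ctrl) & enh_active(pairs$state_kd) ~
        "enh non-active -> active",
      enh_active(pairs$state_ctrl) & !enh_active(pairs$state_kd) ~
        "enh active -> non-active",
      TRUE ~ NA_character_
    ),
    enhancer_width = dplyr::case_when(
      pairs$width_class == "broader" ~ "enh narrow -> wide",
      pairs$width_class == "shorter" ~ "enh wide -> narrow",
      TRUE ~ NA_character_
    )
  )
  res <- lapply(names(classifiers), function(nm) {
    tab <- try(build_contingency(pairs, classifiers[[nm]], prom_change),
               silent = TRUE)
    if (inherits(tab, "try-error") || !all(dim(tab) == c(2, 2)) ||
        any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(NULL)
    }
    ht <- chi_square_2x2(tab)
    tibble::tibble(comparison = nm,
                   cell_11 = tab[1, 1], cell_12 = tab[1, 2],
                   cell_21 = tab[2, 1], cell_22 = tab[2, 2],
                   statistic = ht$statistic, p.value = ht$p.value)
  })
  dplyr::bind_rows(res)
}
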