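#' Plot a promoter state-transition table
#'
#' Tile plot of the 4x4 transition counts between conditions, the numeric
#' equivalent of the alluvial display of promoter histone-modification
#' dynamics.
#'
#' @param transitions Tibble from [promoter_transition_table()].
#' @return A ggplot object.
#' @export
plot_transition_table <- function(transitions) {
  ggplot2::ggplot(transitions,
                  ggplot2::aes(x = .data$state_kd, y = .data$state_ctrl,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "state after", y = "state before", fill = "genes") +
    ggplot2::theme_minimal()
}

#' Heat map of an occupancy matrix with cluster annotation
#'
#' @param object A `chromdyn_occupancy` from [occupancy_matrix()].
#' @param ... Unused.
#' @return A ggplot object: rows (regions, ordered by cluster) by position
#'   relative to the region midpoint.
#' @method autoplot chromdyn_occupancy
#' @export
autoplot.chromdyn_occupancy <- function(object, ...) {
  ord <- order(object$cluster)
  m <- object$matrix[ord, , drop = FALSE]
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  df$pos <- (df$col - ncol(m) / 2 - 0.5) * object$bin
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::labs(x = "position relative to region midpoint (bp)",
                  y = "region (by cluster)", fill = "occupancy") +
    ggplot2::theme_minimal()
}

#' Bar plot of nucleosome dynamics categories
#'
#' @param dynamics Tibble from [pair_nucleosomes()].
#' @return A ggplot object.
#' @export
plot_dynamics_summary <- function(dynamics) {
  counts <- dplyr::count(dynamics, .data$category)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n,
                                       fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "nucleosomes") +
    ggplot2::theme_minimal()
}
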