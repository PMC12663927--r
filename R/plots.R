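#' Plot methods for result tables
#'
#' `autoplot()` methods turning the package's result tibbles into
#' ggplot2 figures: the diversity-coverage curve, the cross-validation
#' error against the identity threshold, the per-position association
#' scores, and the rate-ratio landscape against identity.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name rubiscope-plots
NULL

#' @rdname rubiscope-plots
#' @method autoplot coverage_curve
#' @export
autoplot.coverage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold, .data$coverage)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "identity threshold X",
      y = "fraction of representatives covered",
      title = sprintf("Diversity coverage (%d representatives, %d characterized)",
                      attr(object, "n_representatives"),
                      attr(object, "n_characterized"))
    )
}

#' @rdname rubiscope-plots
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$threshold, .data$rmse_ln,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_evaluable)) +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(x = "training-set identity threshold X",
                  y = "RMSE (ln rate)", size = "evaluable",
                  title = "Identity-thresholded leave-one-out error")
}

#' @rdname rubiscope-plots
#' @param top_n Label the `top_n` highest-scoring positions.
#' @method autoplot position_association
#' @export
autoplot.position_association <- function(object, top_n = 3, ...) {
  lab <- dplyr::slice_min(object, .data$rank, n = top_n, with_ties = FALSE)
  lab$label <- ifelse(is.na(lab$ref_residue), paste0("col ", lab$column),
                      paste0("pos ", lab$ref_residue))
  ggplot2::ggplot(object, ggplot2::aes(.data$column, .data$score)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$column, yend = 0)) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "alignment column",
                  y = "mean |Shapley attribution| (ln rate)",
                  title = "Position association with carboxylation rate")
}

#' @rdname rubiscope-plots
#' @method autoplot ratio_by_identity
#' @export
autoplot.ratio_by_identity <- function(object, ...) {
  pairs <- attr(object, "pairs")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes((.data$bin_low + .data$bin_high) / 2,
                                    .data$median_ratio))
  if (!is.null(pairs)) {
    p <- p + ggplot2::geom_point(
      data = pairs, ggplot2::aes(.data$identity, .data$ratio),
      alpha = 0.2, inherit.aes = FALSE)
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(colour = "firebrick", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pairwise identity", y = "rate ratio (max/min)",
                  title = "Rate-ratio landscape vs sequence identity")
}
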