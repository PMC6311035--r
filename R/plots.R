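#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot expression trajectories
#'
#' @param object An [expr_ts].
#' @param ... Unused.
#' @return A ggplot: expression against time, coloured by gene, one facet
#'   per replicate series.
#' @method autoplot expr_ts
#' @export
autoplot.expr_ts <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$expression,
                               colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$series)) +
    ggplot2::labs(x = "time", y = "expression", colour = "gene") +
    ggplot2::theme_minimal()
}

#' Plot an ROC step curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of the merged-threshold ROC with the AUC in the title.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot edge entry values along the penalty path
#'
#' @param object A `lagged_path`.
#' @param ... Unused.
#' @return A ggplot: one point per candidate edge at its entry penalty
#'   (log scale); never-entering pairs are omitted.
#' @method autoplot lagged_path
#' @export
autoplot.lagged_path <- function(object, ...) {
  d <- dplyr::filter(object$entries, !is.na(.data$entry_lambda))
  d$edge <- stats::reorder(paste0(d$source, " → ", d$target),
                           d$entry_lambda)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$entry_lambda, y = .data$edge)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "entry λ", y = NULL,
                  title = paste("edge entry order,", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot an AUC experiment grid
#'
#' @param results The tibble returned by [experiment_grid()].
#' @return A ggplot: AUC against series length, one line per method,
#'   faceted by sampling interval and maximum lag.
#' @export
plot_experiment_grid <- function(results) {
  d <- dplyr::filter(results, !results$skipped)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_end, y = .data$auc,
                                  colour = .data$method,
                                  shape = factor(.data$l_max))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = interaction(
      .data$method, .data$l_max))) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$dt), labeller = "label_both") +
    ggplot2::labs(x = "series length T", y = "AUC", shape = "l_max") +
    ggplot2::theme_minimal()
}
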