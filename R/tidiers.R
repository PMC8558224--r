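#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-sample predictions of a cross-validated SVM
#'
#' @param x An `mwl_svm_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per sample: fold, truth, prediction, decision
#'   score.
#' @export
tidy.mwl_svm_cv <- function(x, ...) {
  x$predictions
}

#' One-row performance summary of a cross-validated SVM
#'
#' @param x An `mwl_svm_cv` object.
#' @param ... Unused.
#' @return One-row tibble: accuracy, sensitivity, specificity, auc (rates in
#'   percent), kernel scale, cost, folds, n.
#' @export
glance.mwl_svm_cv <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(kernel_scale = x$kernel_scale, cost = x$cost,
                   folds = x$folds, n = x$n)
  )
}

#' Tidy the per-partition classification summary
#'
#' @param x An `mwl_classification` object.
#' @param ... Unused.
#' @return Tibble with one row per partition condition.
#' @export
tidy.mwl_classification <- function(x, ...) {
  x$summary
}

#' ROC curve of a cross-validated SVM
#'
#' @param object An `mwl_svm_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mwl_svm_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC, AUC = %.2f", object$metrics$auc)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curves per partition condition
#'
#' @param object An `mwl_classification` object.
#' @param ... Unused.
#' @return A ggplot with one curve per partition.
#' @export
autoplot.mwl_classification <- function(object, ...) {
  roc <- dplyr::bind_rows(lapply(object$fits, function(f) f$roc),
                          .id = "partition")
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' Butterfly plot of an averaged ERP
#'
#' @param object An `eeg_erp`.
#' @param electrodes Channels to draw; defaults to all.
#' @param ... Unused.
#' @return A ggplot of amplitude against time, one line per channel.
#' @export
autoplot.eeg_erp <- function(object, electrodes = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(electrodes)) df <- df[df$channel %in% electrodes, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$amplitude,
                                   colour = .data$channel)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::labs(x = "Time (ms)", y = expression("Amplitude (" * mu * "V)"),
                  title = sprintf("%s (%d epochs)", object$partition,
                                  object$n_epochs)) +
    ggplot2::theme_minimal()
}

#' Forest plot of Hedges' g with confidence intervals
#'
#' @param effects An [effect_size_report()] tibble.
#' @return A ggplot faceted by measure, one row per electrode and partition.
#' @export
plot_effect_sizes <- function(effects) {
  ggplot2::ggplot(
    effects,
    ggplot2::aes(x = .data$g, y = .data$electrode, colour = .data$partition)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::labs(x = "Hedges' g (high - low workload)", y = NULL,
                  colour = "Condition") +
    ggplot2::theme_minimal()
}
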