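# ggplot2 / broom-style views of the result objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_step labs
#'   theme_minimal facet_wrap
NULL

#' Plot a recall-vs-uncertainty calibration curve
#'
#' Shows cumulative recall of the revision-required class (solid) and the
#' cumulative population fraction (dashed) against ascending uncertainty.
#'
#' @param object A `cqa_calibration_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cqa_calibration_curve
#' @export
autoplot.cqa_calibration_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble(uncertainty = object$uncertainty,
           `cumulative recall` = object$cum_recall,
           `population fraction` = object$pop_fraction),
    -"uncertainty", names_to = "series", values_to = "value")
  ggplot(df, aes(x = .data$uncertainty, y = .data$value,
                 linetype = .data$series)) +
    geom_step() +
    labs(x = "uncertainty (normalized entropy)", y = NULL,
         title = "Recall vs. uncertainty calibration") +
    theme_minimal()
}

#' Plot binned uncertainty-performance relationship
#'
#' @param object A [binned_performance()] result.
#' @param ... Unused.
#' @return A ggplot of per-bin accuracy and recall against mean bin
#'   uncertainty.
#' @method autoplot cqa_binned
#' @export
autoplot.cqa_binned <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("accuracy", "recall"),
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot(df, aes(x = .data$mean_uncertainty, y = .data$value)) +
    geom_point(aes(size = .data$n), alpha = 0.6) +
    facet_wrap(~metric) +
    labs(x = "mean bin uncertainty", y = NULL,
         title = "Performance vs. uncertainty (binned)") +
    theme_minimal()
}

#' Plot the training log of a QA model
#'
#' @param object A trained `cqa_model`.
#' @param ... Unused.
#' @return A ggplot of loss and validation accuracy per epoch.
#' @method autoplot cqa_model
#' @export
autoplot.cqa_model <- function(object, ...) {
  if (is.null(object$log)) abort("model has no training log yet")
  df <- tidyr::pivot_longer(object$log, c("loss", "val_accuracy"),
                            names_to = "series", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~series, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Training history") +
    theme_minimal()
}

#' Tidy the training log of a QA model
#'
#' @param x A trained `cqa_model`.
#' @param ... Unused.
#' @return The per-epoch log tibble (`epoch`, `lr`, `loss`,
#'   `val_accuracy`).
#' @method tidy cqa_model
#' @export
tidy.cqa_model <- function(x, ...) {
  if (is.null(x$log)) abort("model has no training log yet")
  x$log
}

#' One-row summary of a QA model
#'
#' @param x A `cqa_model`.
#' @param ... Unused.
#' @return A tibble with parameter count, epochs trained, final loss and
#'   best validation accuracy.
#' @method glance cqa_model
#' @export
glance.cqa_model <- function(x, ...) {
  tibble(
    backbone = x$config$backbone,
    n_parameters = length(x$theta),
    n_structures = x$catalogue$K,
    dropout_rate = x$config$dropout_rate,
    epochs = if (is.null(x$log)) 0L else nrow(x$log),
    final_loss = if (is.null(x$log)) NA_real_ else
      x$log$loss[nrow(x$log)],
    best_val_accuracy = if (is.null(x$log)) NA_real_ else
      max(x$log$val_accuracy))
}

#' Tidy a threshold table
#'
#' @param x A `cqa_thresholds`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy cqa_thresholds
#' @export
tidy.cqa_thresholds <- function(x, ...) {
  as_tibble(x)
}
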