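# Recall-vs-uncertainty calibration and the accept/flag decision policy.

#' Build the recall-vs-uncertainty calibration curve
#'
#' Predictions are sorted by ascending uncertainty (ties broken stably by
#' input order) and the cumulative recall of the *revision required* class —
#' the sensitivity within the growing accepted prefix — is computed at every
#' point, together with the cumulative population fraction. Before the first
#' revision-required sample enters the prefix, recall is vacuously 1, so an
#' all-acceptable low-uncertainty head never forces the threshold to zero.
#'
#' @param predictions Tibble with columns `label` (true 0/1),
#'   `predicted_label` and `entropy` (e.g. from [mc_predict()]).
#' @return A `cqa_calibration_curve` tibble with columns `uncertainty`,
#'   `cum_recall`, `pop_fraction`.
#' @export
build_calibration_curve <- function(predictions) {
  n <- nrow(predictions)
  if (n < 1) abort("need at least one prediction")
  if (!any(predictions$label == 1))
    abort("recall is undefined: no revision-required samples present")
  ord <- order(predictions$entropy)  # stable in R
  lab <- predictions$label[ord]
  pred <- predictions$predicted_label[ord]
  tp <- cumsum(lab == 1 & pred == 1)
  pos <- cumsum(lab == 1)
  curve <- tibble(
    uncertainty = predictions$entropy[ord],
    cum_recall = ifelse(pos == 0, 1, tp / pos),
    pop_fraction = seq_len(n) / n
  )
  class(curve) <- c("cqa_calibration_curve", class(curve))
  curve
}

#' Select the uncertainty threshold for a target sensitivity
#'
#' Walks the calibration curve in ascending uncertainty and returns the
#' uncertainty of the first point whose cumulative recall drops below the
#' target. If the curve never drops below the target, the threshold is 1.0
#' (every prediction is auto-accepted). By construction, recall among
#' samples with uncertainty strictly below the returned threshold meets the
#' target on the calibration set itself.
#'
#' @param curve A [build_calibration_curve()] result.
#' @param target_recall Required sensitivity in (0, 1].
#' @return The threshold tau in `[0, 1]`.
#' @export
select_threshold <- function(curve, target_recall = 0.98) {
  if (nrow(curve) < 1) abort("empty calibration curve")
  if (target_recall <= 0 || target_recall > 1)
    abort("target_recall must lie in (0, 1]")
  i <- which(curve$cum_recall < target_recall)
  if (length(i) == 0) return(1.0)
  curve$uncertainty[i[1]]
}

#' Per-structure threshold calibration
#'
#' Builds one calibration curve per structure on validation predictions and
#' selects the uncertainty threshold achieving the target sensitivity,
#' reporting the achieved recall and retained population fraction below
#' each threshold.
#'
#' @param predictions Validation `cqa_predictions` (needs `structure`,
#'   `label`, `predicted_label`, `entropy`).
#' @param target_recall Global sensitivity target (default 0.98).
#' @param overrides Optional named numeric vector of per-structure targets,
#'   e.g. `c(prostate_like = 1.0)` for a treatment target where every
#'   questionable contour must reach a clinician.
#' @return A `cqa_thresholds` tibble: `structure`, `target_recall`, `tau`,
#'   `recall_below_tau`, `population_below_tau`.
#' @export
threshold_table <- function(predictions, target_recall = 0.98,
                            overrides = NULL) {
  structs <- unique(predictions$structure)
  rows <- lapply(structs, function(st) {
    sub <- predictions[predictions$structure == st, ]
    tgt <- if (!is.null(overrides) && st %in% names(overrides))
      unname(overrides[st]) else target_recall
    curve <- build_calibration_curve(sub)
    tau <- select_threshold(curve, tgt)
    acc <- sub[sub$entropy < tau, ]
    pos <- sum(acc$label == 1)
    tibble(structure = st, target_recall = tgt, tau = tau,
           recall_below_tau = if (pos == 0) 1 else
             sum(acc$label == 1 & acc$predicted_label == 1) / pos,
           population_below_tau = nrow(acc) / nrow(sub))
  })
  out <- bind_rows(rows)
  class(out) <- c("cqa_thresholds", class(out))
  out
}

#' Apply the accept/flag decision policy
#'
#' A prediction is auto-accepted when its uncertainty is strictly below the
#' structure's threshold; a prediction whose uncertainty equals or exceeds
#' the threshold is flagged for clinician review.
#'
#' @param predictions A `cqa_predictions` tibble.
#' @param thresholds A [threshold_table()] result covering every structure
#'   present in `predictions`.
#' @return `predictions` with an added `decision` column
#'   (`"auto_accept_prediction"` / `"flag_for_review"`).
#' @export
apply_policy <- function(predictions, thresholds) {
  missing <- setdiff(unique(predictions$structure), thresholds$structure)
  if (length(missing))
    abort(sprintf("no threshold for structure(s): %s",
                  paste(missing, collapse = ", ")))
  out <- left_join(predictions,
                   thresholds[, c("structure", "tau")], by = "structure")
  out$decision <- ifelse(out$entropy < out$tau,
                         "auto_accept_prediction", "flag_for_review")
  out
}

#' Bin predictions by uncertainty and summarise performance
#'
#' Partitions `[0, 1]` into `n_bins` uniform uncertainty bins (default 80)
#' and reports, for every populated bin, the mean uncertainty, mean
#' accuracy, and recall of the revision-required class (absent when a bin
#' holds no revision-required samples). A well-calibrated uncertainty score
#' shows accuracy and recall falling as bin uncertainty rises.
#'
#' @param predictions A `cqa_predictions` tibble.
#' @param n_bins Number of uniform bins (>= 1).
#' @return A `cqa_binned` tibble: `bin`, `mean_uncertainty`, `accuracy`,
#'   `recall`, `n`.
#' @export
binned_performance <- function(predictions, n_bins = 80) {
  if (n_bins < 1) abort("n_bins must be >= 1")
  bin <- pmin(floor(predictions$entropy * n_bins) + 1L, n_bins)
  out <- predictions |>
    mutate(bin = bin) |>
    group_by(bin) |>
    summarise(
      mean_uncertainty = mean(.data$entropy),
      accuracy = mean(.data$predicted_label == .data$label),
      recall = if (any(.data$label == 1))
        sum(.data$label == 1 & .data$predicted_label == 1) / sum(.data$label == 1)
      else NA_real_,
      n = dplyr::n(), .groups = "drop")
  class(out) <- c("cqa_binned", class(out))
  out
}
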