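# Classification metrics (positive class = revision required) and the
# deployment-subset report.

# confusion-matrix metrics plus rank-based AUC for one score vector
binary_metrics <- function(truth, score, threshold = 0.5) {
  pred <- as.integer(score >= threshold)
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  auc <- if (n_pos == 0 || n_neg == 0) {
    warn("AUC undefined: only one class present")
    NA_real_
  } else {
    # Mann-Whitney estimator; midranks give the tie correction
    r <- rank(score, ties.method = "average")
    (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1, auc = auc)
}

#' Classification metrics for QA predictions
#'
#' Computes accuracy, precision, recall, F1 and AUC with *revision required*
#' as the positive class and the fixed quality threshold 0.5. Two modes are
#' provided: `"mean_prob"` scores each sample by its Monte-Carlo mean
#' probability; `"per_pass"` evaluates every stochastic pass separately and
#' reports the mean and standard deviation across the `T` passes.
#'
#' @param predictions A `cqa_predictions` tibble with `label` set.
#' @param mode `"mean_prob"` or `"per_pass"`.
#' @param by_structure Also report per-structure rows (pooled slices are
#'   always reported as structure `"overall"`).
#' @return A tibble with columns `structure`, `metric`, `estimate` and (in
#'   per-pass mode) `sd`.
#' @export
compute_metrics <- function(predictions, mode = c("mean_prob", "per_pass"),
                            by_structure = FALSE) {
  mode <- match.arg(mode)
  groups <- list(overall = predictions)
  if (by_structure)
    groups <- c(groups, split(predictions, predictions$structure))
  rows <- purrr::imap_dfr(groups, function(sub, nm) {
    if (mode == "mean_prob") {
      m <- binary_metrics(sub$label, sub$mean_prob)
      tibble(structure = nm, metric = names(m), estimate = unname(m),
             sd = NA_real_)
    } else {
      passes <- do.call(rbind, sub$per_pass)   # n x T
      per_t <- vapply(seq_len(ncol(passes)), function(t)
        binary_metrics(sub$label, passes[, t]), numeric(5))
      tibble(structure = nm, metric = rownames(per_t),
             estimate = unname(rowMeans(per_t)),
             sd = unname(apply(per_t, 1, stats::sd)))
    }
  })
  rows
}

#' Performance on the auto-accepted subset
#'
#' Restricts evaluation to predictions the policy auto-accepted and reports,
#' per structure and overall: accuracy, recall of the revision-required
#' class, and the auto-accepted population fraction. Structures whose
#' auto-accepted subset is empty report absent metrics with a warning.
#'
#' @param decisions Output of [apply_policy()] (predictions + `decision`).
#' @return A tibble: `structure`, `population_auto`, `n_auto`, `accuracy`,
#'   `recall`.
#' @export
deployment_report <- function(decisions) {
  groups <- c(list(overall = decisions), split(decisions, decisions$structure))
  purrr::imap_dfr(groups, function(sub, nm) {
    auto <- sub[sub$decision == "auto_accept_prediction", ]
    if (nrow(auto) == 0) {
      warn(sprintf("structure '%s': no auto-accepted samples; metrics absent", nm))
      return(tibble(structure = nm, population_auto = 0, n_auto = 0L,
                    accuracy = NA_real_, recall = NA_real_))
    }
    pos <- sum(auto$label == 1)
    tibble(structure = nm,
           population_auto = nrow(auto) / nrow(sub),
           n_auto = nrow(auto),
           accuracy = mean(auto$predicted_label == auto$label),
           recall = if (pos == 0) NA_real_ else
             sum(auto$label == 1 & auto$predicted_label == 1) / pos)
  })
}
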