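#' Normalized Shannon entropy of a binary probability
#'
#' `H(p) = -[p log p + (1 - p) log(1 - p)] / log 2`, with the limit
#' convention `0 * log 0 = 0`, so `H(0) = H(1) = 0` and `H(0.5) = 1`.
#' This is the uncertainty score attached to every Monte-Carlo prediction:
#' 0 means fully confident, 1 maximally uncertain.
#'
#' @param p_hat Probabilities in `[0, 1]` (vectorised).
#' @return Entropies in `[0, 1]`.
#' @export
#' @examples
#' normalized_entropy(c(0, 0.5, 0.9, 1))
normalized_entropy <- function(p_hat) {
  if (any(is.na(p_hat)) || any(p_hat < 0 | p_hat > 1))
    abort("p_hat must lie within [0, 1]")
  # each term evaluated with its explicit limit, so the 0 * log 0 := 0
  # convention holds exactly at the endpoints
  t1 <- ifelse(p_hat > 0, p_hat * log(p_hat), 0)
  t2 <- ifelse(p_hat < 1, (1 - p_hat) * log(1 - p_hat), 0)
  h <- -(t1 + t2) / log(2)
  pmin(pmax(h, 0), 1)
}

#' Monte-Carlo dropout prediction with uncertainty
#'
#' Runs `T` stochastic forward passes with dropout kept active, averages the
#' per-pass probabilities into the quality score `p_hat`, computes its
#' normalized entropy, and thresholds `p_hat` at 0.5 (`>= 0.5` means
#' *revision required*). Per-pass seeds are derived from `seed` by pass
#' index, so results are reproducible and independent of batching.
#'
#' @param model A trained `cqa_model` (its config must carry a dropout
#'   rate in (0, 1); uncertainty is undefined without dropout units).
#' @param samples Sample tibble (needs `image`, `mask`, `structure`;
#'   `label`, `patient_id`, `slice_index` are carried through if present).
#' @param T Number of stochastic passes (default 30).
#' @param seed Master seed for the dropout streams.
#' @param dropout Set `FALSE` to run the degenerate no-dropout limit, where
#'   all passes coincide.
#' @return A `cqa_predictions` tibble: provenance columns, `per_pass`
#'   (list of length-`T` vectors), `mean_prob`, `entropy`,
#'   `predicted_label` (0/1), `T`.
#' @export
mc_predict <- function(model, samples, T = 30, seed = 1, dropout = TRUE) {
  if (T < 1) abort("T must be >= 1")
  if (is.null(model$config$dropout_rate) || model$config$dropout_rate <= 0)
    abort("model has no dropout units; MC-dropout uncertainty is undefined")
  probs <- vapply(seq_len(T), function(t)
    predict_prob(model, samples, dropout = dropout,
                 seed = derive_seed(seed, "pass", t)),
    numeric(nrow(samples)))
  probs <- matrix(probs, nrow = nrow(samples))
  keep <- intersect(c("patient_id", "slice_index", "structure", "label"),
                    names(samples))
  out <- dplyr::bind_cols(samples[keep], summarise_passes(probs))
  class(out) <- c("cqa_predictions", class(out))
  out
}

#' Aggregate per-pass probabilities into an MC prediction
#'
#' The Monte-Carlo quality score is the arithmetic mean of the per-pass
#' probabilities; its normalized entropy is the uncertainty; the hard label
#' applies the fixed 0.5 quality threshold (`>= 0.5` is revision required).
#'
#' @param probs Numeric matrix, one row per sample, one column per pass (a
#'   single prediction may be given as a plain vector of passes).
#' @return A tibble with `per_pass`, `mean_prob`, `entropy`,
#'   `predicted_label` and `T`.
#' @export
#' @examples
#' summarise_passes(c(0.2, 0.4, 0.6))  # mean 0.4 -> acceptable
summarise_passes <- function(probs) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  mean_prob <- rowMeans(probs)
  tibble(
    per_pass = lapply(seq_len(nrow(probs)), function(i) probs[i, ]),
    mean_prob = mean_prob,
    entropy = normalized_entropy(mean_prob),
    predicted_label = as.integer(mean_prob >= 0.5),
    T = ncol(probs))
}
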