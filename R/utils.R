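# internal helpers: seed derivation and scoped RNG

#' Derive a child seed from a master seed and a label path
#'
#' Hashes the master seed together with any number of labels into a
#' 32-bit-safe integer seed, so that every stochastic stage of a pipeline
#' draws from its own stream and adding a stage never shifts another stage's
#' randomness.
#'
#' @param seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer,
#'   e.g. `derive_seed(seed, "patient", 17)`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "phantom")
#' derive_seed(1, "epoch", 3)
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 104729
  for (ch in utf8ToInt(parts)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# evaluate expr with a private RNG state; the caller's stream is untouched
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# binary-mask sanity check used across the perturbation operators
check_mask <- function(mask, require_nonempty = TRUE, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    abort(sprintf("`%s` must be a binary {0,1} matrix", arg))
  if (require_nonempty && sum(mask) == 0)
    abort(sprintf("`%s` must contain at least one foreground pixel", arg))
  invisible(mask)
}

# degenerate-perturbation condition: callers resample rather than use these
abort_degenerate <- function(msg) {
  abort(msg, class = "contourqa_degenerate")
}

is_degenerate_error <- function(e) inherits(e, "contourqa_degenerate")
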