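#' Structure catalogue: names to one-hot codes
#'
#' A single multi-structure QA model is conditioned on which anatomical
#' structure a mask represents via a one-hot code appended to the
#' fully connected head. The catalogue fixes the name -> index mapping.
#'
#' @param names Character vector of unique structure names; order defines
#'   the code indices `0..K-1`.
#' @return An object of class `cqa_catalogue`.
#' @export
#' @examples
#' cat <- structure_catalogue(c("prostate", "rectum", "bladder"))
#' encode_structure("rectum", cat)
structure_catalogue <- function(names) {
  if (anyDuplicated(names)) abort("structure names must be unique")
  if (length(names) < 1) abort("catalogue needs at least one structure")
  structure(list(names = as.character(names), K = length(names)),
            class = "cqa_catalogue")
}

#' One-hot encode a structure name
#'
#' @param name Structure name present in the catalogue.
#' @param catalogue A [structure_catalogue()].
#' @return Numeric vector of length `K` with a single 1 at the structure's
#'   index.
#' @export
encode_structure <- function(name, catalogue) {
  i <- match(name, catalogue$names)
  if (is.na(i)) abort(sprintf("unknown structure name: '%s'", name))
  v <- numeric(catalogue$K)
  v[i] <- 1
  v
}

#' Flatten phantom patients into a slice-sample table
#'
#' Produces one row per (slice, structure) pair, all labelled *acceptable*
#' (0); perturbed *revision required* counterparts are added later by
#' [build_epoch()]. Empty masks are dropped (nothing to QA).
#'
#' @param patients List of `cqa_patient` objects (e.g. one split of a
#'   [generate_cohort()] result).
#' @return A tibble with columns `patient_id`, `slice_index`, `structure`,
#'   `image` (list), `mask` (list), `label` (0), `perturbation` (list of
#'   `NULL`).
#' @export
cohort_samples <- function(patients) {
  rows <- purrr::map_dfr(patients, function(p) {
    purrr::imap_dfr(p$slices, function(sl, k) {
      keep <- vapply(sl$masks, function(m) sum(m) > 0, TRUE)
      structs <- names(sl$masks)[keep]
      tibble(patient_id = p$patient_id, slice_index = k,
             structure = structs,
             image = rep(list(sl$image), length(structs)),
             mask = unname(sl$masks[keep]),
             label = 0L,
             perturbation = rep(list(NULL), length(structs)))
    })
  })
  rows
}

#' Build a class-balanced epoch with freshly perturbed counterexamples
#'
#' For every structure, each acceptable sample is paired with a
#' *revision required* copy whose mask was corrupted by one randomly drawn
#' perturbation family, giving exact per-structure class balance. Perturbed
#' masks are regenerated from the seed on every call, so different epoch
#' seeds yield different synthetic errors (dynamic generation), while the
#' same seed reproduces the epoch exactly — which is also how frozen
#' validation and test sets are built.
#'
#' @param pool Acceptable-sample tibble from [cohort_samples()].
#' @param catalogue Optional [structure_catalogue()]; when given, every
#'   catalogue structure must be present in the pool.
#' @param seed Integer seed.
#' @param shuffle Shuffle the rows (default TRUE; keep FALSE for frozen
#'   evaluation sets where stable ordering aids reproducibility).
#' @return A tibble like `pool` with twice the rows; perturbed rows carry
#'   `label = 1` and the sampled `perturbation` spec.
#' @export
build_epoch <- function(pool, catalogue = NULL, seed = 1, shuffle = TRUE) {
  if (nrow(pool) == 0) abort("empty sample pool")
  if (!is.null(catalogue)) {
    missing <- setdiff(catalogue$names, unique(pool$structure))
    if (length(missing))
      abort(sprintf("no acceptable samples for structure(s): %s",
                    paste(missing, collapse = ", ")))
  }
  perturbed <- pool
  res <- purrr::pmap(
    list(pool$mask, pool$patient_id, pool$slice_index, pool$structure),
    function(m, pid, k, st)
      sample_perturbation(m, derive_seed(seed, "perturb", pid, k, st)))
  perturbed$mask <- purrr::map(res, "mask")
  perturbed$perturbation <- purrr::map(res, "spec")
  perturbed$label <- 1L
  out <- bind_rows(pool, perturbed)
  if (shuffle)
    out <- out[with_rng(derive_seed(seed, "shuffle"),
                        sample(nrow(out))), ]
  out
}

#' Build the frozen balanced test set
#'
#' Pairs every acceptable evaluation slice with exactly one perturbed
#' counterpart, seeded once so the set is identical across evaluations.
#' Rows are kept in deterministic (unshuffled) order.
#'
#' @inheritParams build_epoch
#' @return A balanced sample tibble.
#' @export
build_test_set <- function(pool, catalogue = NULL, seed = 1) {
  build_epoch(pool, catalogue, seed = seed, shuffle = FALSE)
}

#' Summarise the perturbations present in a sample table
#'
#' @param samples Tibble from [build_epoch()] / [build_test_set()].
#' @return A tibble with one row per revision-required sample: provenance
#'   columns, `family`, and the sampled parameters serialized as JSON.
#' @export
perturbation_log <- function(samples) {
  rr <- dplyr::filter(samples, .data$label == 1L)
  tibble(
    patient_id = rr$patient_id,
    slice_index = rr$slice_index,
    structure = rr$structure,
    family = vapply(rr$perturbation, function(s) s$family, ""),
    params = vapply(rr$perturbation, function(s)
      as.character(jsonlite::toJSON(s[setdiff(names(s), "family")],
                                    auto_unbox = TRUE)), "")
  )
}
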