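#' Configure the synthetic phantom generator
#'
#' The phantom emulates resampled pelvic MR slices at desk scale: each
#' "patient" is a short stack of square grayscale slices containing one
#' bright/dark elliptical blob per structure on a noisy background. Three
#' archetypes with different characteristic sizes are provided by default
#' (a large bladder-like, a medium prostate-like and a small urethra-like
#' class) so that size-dependent perturbation behaviour is exercised.
#'
#' Images are rendered as: uniform background, per-structure foreground
#' intensity painted over the rasterized ellipse, i.i.d. Gaussian pixel
#' noise, Gaussian blur, then clamping to `[0, 1]`. The ground-truth mask of
#' each structure is the rasterized ellipse indicator *before* noise and
#' blur, so masks are exact.
#'
#' @param image_size Pixels per side of the square grid (>= 32).
#' @param n_structures Number of structure classes (default 3). Size
#'   archetypes are recycled when more than three are requested.
#' @param slices_per_patient Integer range `c(min, max)`; each patient draws
#'   its slice count uniformly from this range.
#' @param background_mean,background_sd Background intensity model; the sd is
#'   also the pixel noise level on the background.
#' @param foreground_means,foreground_sds Per-structure foreground intensity
#'   model (recycled to `n_structures`).
#' @param blur_sigma Gaussian blur applied after noise (pixels).
#' @param axis_ranges List (recycled) of `c(min, max)` semi-axis ranges, as
#'   fractions of `image_size`.
#' @param centers List (recycled) of `c(y, x)` nominal centers as fractions
#'   of `image_size`.
#' @param center_jitter Maximum per-patient center displacement (pixels).
#' @param seed Master RNG seed for cohort generation.
#' @return An object of class `cqa_phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(image_size = 32, slices_per_patient = c(2, 3))
#' pat <- generate_patient(cfg, "pt01", seed = 1)
#' length(pat$slices)
phantom_config <- function(image_size = 64,
                           n_structures = 3,
                           slices_per_patient = c(3, 6),
                           background_mean = 0.25,
                           background_sd = 0.06,
                           foreground_means = c(0.85, 0.65, 0.95),
                           foreground_sds = 0.06,
                           blur_sigma = 0.7,
                           axis_ranges = list(c(0.16, 0.25),
                                              c(0.09, 0.14),
                                              c(0.035, 0.06)),
                           centers = list(c(0.36, 0.36),
                                          c(0.63, 0.62),
                                          c(0.40, 0.70)),
                           center_jitter = 4,
                           seed = 1) {
  base_names <- c("bladder_like", "prostate_like", "urethra_like")
  k <- seq_len(n_structures)
  rec <- function(x) x[((k - 1) %% length(x)) + 1]
  names <- if (n_structures <= 3) base_names[k] else
    paste0(rec(base_names), "_", k)
  cfg <- structure(list(
    image_size = as.integer(image_size),
    n_structures = as.integer(n_structures),
    structure_names = names,
    slices_per_patient = as.integer(slices_per_patient),
    background_mean = background_mean,
    background_sd = background_sd,
    foreground_means = rec(foreground_means),
    foreground_sds = rec(foreground_sds),
    blur_sigma = blur_sigma,
    axis_ranges = rec(axis_ranges),
    centers = rec(centers),
    center_jitter = center_jitter,
    seed = as.integer(seed)
  ), class = "cqa_phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_size < 32)
    abort("image_size must be at least 32 pixels")
  if (length(cfg$slices_per_patient) != 2 ||
      any(cfg$slices_per_patient < 1) ||
      cfg$slices_per_patient[1] > cfg$slices_per_patient[2])
    abort("slices_per_patient must be an increasing integer range c(min, max)")
  max_ax <- max(vapply(cfg$axis_ranges, max, 0)) * cfg$image_size
  if (max_ax >= cfg$image_size / 2)
    abort("shapes do not fit: maximum semi-axis must be < image_size / 2")
  noise <- pmax(cfg$background_sd, cfg$foreground_sds)
  sep <- abs(cfg$foreground_means - cfg$background_mean)
  if (any(sep < 2 * noise))
    abort(paste0(
      "structures are not learnable: foreground and background means must ",
      "differ by at least 2 noise standard deviations (violated for: ",
      paste(cfg$structure_names[sep < 2 * noise], collapse = ", "), ")"))
  invisible(cfg)
}

# rasterize an ellipse on the pixel grid; 0-based pixel-center coordinates,
# (row, col) = (y, x)
rasterize_ellipse <- function(image_size, cy, cx, a, b, theta) {
  yy <- matrix(0:(image_size - 1), image_size, image_size) - cy
  xx <- t(matrix(0:(image_size - 1), image_size, image_size)) - cx
  u <- (xx * cos(theta) + yy * sin(theta)) / a
  v <- (-xx * sin(theta) + yy * cos(theta)) / b
  m <- matrix(0L, image_size, image_size)
  m[u^2 + v^2 <= 1] <- 1L
  m
}

#' Generate one phantom patient
#'
#' Draws patient-level shape parameters (size, orientation, center) for every
#' structure, then renders each slice with small per-slice jitter so slices
#' within a patient resemble each other the way neighbouring anatomy does.
#'
#' @param config A [phantom_config()].
#' @param patient_id Character identifier.
#' @param seed Integer seed; the same seed reproduces the patient bit for bit.
#' @return An object of class `cqa_patient`: a list with `patient_id` and
#'   `slices`, each slice holding `image` (matrix in `[0,1]`) and `masks`
#'   (named list of binary matrices, one per structure).
#' @export
generate_patient <- function(config, patient_id, seed) {
  validate_phantom_config(config)
  s <- config$image_size
  with_rng(seed, {
    rng <- config$slices_per_patient
    n_slices <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
    base <- lapply(seq_len(config$n_structures), function(i) {
      ar <- config$axis_ranges[[i]] * s
      list(a = runif(1, ar[1], ar[2]),
           b = runif(1, ar[1], ar[2]),
           theta = runif(1, 0, pi),
           cy = config$centers[[i]][1] * s +
             runif(1, -config$center_jitter, config$center_jitter),
           cx = config$centers[[i]][2] * s +
             runif(1, -config$center_jitter, config$center_jitter))
    })
    slices <- lapply(seq_len(n_slices), function(k) {
      masks <- list()
      img <- matrix(config$background_mean, s, s)
      noise_sd <- matrix(config$background_sd, s, s)
      for (i in seq_len(config$n_structures)) {
        p <- base[[i]]
        scale <- max(0.8, rnorm(1, 1, 0.05))
        m <- rasterize_ellipse(s,
                               p$cy + runif(1, -1, 1), p$cx + runif(1, -1, 1),
                               p$a * scale, p$b * scale, p$theta)
        masks[[config$structure_names[i]]] <- m
        img[m == 1] <- config$foreground_means[i]
        noise_sd[m == 1] <- config$foreground_sds[i]
      }
      img <- img + matrix(rnorm(s * s), s, s) * noise_sd
      if (config$blur_sigma > 0)
        img <- as.matrix(EBImage::gblur(img, sigma = config$blur_sigma))
      img <- pmin(pmax(img, 0), 1)
      list(image = img, masks = masks)
    })
    structure(list(patient_id = patient_id, slices = slices),
              class = "cqa_patient")
  })
}

#' Generate a patient-level split cohort
#'
#' Patients receive globally unique ids and are partitioned into disjoint
#' training / validation / test lists, mirroring a patient-level split so no
#' subject leaks between splits. Each patient's content is a pure function of
#' the config seed and its id, so regenerating with the same seed reproduces
#' the cohort exactly.
#'
#' @param config A [phantom_config()]; its `seed` drives everything.
#' @param n_train,n_val,n_test Patient counts per split (all >= 1).
#' @return An object of class `cqa_cohort`: list with elements `train`,
#'   `val`, `test` (lists of `cqa_patient`) and the `config`.
#' @export
generate_cohort <- function(config, n_train, n_val, n_test) {
  if (any(c(n_train, n_val, n_test) < 1))
    abort("all split sizes must be >= 1")
  total <- n_train + n_val + n_test
  ids <- sprintf("pt%04d", seq_len(total))
  patients <- lapply(ids, function(id)
    generate_patient(config, id, derive_seed(config$seed, "patient", id)))
  structure(list(
    train = patients[seq_len(n_train)],
    val = patients[n_train + seq_len(n_val)],
    test = patients[n_train + n_val + seq_len(n_test)],
    config = config
  ), class = "cqa_cohort")
}

#' @export
print.cqa_cohort <- function(x, ...) {
  cat(sprintf(
    "<cqa_cohort> %d/%d/%d patients (train/val/test), %d structures, %dx%d px\n",
    length(x$train), length(x$val), length(x$test),
    x$config$n_structures, x$config$image_size, x$config$image_size))
  invisible(x)
}

#' @export
print.cqa_patient <- function(x, ...) {
  cat(sprintf("<cqa_patient> %s: %d slices, %d structures\n", x$patient_id,
              length(x$slices), length(x$slices[[1]]$masks)))
  invisible(x)
}
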