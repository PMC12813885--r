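# shared fixtures: small masks, configs and toy prediction tables

square_mask <- function(h = 10, w = h, rows = 4:7, cols = rows) {
  m <- matrix(0L, h, w)
  m[rows, cols] <- 1L
  m
}

disc_mask <- function(h = 24, r = 6, cy = (h - 1) / 2, cx = cy) {
  yy <- matrix(0:(h - 1), h, h)
  xx <- t(yy)
  m <- matrix(0L, h, h)
  m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 1L
  m
}

tiny_phantom <- function(seed = 1, image_size = 32) {
  phantom_config(image_size = image_size, slices_per_patient = c(2, 3),
                 seed = seed)
}

# random masks of assorted size for property tests: discs and rectangles
random_mask <- function(seed, min_r = 3, max_r = 8, h = 28) {
  set.seed(seed)
  if (runif(1) < 0.5) {
    r <- sample(min_r:max_r, 1)
    cy <- runif(1, r + 3, h - r - 4)
    cx <- runif(1, r + 3, h - r - 4)
    disc_mask(h, r, cy, cx)
  } else {
    a <- sample(min_r:max_r, 1); b <- sample(min_r:max_r, 1)
    r0 <- sample(4:(h - 2 * a - 4), 1); c0 <- sample(4:(h - 2 * b - 4), 1)
    square_mask(h, h, r0:(r0 + a), c0:(c0 + b))
  }
}

# toy prediction table with controllable labels/uncertainties
toy_predictions <- function(label, predicted_label, entropy,
                            structure = "organ") {
  tibble::tibble(label = as.integer(label),
                 predicted_label = as.integer(predicted_label),
                 entropy = entropy,
                 structure = structure)
}

random_predictions <- function(n, seed, structure = "organ") {
  set.seed(seed)
  label <- rbinom(n, 1, 0.5)
  if (all(label == 0)) label[1] <- 1L
  if (all(label == 1)) label[1] <- 0L
  mean_prob <- runif(n)
  tibble::tibble(
    label = as.integer(label),
    mean_prob = mean_prob,
    predicted_label = as.integer(mean_prob >= 0.5),
    entropy = contourqa::normalized_entropy(mean_prob),
    structure = structure)
}
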