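# independent oracle implementations, deliberately written differently from
# the package code paths they check

# translation by explicit per-pixel loop
oracle_shift <- function(mask, dx, dy) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    si <- i - dy; sj <- j - dx
    if (si >= 1 && si <= h && sj >= 1 && sj <= w && mask[si, sj] == 1)
      out[i, j] <- 1L
  }
  out
}

# brute-force morphological dilation/erosion with an arbitrary flat kernel
oracle_morph <- function(mask, kern, op = c("dilate", "erode")) {
  op <- match.arg(op)
  h <- nrow(mask); w <- ncol(mask)
  kh <- nrow(kern); kw <- ncol(kern)
  oy <- (kh - 1) / 2; ox <- (kw - 1) / 2
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (a in seq_len(kh)) for (b in seq_len(kw)) {
      if (kern[a, b] == 0) next
      si <- i + a - 1 - oy; sj <- j + b - 1 - ox
      vals <- c(vals, if (si >= 1 && si <= h && sj >= 1 && sj <= w)
        mask[si, sj] else 0L)
    }
    out[i, j] <- if (op == "dilate") max(vals) else min(vals)
  }
  out
}

# even-odd ray-casting point-in-polygon, independent of mgcv::in.out
oracle_point_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# prefix enumeration of the calibration curve and exhaustive threshold search
oracle_curve <- function(label, predicted, entropy) {
  ord <- order(entropy)
  lab <- label[ord]; prd <- predicted[ord]
  n <- length(lab)
  rec <- numeric(n)
  for (i in seq_len(n)) {
    pos <- sum(lab[1:i] == 1)
    rec[i] <- if (pos == 0) 1 else sum(lab[1:i] == 1 & prd[1:i] == 1) / pos
  }
  list(uncertainty = entropy[ord], cum_recall = rec,
       pop_fraction = (1:n) / n)
}

oracle_threshold <- function(label, predicted, entropy, target) {
  oc <- oracle_curve(label, predicted, entropy)
  for (i in seq_along(oc$cum_recall))
    if (oc$cum_recall[i] < target) return(oc$uncertainty[i])
  1.0
}

# confusion-matrix metrics from scratch (no shared helpers)
oracle_metrics <- function(truth, score) {
  pred <- ifelse(score >= 0.5, 1L, 0L)
  acc <- mean(pred == truth)
  tp <- sum(pred == 1 & truth == 1)
  prec <- tp / sum(pred == 1)
  rec <- tp / sum(truth == 1)
  f1 <- 2 * prec * rec / (prec + rec)
  # Mann-Whitney statistic by pairwise comparison
  pos <- score[truth == 1]; neg <- score[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    auc = mean(cmp))
}

# uniform-bin summary via cut(), independent of the package binning
oracle_binned <- function(label, predicted, entropy, n_bins) {
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(entropy, br, include.lowest = FALSE, right = FALSE,
             labels = FALSE)
  bin[entropy >= 1] <- n_bins
  bin[entropy == 0] <- 1L
  res <- list()
  for (b in sort(unique(bin))) {
    k <- bin == b
    pos <- sum(label[k] == 1)
    res[[length(res) + 1]] <- data.frame(
      bin = b, mean_uncertainty = mean(entropy[k]),
      accuracy = mean(predicted[k] == label[k]),
      recall = if (pos > 0) sum(label[k] == 1 & predicted[k] == 1) / pos
      else NA_real_,
      n = sum(k))
  }
  do.call(rbind, res)
}
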