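mk_pred <- function(label, mean_prob, structure = "organ", T = 3,
                    per_pass = NULL) {
  n <- length(label)
  tibble::tibble(
    label = as.integer(label),
    structure = structure,
    mean_prob = mean_prob,
    predicted_label = as.integer(mean_prob >= 0.5),
    entropy = contourqa::normalized_entropy(mean_prob),
    per_pass = if (is.null(per_pass)) lapply(mean_prob, rep, T) else per_pass,
    T = as.integer(T))
}

test_that("perfect separation and perfect inversion give the expected metrics", {
  perfect <- mk_pred(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  m <- compute_metrics(perfect, "mean_prob")
  expect_equal(m$estimate, rep(1, 5))
  inverted <- mk_pred(c(1, 0), c(0.4, 0.6))
  mi <- compute_metrics(inverted, "mean_prob")
  got <- setNames(mi$estimate, mi$metric)
  expect_equal(unname(got["accuracy"]), 0)
  expect_equal(unname(got["recall"]), 0)
  expect_equal(unname(got["auc"]), 0)
})

test_that("metrics equal the confusion-matrix / Mann-Whitney oracle", {
  for (s in 1:60) {
    set.seed(s)
    n <- 30
    lab <- rbinom(n, 1, 0.5)
    if (all(lab == 0)) lab[1] <- 1L
    if (all(lab == 1)) lab[1] <- 0L
    # scores with deliberate ties to exercise the tie correction
    score <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    pred <- mk_pred(lab, score)
    m <- compute_metrics(pred, "mean_prob")
    got <- setNames(m$estimate, m$metric)
    want <- oracle_metrics(lab, score)
    for (k in names(want))
      if (!is.na(want[k]))
        expect_equal(unname(got[k]), unname(want[k]), tolerance = 1e-12)
  }
})

test_that("F1 is the harmonic mean of the reported precision and recall", {
  set.seed(5)
  pred <- mk_pred(rbinom(40, 1, 0.5), runif(40))
  m <- compute_metrics(pred, "mean_prob")
  v <- setNames(m$estimate, m$metric)
  expect_equal(v[["f1"]],
               2 * v[["precision"]] * v[["recall"]] /
                 (v[["precision"]] + v[["recall"]]), tolerance = 1e-12)
})

test_that("per-pass mode reports mean and spread across passes", {
  set.seed(8)
  n <- 20; T <- 6
  lab <- rbinom(n, 1, 0.5); lab[1:2] <- c(0L, 1L)
  passes <- lapply(seq_len(n), function(i) pmin(pmax(
    lab[i] * 0.7 + 0.15 + rnorm(T, 0, 0.15), 0), 1))
  pred <- mk_pred(lab, vapply(passes, mean, 0), per_pass = passes, T = T)
  m <- compute_metrics(pred, "per_pass")
  expect_true(all(!is.na(m$sd)))
  # oracle: evaluate each pass independently
  pm <- do.call(rbind, passes)
  per_t <- vapply(seq_len(T), function(t) oracle_metrics(lab, pm[, t]),
                  numeric(5))
  for (k in rownames(per_t)) {
    expect_equal(m$estimate[m$metric == k], mean(per_t[k, ]),
                 tolerance = 1e-12)
    expect_equal(m$sd[m$metric == k], sd(per_t[k, ]), tolerance = 1e-12)
  }
  # identical passes (dropout off) give exactly zero spread
  pred0 <- mk_pred(lab, vapply(passes, mean, 0), T = 4)
  m0 <- compute_metrics(pred0, "per_pass")
  expect_equal(m0$sd, rep(0, 5))
})

test_that("single-class input reports AUC as absent with a warning", {
  pred <- mk_pred(c(1, 1, 1), c(0.9, 0.8, 0.7))
  expect_warning(m <- compute_metrics(pred, "mean_prob"), "one class")
  v <- setNames(m$estimate, m$metric)
  expect_true(is.na(v[["auc"]]))
  expect_equal(unname(v["accuracy"]), 1)
})

test_that("AUC is invariant to strictly monotone transforms and agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  lab <- rbinom(50, 1, 0.4); lab[1:2] <- c(0L, 1L)
  score <- runif(50)
  a1 <- compute_metrics(mk_pred(lab, score), "mean_prob")
  a2 <- compute_metrics(mk_pred(lab, plogis(5 * qlogis(
    pmin(pmax(score, 1e-6), 1 - 1e-6)))), "mean_prob")
  auc1 <- a1$estimate[a1$metric == "auc"]
  expect_equal(auc1, a2$estimate[a2$metric == "auc"], tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc1, ref, tolerance = 1e-12)
})

test_that("deployment report computes auto-subset metrics per structure", {
  dec <- dplyr::bind_rows(
    mk_pred(c(1, 1, 0, 0), c(0.9, 0.4, 0.1, 0.8), "a"),
    mk_pred(c(1, 0), c(0.95, 0.05), "b"))
  dec$decision <- c("auto_accept_prediction", "flag_for_review",
                    "auto_accept_prediction", "auto_accept_prediction",
                    "auto_accept_prediction", "auto_accept_prediction")
  rep <- deployment_report(dec)
  a <- rep[rep$structure == "a", ]
  # auto subset of a: rows 1 (TP), 3 (TN), 4 (FP) -> acc 2/3, recall 1
  expect_equal(a$population_auto, 3 / 4)
  expect_equal(a$accuracy, 2 / 3)
  expect_equal(a$recall, 1)
  b <- rep[rep$structure == "b", ]
  expect_equal(b$population_auto, 1)
  expect_equal(b$accuracy, 1)
  # all flagged -> absent metrics with warning
  dec$decision <- "flag_for_review"
  w <- capture_warnings(r0 <- deployment_report(dec))
  expect_true(all(grepl("no auto-accepted", w)))
  expect_true(all(r0$population_auto == 0))
  expect_true(all(is.na(r0$accuracy)))
})
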