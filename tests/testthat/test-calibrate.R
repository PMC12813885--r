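test_that("the calibration curve matches prefix enumeration on the worked example", {
  # labels R,R,A,R with the third revision-required one missed
  pred <- toy_predictions(label = c(1, 1, 0, 1),
                          predicted_label = c(1, 1, 0, 0),
                          entropy = c(0.1, 0.2, 0.3, 0.4))
  curve <- build_calibration_curve(pred)
  expect_equal(curve$uncertainty, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(curve$cum_recall, c(1, 1, 1, 2 / 3))
  expect_equal(curve$pop_fraction, (1:4) / 4)
  # threshold at 98%: first drop below target is the fourth point
  expect_equal(select_threshold(curve, 0.98), 0.4)
  # and the accepted prefix below tau has recall 1
  acc <- pred[pred$entropy < 0.4, ]
  expect_equal(mean(acc$predicted_label[acc$label == 1] == 1), 1)
})

test_that("curve edge conventions: all-correct, vacuous prefix, order invariance", {
  pred <- toy_predictions(c(0, 1, 0, 1), c(0, 1, 0, 1),
                          c(0.4, 0.1, 0.3, 0.2))
  curve <- build_calibration_curve(pred)
  expect_true(all(curve$cum_recall == 1))
  expect_equal(select_threshold(curve, 0.98), 1.0)
  # permuting the input leaves the curve unchanged
  perm <- pred[c(3, 1, 4, 2), ]
  expect_equal(build_calibration_curve(perm), curve)
  # recall is vacuously 1 before any revision-required sample appears
  pred2 <- toy_predictions(c(0, 0, 1), c(1, 0, 0), c(0.1, 0.2, 0.9))
  expect_equal(build_calibration_curve(pred2)$cum_recall, c(1, 1, 0))
  expect_error(build_calibration_curve(toy_predictions(0, 0, 0.5)),
               "undefined")
})

test_that("curve and threshold match exhaustive brute force on random instances", {
  for (s in 1:60) {
    set.seed(s)
    n <- sample(3:50, 1)
    lab <- rbinom(n, 1, 0.5); if (!any(lab == 1)) lab[1] <- 1L
    prd <- ifelse(runif(n) < 0.8, lab, 1L - lab)   # mostly correct
    ent <- round(runif(n), 2)                      # ties on purpose
    target <- sample(c(0.8, 0.9, 0.98, 1.0), 1)
    pred <- toy_predictions(lab, prd, ent)
    curve <- build_calibration_curve(pred)
    oc <- oracle_curve(lab, prd, ent)
    expect_equal(curve$cum_recall, oc$cum_recall)
    expect_equal(curve$uncertainty, oc$uncertainty)
    tau <- select_threshold(curve, target)
    expect_equal(tau, oracle_threshold(lab, prd, ent, target))
    # threshold guarantee on the calibration set itself
    acc <- pred[pred$entropy < tau, ]
    if (any(acc$label == 1)) {
      rec <- sum(acc$label == 1 & acc$predicted_label == 1) / sum(acc$label == 1)
      expect_gte(rec, target)
    }
  }
})

test_that("a target of 1.0 cuts at the first missed revision-required sample", {
  pred <- toy_predictions(c(1, 1, 1, 0), c(1, 0, 1, 0),
                          c(0.05, 0.11, 0.2, 0.3))
  expect_equal(select_threshold(build_calibration_curve(pred), 1.0), 0.11)
  # with no misses the threshold stays at 1 (urethra-style limit)
  perfect <- toy_predictions(c(1, 1), c(1, 1), c(0.2, 0.9))
  expect_equal(select_threshold(build_calibration_curve(perfect), 1.0), 1.0)
})

test_that("threshold_table calibrates per structure with overrides", {
  pred <- dplyr::bind_rows(
    toy_predictions(c(1, 1, 0, 1), c(1, 1, 0, 0), c(0.1, 0.2, 0.3, 0.4), "a"),
    toy_predictions(c(1, 0, 1), c(1, 0, 1), c(0.5, 0.6, 0.7), "b"))
  tt <- threshold_table(pred, 0.98, overrides = c(b = 1.0))
  expect_equal(tt$tau[tt$structure == "a"], 0.4)
  expect_equal(tt$tau[tt$structure == "b"], 1.0)
  expect_equal(tt$target_recall, c(0.98, 1.0))
  expect_true(all(tt$recall_below_tau >= tt$target_recall))
  # idempotence: recalibrating the same predictions gives the same table
  expect_equal(threshold_table(pred, 0.98, overrides = c(b = 1.0)), tt)
})

test_that("the decision policy flags at and above the threshold (strict <)", {
  pred <- toy_predictions(c(0, 1, 0), c(0, 1, 0), c(0.0, 0.5, 0.7))
  thr <- tibble::tibble(structure = "organ", target_recall = 0.98,
                        tau = 0.5, recall_below_tau = 1,
                        population_below_tau = 1 / 3)
  dec <- apply_policy(pred, thr)
  expect_equal(dec$decision,
               c("auto_accept_prediction", "flag_for_review",
                 "flag_for_review"))
  other <- toy_predictions(1, 1, 0.2, structure = "unknown")
  expect_error(apply_policy(other, thr), "no threshold")
  # population bookkeeping: n auto + n flagged = n
  rep <- deployment_report(dec)
  ov <- rep[rep$structure == "overall", ]
  expect_equal(ov$population_auto, 1 / 3)
})

test_that("binned performance matches an independent histogram oracle", {
  expect_equal(formals(binned_performance)$n_bins, 80)
  for (s in 1:20) {
    pred <- random_predictions(60, seed = s)
    nb <- sample(c(5, 16, 80), 1)
    got <- binned_performance(pred, nb)
    want <- oracle_binned(pred$label, pred$predicted_label, pred$entropy, nb)
    expect_equal(as.data.frame(got), want, tolerance = 1e-12)
  }
  # single-bin edge case: bin accuracy equals overall accuracy
  pred <- random_predictions(40, seed = 99)
  one <- binned_performance(pred, 1)
  expect_equal(one$accuracy, mean(pred$predicted_label == pred$label))
  expect_error(binned_performance(pred, 0), "n_bins")
})
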