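small_cfg <- function(K = 2, image_size = 32)
  model_config(image_size = image_size, structure_code_length = K,
               fc_sizes = 8L)

test_that("configuration invariants are enforced", {
  expect_error(model_config(dropout_rate = 0), "between 0 and 1")
  expect_error(model_config(dropout_rate = 1), "between 0 and 1")
  expect_error(model_config(image_size = 50), "divisible")
  big <- model_config("resnet34_style", image_size = 64,
                      structure_code_length = 7)
  expect_equal(big$stage_blocks, c(3L, 4L, 6L, 3L))
  expect_equal(big$stage_channels, c(64L, 128L, 256L, 512L))
  expect_error(train_config(initial_lr = 0), "positive")
  expect_error(train_config(batch_size = 0), "batch_size")
})

test_that("the learning-rate schedule decays 80% every 100 epochs", {
  tc <- train_config()
  expect_equal(tc$initial_lr, 1e-4)
  expect_equal(tc$batch_size, 64L)
  expect_equal(lr_at_epoch(tc, 0), 1e-4)
  expect_equal(lr_at_epoch(tc, 99), 1e-4)
  expect_equal(lr_at_epoch(tc, 100), 2e-5)
  expect_equal(lr_at_epoch(tc, 200), 4e-6)
})

test_that("forward output is a probability, deterministic without dropout", {
  ct <- structure_catalogue(c("a", "b"))
  m <- qa_model(small_cfg(), ct, seed = 3)
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- disc_mask(32, 5)
  p1 <- qa_forward(m, img, msk, "a")
  p2 <- qa_forward(m, img, msk, "a")
  expect_identical(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
  # dropout-off inference ignores the seed entirely
  expect_identical(qa_forward(m, img, msk, "a", seed = 7),
                   qa_forward(m, img, msk, "a", seed = 8))
  # with dropout: reproducible per seed, stochastic across seeds
  d1 <- qa_forward(m, img, msk, "a", dropout = TRUE, seed = 1)
  expect_identical(d1, qa_forward(m, img, msk, "a", dropout = TRUE, seed = 1))
  expect_false(identical(d1,
                         qa_forward(m, img, msk, "a", dropout = TRUE, seed = 2)))
  # shape and catalogue mismatches error
  expect_error(qa_forward(m, img[1:16, ], msk, "a"), "shape")
  expect_error(qa_forward(m, img, msk, "c"), "unknown structure")
})

test_that("the head consumes the structure code", {
  ct <- structure_catalogue(c("a", "b"))
  m <- qa_model(small_cfg(), ct, seed = 5)
  set.seed(2)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- disc_mask(32, 5)
  pa <- qa_forward(m, img, msk, "a")
  pb <- qa_forward(m, img, msk, "b")
  expect_false(isTRUE(all.equal(pa, pb)))
})

test_that("backpropagation matches finite differences on a tiny network", {
  cfg <- list(in_channels = 2L, structure_code_length = 2L,
              stage_channels = c(3L, 4L), stage_blocks = c(1L, 1L),
              fc_sizes = 5L, dropout_rate = 0.1)
  sh <- contourqa:::cpp_param_shapes(cfg)
  np <- sum(sh$nrow * sh$ncol)
  set.seed(1)
  theta <- rnorm(np, sd = 0.2)
  H <- 8L; N <- 3L
  x <- array(rnorm(H * H * 2 * N), dim = c(H, H, 2L, N))
  codes <- matrix(0, N, 2); codes[cbind(1:N, c(1, 2, 1))] <- 1
  lab <- c(0, 1, 1)
  g <- contourqa:::cpp_loss_grad(cfg, theta, as.numeric(x), c(H, H, 2L, N),
                                 codes, lab, FALSE, 7L)
  eps <- 1e-6
  idx <- sort(sample(np, 50))
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    num <- (contourqa:::cpp_loss_grad(cfg, tp, as.numeric(x), c(H, H, 2L, N),
                                      codes, lab, FALSE, 7L)$loss -
            contourqa:::cpp_loss_grad(cfg, tm, as.numeric(x), c(H, H, 2L, N),
                                      codes, lab, FALSE, 7L)$loss) / (2 * eps)
    expect_equal(g$grad[i], num, tolerance = 1e-5)
  }
})

test_that("training on separable phantom data reduces the loss", {
  pc <- phantom_config(image_size = 32, slices_per_patient = c(3, 3),
                       seed = 5)
  co <- generate_cohort(pc, 8, 2, 2)
  ct <- structure_catalogue(pc$structure_names)
  pool <- cohort_samples(co$train)
  val <- build_test_set(cohort_samples(co$val), ct, seed = 3)
  m <- qa_model(model_config(image_size = 32, structure_code_length = 3),
                ct, seed = 1)
  tc <- train_config(initial_lr = 3e-3, batch_size = 16, epochs = 15,
                     seed = 4)
  m <- train_qa_model(m, pool, val, tc)
  expect_equal(nrow(m$log), 15)
  expect_lt(mean(tail(m$log$loss, 3)), mean(head(m$log$loss, 3)))
  expect_equal(m$log$lr, rep(3e-3, 15))
  # broom-style views
  expect_equal(tidy(m), m$log)
  g <- glance(m)
  expect_equal(g$epochs, 15L)
  expect_equal(g$n_parameters, length(m$theta))
})

test_that("training is reproducible for a fixed seed", {
  pc <- phantom_config(image_size = 32, slices_per_patient = c(2, 2),
                       seed = 6)
  co <- generate_cohort(pc, 3, 1, 1)
  ct <- structure_catalogue(pc$structure_names)
  pool <- cohort_samples(co$train)
  val <- build_test_set(cohort_samples(co$val), ct, seed = 2)
  tc <- train_config(initial_lr = 1e-3, epochs = 2, seed = 11)
  m1 <- train_qa_model(qa_model(small_cfg(3), ct, 7), pool, val, tc)
  m2 <- train_qa_model(qa_model(small_cfg(3), ct, 7), pool, val, tc)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$log, m2$log)
})
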