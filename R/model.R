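#' Configure the QA network architecture
#'
#' The classifier is a residual CNN over a two-channel input (image slice and
#' binary mask stacked), followed by global average pooling and a fully
#' connected head. The one-hot structure code is concatenated to the pooled
#' features before the first FC layer, and a dropout unit precedes every FC
#' layer so the same dropout machinery drives both regularization and
#' Monte-Carlo uncertainty at inference. The output is a single sigmoid unit:
#' the predicted probability that the contour requires revision.
#'
#' Two presets are provided: `"small_resnet"` (two stages of one residual
#' block, widths 8/16 — trains in minutes on a CPU) and `"resnet34_style"`
#' (four stages of 3/4/6/3 blocks, widths 64/128/256/512). Explicit
#' `stage_channels` / `stage_blocks` override the preset.
#'
#' @param backbone `"small_resnet"` or `"resnet34_style"`.
#' @param image_size Input side length; must be divisible by
#'   `2^(n_stages + 1)` (one stem pooling plus one per stage).
#' @param structure_code_length K, the catalogue size.
#' @param fc_sizes Hidden widths of the FC head (the 1-unit output layer is
#'   appended automatically).
#' @param dropout_rate Dropout probability in (0, 1) for every FC layer
#'   input; default 0.1.
#' @param stage_channels,stage_blocks Optional explicit architecture.
#' @return An object of class `cqa_model_config`.
#' @export
model_config <- function(backbone = c("small_resnet", "resnet34_style"),
                         image_size = 64,
                         structure_code_length = 3,
                         fc_sizes = NULL,
                         dropout_rate = 0.1,
                         stage_channels = NULL,
                         stage_blocks = NULL) {
  backbone <- match.arg(backbone)
  if (is.null(stage_channels)) {
    if (backbone == "small_resnet") {
      stage_channels <- c(8L, 16L); stage_blocks <- c(1L, 1L)
      if (is.null(fc_sizes)) fc_sizes <- 64L
    } else {
      stage_channels <- c(64L, 128L, 256L, 512L)
      stage_blocks <- c(3L, 4L, 6L, 3L)
      if (is.null(fc_sizes)) fc_sizes <- 256L
    }
  }
  if (is.null(fc_sizes)) fc_sizes <- 64L
  if (dropout_rate <= 0 || dropout_rate >= 1)
    abort("dropout_rate must lie strictly between 0 and 1")
  n_pool <- length(stage_channels) + 1
  if (image_size %% (2^n_pool) != 0)
    abort(sprintf("image_size must be divisible by %d for %d pooling steps",
                  2^n_pool, n_pool))
  structure(list(
    backbone = backbone,
    image_size = as.integer(image_size),
    in_channels = 2L,
    structure_code_length = as.integer(structure_code_length),
    stage_channels = as.integer(stage_channels),
    stage_blocks = as.integer(stage_blocks),
    fc_sizes = as.integer(fc_sizes),
    dropout_rate = dropout_rate
  ), class = "cqa_model_config")
}

#' Configure the training protocol
#'
#' Defaults follow the reference protocol: binary cross-entropy with Adam,
#' initial learning rate `1e-4`, reduced by 80% (multiplied by 0.2) every
#' 100 epochs, batch size 64.
#'
#' @param initial_lr Initial Adam learning rate (> 0).
#' @param lr_decay_every Epochs between decays.
#' @param lr_decay_factor Multiplier applied at each decay (0.2 = an 80%
#'   reduction).
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of training epochs.
#' @param seed Seed driving epoch construction, shuffling and dropout.
#' @return An object of class `cqa_train_config`.
#' @export
train_config <- function(initial_lr = 1e-4, lr_decay_every = 100,
                         lr_decay_factor = 0.2, batch_size = 64,
                         epochs = 30, seed = 1) {
  if (initial_lr <= 0) abort("initial_lr must be positive")
  if (batch_size < 1) abort("batch_size must be >= 1")
  structure(list(initial_lr = initial_lr,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "cqa_train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The scheduled learning rate, e.g. with defaults `1e-4` at epoch
#'   0, `2e-5` at epoch 100, `4e-6` at epoch 200.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$initial_lr * config$lr_decay_factor^(epoch %/% config$lr_decay_every)
}

cfg_for_cpp <- function(config) {
  list(in_channels = config$in_channels,
       structure_code_length = config$structure_code_length,
       stage_channels = config$stage_channels,
       stage_blocks = config$stage_blocks,
       fc_sizes = config$fc_sizes,
       dropout_rate = config$dropout_rate)
}

#' Initialise a QA model
#'
#' He-initialised weights; biases start at zero.
#'
#' @param config A [model_config()].
#' @param catalogue A [structure_catalogue()]; its size must match
#'   `config$structure_code_length`.
#' @param seed Weight-initialisation seed.
#' @return An object of class `cqa_model`.
#' @export
qa_model <- function(config, catalogue, seed = 1) {
  if (catalogue$K != config$structure_code_length)
    abort("catalogue size and structure_code_length disagree")
  sh <- cpp_param_shapes(cfg_for_cpp(config))
  sizes <- sh$nrow * sh$ncol
  theta <- with_rng(seed, {
    unlist(lapply(seq_along(sh$name), function(i) {
      if (grepl("\\.b$", sh$name[i]) || sh$name[i] %in% c("stem.b", "out.b"))
        return(numeric(sizes[i]))
      rnorm(sizes[i], sd = sqrt(2 / sh$nrow[i]))
    }))
  })
  structure(list(
    config = config,
    catalogue = catalogue,
    theta = theta,
    opt = list(m = numeric(length(theta)), v = numeric(length(theta)),
               adam_t = 0L),
    log = NULL
  ), class = "cqa_model")
}

#' @export
print.cqa_model <- function(x, ...) {
  cat(sprintf(
    "<cqa_model> %s backbone, %d weights, K = %d structures, dropout %.2g%s\n",
    x$config$backbone, length(x$theta), x$catalogue$K,
    x$config$dropout_rate,
    if (is.null(x$log)) " (untrained)"
    else sprintf(", %d epochs trained", max(x$log$epoch) + 1)))
  invisible(x)
}

samples_to_arrays <- function(samples, config, catalogue) {
  s <- config$image_size
  n <- nrow(samples)
  x <- array(0, dim = c(s, s, 2L, n))
  for (i in seq_len(n)) {
    img <- samples$image[[i]]; msk <- samples$mask[[i]]
    if (!all(dim(img) == c(s, s)) || !all(dim(msk) == c(s, s)))
      abort(sprintf("sample %d: image/mask shape does not match the configured %dx%d input",
                    i, s, s))
    x[, , 1, i] <- img
    x[, , 2, i] <- msk
  }
  codes <- t(vapply(samples$structure, encode_structure, numeric(catalogue$K),
                    catalogue = catalogue))
  dimnames(codes) <- NULL
  list(x = x, codes = codes)
}

#' Forward pass: probability that a contour requires revision
#'
#' Runs the network over a table of samples. With `dropout = FALSE` the
#' output is deterministic; with `dropout = TRUE` one stochastic dropout
#' pass is performed, reproducible for a fixed `seed`.
#'
#' @param model A `cqa_model`.
#' @param samples Sample tibble (needs `image`, `mask`, `structure`).
#' @param dropout Keep dropout active (Monte-Carlo pass)?
#' @param seed Seed for the dropout masks.
#' @param chunk_size Samples per compiled-forward call (memory control).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, samples, dropout = FALSE, seed = 0,
                         chunk_size = 64) {
  arr <- samples_to_arrays(samples, model$config, model$catalogue)
  n <- nrow(samples)
  s <- model$config$image_size
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  out <- numeric(n)
  for (ci in seq_along(idx)) {
    ix <- idx[[ci]]
    out[ix] <- cpp_forward(
      cfg_for_cpp(model$config), model$theta,
      as.numeric(arr$x[, , , ix, drop = FALSE]),
      c(s, s, 2L, length(ix)),
      arr$codes[ix, , drop = FALSE],
      dropout, derive_seed(seed, "chunk", ci))
  }
  out
}

#' Forward pass for a single slice
#'
#' Convenience wrapper around [predict_prob()] for one image/mask pair.
#'
#' @param model A `cqa_model`.
#' @param image,mask Matrices of the configured input size.
#' @param structure Structure name (must be in the model's catalogue).
#' @param dropout Keep dropout active?
#' @param seed Dropout seed.
#' @return A single probability.
#' @export
qa_forward <- function(model, image, mask, structure, dropout = FALSE,
                       seed = 0) {
  predict_prob(model,
               tibble(image = list(image), mask = list(mask),
                      structure = structure),
               dropout = dropout, seed = seed)
}

#' Train the QA model
#'
#' Each epoch is built freshly by [build_epoch()] (balanced classes per
#' structure, newly sampled perturbations), then optimised with Adam under
#' the scheduled learning rate. Validation accuracy (dropout off, quality
#' threshold 0.5) is tracked per epoch and the best-validation weights are
#' restored at the end. A non-finite training loss aborts with a diagnostic.
#'
#' @param model A `cqa_model` from [qa_model()].
#' @param pool Acceptable-sample pool ([cohort_samples()]) used to build
#'   training epochs.
#' @param val_samples Frozen balanced validation set ([build_test_set()]).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch?
#' @return The trained `cqa_model`, with a `log` tibble (epoch, lr, loss,
#'   val_accuracy).
#' @export
train_qa_model <- function(model, pool, val_samples, config,
                           verbose = FALSE) {
  cfg <- cfg_for_cpp(model$config)
  val_arr <- NULL
  best_acc <- -Inf
  best_theta <- model$theta
  log <- vector("list", config$epochs)
  for (e in seq_len(config$epochs) - 1L) {
    epoch <- build_epoch(pool, model$catalogue,
                         seed = derive_seed(config$seed, "epoch", e))
    arr <- samples_to_arrays(epoch, model$config, model$catalogue)
    lr <- lr_at_epoch(config, e)
    res <- cpp_train_epoch(
      cfg, model$theta, model$opt$m, model$opt$v, model$opt$adam_t,
      as.numeric(arr$x), c(dim(arr$x)), arr$codes,
      as.numeric(epoch$label), lr, config$batch_size,
      derive_seed(config$seed, "dropout", e))
    model$theta <- res$theta
    model$opt <- list(m = res$m, v = res$v, adam_t = res$adam_t)
    val_prob <- predict_prob(model, val_samples)
    val_acc <- mean((val_prob >= 0.5) == (val_samples$label == 1L))
    if (val_acc >= best_acc) {  # later epoch wins ties (more training)
      best_acc <- val_acc
      best_theta <- model$theta
    }
    log[[e + 1]] <- tibble(epoch = e, lr = lr,
                           loss = mean(res$batch_loss),
                           val_accuracy = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  loss %.4f  val acc %.3f",
                      e, lr, mean(res$batch_loss), val_acc))
  }
  model$log <- bind_rows(log)
  model$theta <- best_theta
  model
}
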