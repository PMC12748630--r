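#' Training configuration
#'
#' Defaults follow the study protocol: 100 epochs, batch size 64, learning
#' rate 0.1 with a step scheduler multiplying the rate by 0.1 every 25
#' epochs, binary cross-entropy loss, and the adaptive-moment (Adam)
#' optimizer with standard moment coefficients (0.9 / 0.999). A learning
#' rate of 0.1 is unusually high for this optimizer and is kept for
#' fidelity; `grad_clip` exposes an optional global gradient-norm cap
#' (default `Inf`, i.e. off) for small-fixture stability.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size (>= 2; a trailing batch of one sample
#'   is folded into the previous batch so batch statistics stay defined).
#' @param learning_rate Initial learning rate (> 0).
#' @param lr_step Scheduler step size in epochs.
#' @param lr_decay Multiplicative decay applied every `lr_step` epochs.
#' @param grad_clip Global gradient-norm cap (`Inf` = off).
#' @param shuffle Uniformly reshuffle samples each epoch.
#' @param seed Seed governing shuffling, dropout, and any other training
#'   randomness; identical seed + data + config reproduce the loss history
#'   exactly under fixed thread settings.
#' @return An object of class `vg_train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L,
                         learning_rate = 0.1, lr_step = 25L,
                         lr_decay = 0.1, grad_clip = Inf,
                         shuffle = TRUE, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, lr_step = as.integer(lr_step),
              lr_decay = lr_decay, grad_clip = grad_clip,
              shuffle = isTRUE(shuffle), seed = as.integer(seed))
  class(cfg) <- "vg_train_config"
  check_that(cfg$epochs >= 1L, "epochs must be >= 1")
  check_that(cfg$batch_size >= 2L, "batch_size must be >= 2")
  check_that(cfg$learning_rate > 0, "learning_rate must be > 0")
  check_that(cfg$lr_step >= 1L, "lr_step must be >= 1")
  check_that(cfg$lr_decay > 0, "lr_decay must be > 0")
  cfg
}

#' Fine-tuning configuration
#'
#' The convolutional branches (weights, biases, batch-norm parameters and
#' running statistics) are frozen bit-identically; only the dense stage and
#' output layer are updated, for 20 epochs by default.
#'
#' @param epochs Fine-tuning epochs (default 20).
#' @param learning_rate Learning rate (default: the baseline 0.1).
#' @param batch_size,lr_step,lr_decay,grad_clip,shuffle,seed As in
#'   [train_config()].
#' @return An object of class `vg_train_config` with `frozen = "conv"`.
#' @export
finetune_config <- function(epochs = 20L, learning_rate = 0.1,
                            batch_size = 64L, lr_step = 25L, lr_decay = 0.1,
                            grad_clip = Inf, shuffle = TRUE, seed = 1L) {
  cfg <- train_config(epochs = epochs, batch_size = batch_size,
                      learning_rate = learning_rate, lr_step = lr_step,
                      lr_decay = lr_decay, grad_clip = grad_clip,
                      shuffle = shuffle, seed = seed)
  cfg$frozen <- "conv"
  cfg
}

#' Learning-rate schedule
#'
#' Step decay: `learning_rate * lr_decay^floor((epoch - 1) / lr_step)`, so
#' with the defaults epochs 1, 26, 51, 76 run at 0.1, 0.01, 0.001, 1e-4.
#'
#' @param config A [train_config()].
#' @param epoch Epoch number(s), 1-based.
#' @return Numeric learning rate(s).
#' @export
lr_at_epoch <- function(config, epoch) {
  config$learning_rate * config$lr_decay^((epoch - 1L) %/% config$lr_step)
}

as_binary_labels <- function(y) {
  if (is.factor(y)) return(as.integer(y) - 1L)
  if (is.character(y)) {
    check_that(all(y %in% vg_groups()), "labels must be control/patient",
               class = "vg_contract_error")
    return(as.integer(y == "patient"))
  }
  check_that(all(y %in% c(0, 1)), "numeric labels must be 0/1",
             class = "vg_contract_error")
  as.integer(y)
}

dataset_xy <- function(ds) {
  list(x = ds$x, y = as_binary_labels(ds$meta$group))
}

#' Train a classifier
#'
#' Mini-batch gradient descent with binary cross-entropy loss, the
#' adaptive-moment optimizer, and the step learning-rate schedule.
#' `x`/`y` must already be normalized (see [fit_range()]); the
#' leave-one-out driver handles that bookkeeping. Training is deterministic
#' given `config$seed`, the data, and fixed thread settings.
#'
#' @param model A freshly built (or pretrained) `vg_model`.
#' @param x 6 x T x n array or `vg_dataset` of normalized samples (if a
#'   dataset, labels are taken from `meta$group` and `y` may be omitted).
#' @param y Labels: 0/1, factor, or control/patient strings. Positive = 1 =
#'   patient. A single-class training set is a contract error.
#' @param config A [train_config()] ([finetune_config()] freezes the
#'   convolutional stage).
#' @return The trained `vg_model`; per-epoch mean loss in
#'   `$meta$loss_history`, the per-epoch learning rates in `$meta$lr_trace`,
#'   and the optimizer step count in `$meta$steps`.
#' @export
train_model <- function(model, x, y = NULL, config = train_config()) {
  if (inherits(x, "vg_dataset")) {
    if (is.null(y)) y <- x$meta$group
    x <- x$x
  }
  y <- as_binary_labels(y)
  x <- as_input_array(model, x)
  N <- dim(x)[3]
  check_that(length(y) == N, "label count (%d) != sample count (%d)",
             length(y), N, class = "vg_contract_error")
  check_that(length(unique(y)) == 2L,
             "training set must contain both classes",
             class = "vg_contract_error")
  frozen_conv <- identical(config$frozen, "conv")
  upd <- names(model$params)
  if (frozen_conv) upd <- setdiff(upd, conv_param_names(model$spec))

  withr::with_seed(config$seed, {
    opt <- adam_init(model$params, upd)
    history <- numeric(config$epochs)
    steps <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch)
      idx <- if (config$shuffle) sample.int(N) else seq_len(N)
      starts <- seq(1L, N, by = config$batch_size)
      batches <- lapply(starts, function(s) {
        idx[s:min(s + config$batch_size - 1L, N)]
      })
      nb <- length(batches)
      if (nb > 1L && length(batches[[nb]]) == 1L) {
        batches[[nb - 1L]] <- c(batches[[nb - 1L]], batches[[nb]])
        batches[[nb]] <- NULL
      }
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        bidx <- batches[[bi]]
        xb <- x[, , bidx, drop = FALSE]
        yb <- y[bidx]
        fw <- nn_forward(model, xb, train = TRUE, conv_train = !frozen_conv)
        model$state <- fw$state
        losses[bi] <- bce_loss(fw$prob, yb)
        grads <- nn_backward(model, fw$cache, yb, conv = !frozen_conv)
        if (is.finite(config$grad_clip)) {
          gn <- global_grad_norm(grads, upd)
          if (gn > config$grad_clip) {
            sc <- config$grad_clip / gn
            for (nm in upd) grads[[nm]] <- grads[[nm]] * sc
          }
        }
        st <- adam_step(opt, model$params, grads, upd, lr)
        opt <- st$opt
        model$params <- st$params
        steps <- steps + 1L
      }
      history[epoch] <- mean(losses)
    }
    # re-estimate batch-normalization running statistics in one pass over
    # the training set; at small step budgets the momentum-averaged
    # statistics lag the trained parameters, which would distort
    # eval-mode predictions. A frozen convolutional stage is left
    # untouched (its statistics belong to the checkpoint).
    fw <- nn_forward(model, x, train = TRUE, conv_train = !frozen_conv,
                     momentum = 1, dropout = FALSE)
    model$state <- fw$state
    model$meta$loss_history <- history
    model$meta$lr_trace <- lr_at_epoch(config, seq_len(config$epochs))
    model$meta$steps <- steps
    model$meta$config <- config
  })
  model
}

#' Pretrain a classifier on a source dataset
#'
#' Estimates source validation performance by k-fold cross-validation
#' (sample-level folds for unsegmented activity sources; subject-level
#' folds when `fold_unit = "subject"`), then trains a final model on the
#' full source for use as a transfer checkpoint. Within each fold the
#' range normalization is fitted on that fold's training data only.
#'
#' @param ds A `vg_dataset` of source samples on the model input grid
#'   (resample activity windows first, see [resample_dataset()]).
#' @param spec A [model_spec()].
#' @param config A [train_config()]; activity-window sources conventionally
#'   use `learning_rate = 0.001`.
#' @param n_folds Number of validation folds.
#' @param fold_unit `"sample"` or `"subject"`.
#' @return A list of class `vg_pretrain`: `model` (trained on all source
#'   data, with its normalization attached), `val_accuracy` (mean over
#'   folds; pooled sample accuracy for sample folds, mean of per-subject
#'   means for subject folds), and `fold_accuracies`.
#' @export
pretrain_model <- function(ds, spec, config = train_config(),
                           n_folds = 5L, fold_unit = c("sample", "subject")) {
  fold_unit <- match.arg(fold_unit)
  xy <- dataset_xy(ds)
  N <- length(xy$y)
  units <- if (fold_unit == "sample") seq_len(N) else
    sort(unique(ds$meta$subject_id))
  fold_of <- withr::with_seed(config$seed, {
    sample(rep_len(seq_len(n_folds), length(units)))
  })
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    if (fold_unit == "sample") {
      val_idx <- which(fold_of == f)
    } else {
      val_idx <- which(ds$meta$subject_id %in% units[fold_of == f])
    }
    tr_idx <- setdiff(seq_len(N), val_idx)
    norm <- fit_range(xy$x[, , tr_idx, drop = FALSE])
    m <- build_model(modify_seed(spec, spec$seed + f))
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    m <- train_model(m, apply_range(norm, xy$x[, , tr_idx, drop = FALSE]),
                     xy$y[tr_idx], cfg_f)
    pv <- forward(m, apply_range(norm, xy$x[, , val_idx, drop = FALSE]))
    correct <- (pv >= spec$threshold) == (xy$y[val_idx] == 1L)
    if (fold_unit == "sample") {
      fold_acc[f] <- mean(correct)
    } else {
      fold_acc[f] <- mean(tapply(correct, ds$meta$subject_id[val_idx], mean))
    }
  }
  norm_all <- fit_range(xy$x)
  final <- build_model(spec)
  final <- train_model(final, apply_range(norm_all, xy$x), xy$y, config)
  final$norm <- norm_all
  structure(list(model = final, val_accuracy = mean(fold_acc),
                 fold_accuracies = fold_acc),
            class = "vg_pretrain")
}

modify_seed <- function(spec, seed) {
  spec$seed <- as.integer(seed %% .Machine$integer.max)
  spec
}

#' Fine-tune a pretrained checkpoint on target data
#'
#' Starts from the checkpoint's parameters, freezes the convolutional
#' branches (parameters and batch-norm running statistics stay
#' bit-identical), and updates only the dense stage and output layer for
#' `config$epochs` (default 20) epochs.
#'
#' @param checkpoint A pretrained `vg_model` (or `vg_pretrain`).
#' @param x,y Normalized target samples and labels as in [train_model()].
#' @param config A [finetune_config()].
#' @return The fine-tuned `vg_model`.
#' @export
finetune_model <- function(checkpoint, x, y = NULL,
                           config = finetune_config()) {
  if (inherits(checkpoint, "vg_pretrain")) checkpoint <- checkpoint$model
  check_that(identical(config$frozen, "conv"),
             "finetune_model requires a finetune_config()",
             class = "vg_contract_error")
  if (inherits(x, "vg_dataset")) {
    if (is.null(y)) y <- x$meta$group
    x <- x$x
  }
  check_that(dim(x)[1] == checkpoint$spec$input_shape[1] &&
               dim(x)[2] == checkpoint$spec$input_shape[2],
             "target input shape does not match checkpoint spec",
             class = "vg_contract_error")
  model <- checkpoint
  model$norm <- NULL
  model$meta <- list()
  train_model(model, x, y, config)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding the spec, every parameter and
#' running-state tensor, the fitted normalization, and training metadata,
#' with a format version stamp. Reloading reproduces eval-mode outputs
#' exactly.
#'
#' @param model A `vg_model`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   the restored `vg_model`.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(format = "vg_checkpoint_v1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  check_that(identical(obj$format, "vg_checkpoint_v1"),
             "not a vestgait checkpoint: %s", path, class = "vg_format_error")
  obj$model
}
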