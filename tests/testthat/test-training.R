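test_that("the learning-rate schedule decays by gamma every step epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, c(1, 25, 26, 51, 76, 100)),
               c(0.1, 0.1, 0.01, 0.001, 1e-4, 1e-4))
  m <- train_model(build_model(model_spec(filters = c(2L, 2L, 2L, 2L),
                                          dense_sizes = c(4L, 4L),
                                          input_shape = c(6L, 32L),
                                          seed = 1L)),
                   array(runif(6 * 32 * 8), c(6, 32, 8)),
                   rep(0:1, 4),
                   train_config(epochs = 3L, batch_size = 8L,
                                lr_step = 2L, seed = 1L))
  expect_equal(m$meta$lr_trace, c(0.1, 0.1, 0.01))
  expect_length(m$meta$loss_history, 3L)
})

test_that("training is deterministic under a fixed seed", {
  ds <- strong_head_ds()
  norm <- fit_range(ds)
  x <- apply_range(norm, ds$x)
  y <- ds$meta$group
  cfg <- tiny_config(epochs = 3L)
  m1 <- train_model(build_model(tiny_spec()), x, y, cfg)
  m2 <- train_model(build_model(tiny_spec()), x, y, cfg)
  expect_identical(m1$meta$loss_history, m2$meta$loss_history)
  expect_identical(m1$params, m2$params)
  m3 <- train_model(build_model(tiny_spec()), x, y, tiny_config(seed = 99L,
                                                                epochs = 3L))
  expect_false(identical(m3$meta$loss_history, m1$meta$loss_history))
})

test_that("separable cycles are learned and permuted labels are not", {
  ds <- strong_head_ds()
  norm <- fit_range(ds)
  x <- apply_range(norm, ds$x)
  y <- as.integer(ds$meta$group) - 1L
  cfg <- tiny_config()
  m <- train_model(build_model(tiny_spec()), x, y, cfg)
  acc <- mean((forward(m, x) >= 0.5) == (y == 1))
  expect_gte(acc, 0.95)
  y_perm <- withr::with_seed(1L, sample(y))
  m_perm <- train_model(build_model(tiny_spec()), x, y_perm, cfg)
  expect_gt(tail(m_perm$meta$loss_history, 1), tail(m$meta$loss_history, 1))
})

test_that("single-class training sets are rejected", {
  expect_error(train_model(build_model(tiny_spec()),
                           array(0.5, c(6, 512, 4)), rep(1L, 4),
                           tiny_config(epochs = 1L)),
               "both classes", class = "vg_contract_error")
})

test_that("pretraining learns separable activity windows and not null ones", {
  pre <- pretrained_checkpoint()
  expect_gte(pre$val_accuracy, 0.9)
  null_windows <- generate_activity_windows(
    activity_config(n_windows_per_class = 30L,
                    class_freq = c(walk = 1.5, run = 1.5),
                    noise_sd = 0.5, seed = 3L))
  pre0 <- pretrain_model(resample_dataset(null_windows, 512L, "cubic"),
                         tiny_spec(),
                         train_config(epochs = 6L, batch_size = 64L,
                                      learning_rate = 0.01, seed = 5L),
                         n_folds = 3L)
  # 95% binomial band around 0.5 for 60 validation windows
  expect_gt(pre0$val_accuracy, 0.5 - 1.96 * sqrt(0.25 / 60))
  expect_lt(pre0$val_accuracy, 0.5 + 1.96 * sqrt(0.25 / 60))
})

test_that("fine-tuning freezes the convolutional stage bit-identically", {
  pre <- pretrained_checkpoint()
  ds <- strong_head_ds()
  norm <- fit_range(ds)
  x <- apply_range(norm, ds$x)
  ft <- finetune_model(pre, x, ds$meta$group, tiny_finetune())
  spec <- tiny_spec()
  for (nm in vestgait:::conv_param_names(spec)) {
    expect_identical(ft$params[[nm]], pre$model$params[[nm]])
  }
  for (nm in vestgait:::conv_state_names(spec)) {
    expect_identical(ft$state[[nm]], pre$model$state[[nm]])
  }
  # dense parameters did move
  expect_gt(max(abs(ft$params[["fc1.W"]] - pre$model$params[["fc1.W"]])), 0)
  # step bookkeeping: epochs x batches per epoch
  n <- n_samples(ds)
  expect_equal(ft$meta$steps, 5L * ceiling(n / 64))
  # transfer sanity: fine-tuned model beats chance on its target
  acc <- mean((forward(ft, x) >= 0.5) == (ds$meta$group == "patient"))
  expect_gte(acc, 0.6)
  expect_error(finetune_model(pre, array(0, c(6, 256, 4)), rep(0:1, 2),
                              tiny_finetune()),
               "shape", class = "vg_contract_error")
})

test_that("checkpoints round-trip through disk with identical outputs", {
  pre <- pretrained_checkpoint()
  path <- file.path(withr::local_tempdir(), "ckpt.rds")
  save_checkpoint(pre$model, path)
  back <- load_checkpoint(path)
  set.seed(21)
  x <- array(runif(6 * 512 * 3), c(6, 512, 3))
  expect_identical(forward(back, x), forward(pre$model, x))
  expect_identical(back$norm, pre$model$norm)
})
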