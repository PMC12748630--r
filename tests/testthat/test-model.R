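test_that("spec validation enforces the pooling and threshold contracts", {
  expect_error(model_spec(input_shape = c(6L, 500L)), "divisible",
               class = "vg_spec_error")
  expect_error(model_spec(dropout_rate = 1), "dropout",
               class = "vg_spec_error")
  expect_error(model_spec(filters = c(8L, 16L)), "per conv block",
               class = "vg_spec_error")
  spec <- model_spec()
  expect_equal(spec$input_shape[2] / spec$pool_size^spec$conv_blocks, 32)
})

test_that("convolutional parameter count matches the closed form", {
  # default widths: 32 + 400 + 1568 + 6208 = 8208 per branch
  expect_equal(conv_parameter_count(model_spec()), 8208L)
  for (filters in list(c(4L, 8L, 8L, 16L), c(2L, 4L, 4L, 8L))) {
    spec <- model_spec(filters = filters, dense_sizes = c(8L, 4L))
    m <- build_model(spec)
    # oracle: count the built tensors directly
    nm <- grep("^br1\\.conv", names(m$params), value = TRUE)
    actual <- sum(vapply(m$params[nm], length, integer(1)))
    expect_equal(actual, conv_parameter_count(spec))
  }
})

test_that("forward outputs are probabilities and eval mode is deterministic", {
  spec <- model_spec(filters = c(2L, 4L, 4L, 8L), dense_sizes = c(8L, 4L),
                     seed = 2L)
  m <- build_model(spec)
  set.seed(9)
  x <- array(runif(6 * 512 * 3), c(6, 512, 3))
  p1 <- forward(m, x)
  p2 <- forward(m, x)
  expect_length(p1, 3L)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  # batch-size invariance: per-sample eval outputs do not depend on peers
  single <- vapply(1:3, function(i) forward(m, x[, , i]), numeric(1))
  expect_equal(single, p1, tolerance = 1e-6)
  # rebuilding from the same spec reproduces the initialization
  expect_identical(build_model(spec)$params, m$params)
  expect_error(forward(m, array(0, c(6, 256, 2))), "shape",
               class = "vg_contract_error")
})

test_that("each branch sees only its own input channel", {
  spec <- model_spec(filters = c(2L, 4L, 4L, 8L), dense_sizes = c(8L, 4L),
                     seed = 3L)
  m <- build_model(spec)
  set.seed(11)
  x <- array(runif(6 * 512 * 2), c(6, 512, 2))
  base <- vestgait:::branch_features(m, x)
  for (k in c(2L, 5L)) {
    xz <- x
    xz[k, , ] <- 0
    feats <- vestgait:::branch_features(m, xz)
    for (b in seq_len(6L)) {
      if (b == k) {
        expect_gt(max(abs(feats[[b]] - base[[b]])), 0)
      } else {
        expect_identical(feats[[b]], base[[b]])
      }
    }
  }
})

test_that("predict_label thresholds with the positive-at-tie convention", {
  expect_equal(predict_label(c(0.73, 0.21, 0.5)),
               c("patient", "control", "patient"))
  expect_equal(predict_label(0.8, threshold = 0.9), "control")
  expect_error(predict_label(1.2), "\\[0, 1\\]")
})

test_that("analytic gradients match numerical differentiation", {
  spec <- model_spec(filters = c(3L, 4L, 4L, 5L), dense_sizes = c(7L, 5L),
                     input_shape = c(6L, 32L), dropout_rate = 0, seed = 3L)
  m <- build_model(spec)
  set.seed(1)
  x <- array(rnorm(6 * 32 * 5), c(6, 32, 5))
  y <- c(0, 1, 0, 1, 1)
  fw <- vestgait:::nn_forward(m, x, train = TRUE)
  grads <- vestgait:::nn_backward(m, fw$cache, y)
  loss_at <- function(mm) {
    f <- vestgait:::nn_forward(mm, x, train = TRUE)
    vestgait:::bce_loss(f$prob, y)
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2L, length(p)))) {
      up <- m; up$params[[nm]][i] <- p[i] + eps
      dn <- m; dn$params[[nm]][i] <- p[i] - eps
      numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(as.numeric(grads[[nm]][i]), numeric_grad,
                   tolerance = 1e-4,
                   label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})
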