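#' Architecture specification of the six-branch 1-D convolutional classifier
#'
#' One independent convolutional branch per input channel (no weight
#' sharing), each branch four repetitions of
#' convolution(kernel 3, padding 1, stride 1) -> ReLU -> batch
#' normalization -> max pool(2, 2); branch outputs are flattened,
#' concatenated, and passed through two fully connected blocks
#' (affine -> ReLU -> batch normalization -> dropout 0.5) and a final
#' single-unit affine layer with logistic output. A probability at or above
#' `threshold` is classified as the positive class (`patient`).
#'
#' Per-branch filter counts and dense widths are configurable; the defaults
#' (`filters = c(8, 16, 32, 64)`, `dense_sizes = c(128, 64)`) keep the
#' flattened feature width at `6 * 64 * 32 = 12288` for the 6 x 512 input.
#'
#' @param n_branches Number of parallel branches (= input channels).
#' @param conv_blocks Convolution blocks per branch.
#' @param kernel_size Convolution kernel size (odd; padding keeps length).
#' @param filters Output channels of the four blocks.
#' @param dense_sizes Widths of the two hidden dense layers.
#' @param dropout_rate Dropout probability in the dense stage.
#' @param input_shape `c(channels, time)`; time must be divisible by
#'   `pool_size^conv_blocks`.
#' @param threshold Decision threshold on the output probability; a value
#'   exactly at the threshold is classified positive.
#' @param seed Seed for parameter initialization.
#' @return An object of class `vg_model_spec`.
#' @export
model_spec <- function(n_branches = 6L,
                       conv_blocks = 4L,
                       kernel_size = 3L,
                       filters = c(8L, 16L, 32L, 64L),
                       dense_sizes = c(128L, 64L),
                       dropout_rate = 0.5,
                       input_shape = c(6L, 512L),
                       threshold = 0.5,
                       seed = 1L) {
  spec <- list(n_branches = as.integer(n_branches),
               conv_blocks = as.integer(conv_blocks),
               kernel_size = as.integer(kernel_size),
               padding = (as.integer(kernel_size) - 1L) %/% 2L,
               conv_stride = 1L, pool_size = 2L, pool_stride = 2L,
               filters = as.integer(filters),
               dense_sizes = as.integer(dense_sizes),
               dropout_rate = dropout_rate,
               input_shape = as.integer(input_shape),
               threshold = threshold, seed = as.integer(seed))
  class(spec) <- "vg_model_spec"
  check_that(spec$kernel_size %% 2L == 1L,
             "kernel_size must be odd (length-preserving padding)",
             class = "vg_spec_error")
  check_that(length(spec$filters) == spec$conv_blocks,
             "filters must list one count per conv block",
             class = "vg_spec_error")
  check_that(spec$input_shape[1] == spec$n_branches,
             "input channel count must equal n_branches",
             class = "vg_spec_error")
  check_that(spec$input_shape[2] %% spec$pool_size^spec$conv_blocks == 0L,
             "time axis (%d) must be divisible by %d for %d poolings",
             spec$input_shape[2], spec$pool_size^spec$conv_blocks,
             spec$conv_blocks, class = "vg_spec_error")
  check_that(spec$dropout_rate >= 0 && spec$dropout_rate < 1,
             "dropout_rate must be in [0, 1)", class = "vg_spec_error")
  check_that(spec$threshold > 0 && spec$threshold < 1,
             "threshold must be in (0, 1)", class = "vg_spec_error")
  spec
}

#' Closed-form convolutional parameter count
#'
#' Sum over blocks of `c_in * c_out * kernel + c_out` (weights + biases)
#' for one branch; batch-normalization parameters are excluded. With the
#' default spec this is 32 + 400 + 1568 + 6208 = 8208 per branch.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count for a single branch.
#' @export
conv_parameter_count <- function(spec) {
  c_in <- 1L
  total <- 0L
  for (k in seq_len(spec$conv_blocks)) {
    c_out <- spec$filters[k]
    total <- total + c_in * c_out * spec$kernel_size + c_out
    c_in <- c_out
  }
  total
}

#' Build a classifier from a spec
#'
#' Initializes all weights with fan-in-scaled normal draws from
#' `spec$seed` (biases zero, batch-norm scale one / shift zero), so two
#' builds from the same spec are identical.
#'
#' @param spec A [model_spec()].
#' @return An object of class `vg_model`: spec, named parameter list,
#'   batch-norm running state, and a `norm` slot for the training-range
#'   normalization fitted alongside the model.
#' @export
build_model <- function(spec) {
  init <- withr::with_seed(spec$seed, init_params(spec))
  structure(list(spec = spec, params = init$params, state = init$state,
                 norm = NULL, meta = list()),
            class = "vg_model")
}

#' @export
print.vg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<vg_model> %d branches x %d blocks (filters %s), dense %s; %d parameters\n",
    x$spec$n_branches, x$spec$conv_blocks,
    paste(x$spec$filters, collapse = "/"),
    paste(x$spec$dense_sizes, collapse = "/"), np))
  invisible(x)
}

#' Forward pass: cycle matrices to probabilities
#'
#' Evaluation mode is deterministic: dropout is inactive and batch
#' normalization uses running statistics, so per-sample outputs are
#' independent of batch composition. Train mode applies dropout and batch
#' statistics and is stochastic under the caller's RNG.
#'
#' @param model A `vg_model`.
#' @param x A 6 x T matrix, 6 x T x n array, or `vg_dataset` of
#'   already-normalized inputs.
#' @param mode `"eval"` (default) or `"train"`.
#' @return Numeric vector of probabilities in (0, 1), one per sample.
#' @export
forward <- function(model, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  x <- as_input_array(model, x)
  nn_forward(model, x, train = mode == "train")$prob
}

as_input_array <- function(model, x) {
  if (inherits(x, "vg_dataset")) x <- x$x
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  sh <- model$spec$input_shape
  check_that(length(dim(x)) == 3L && dim(x)[1] == sh[1] && dim(x)[2] == sh[2],
             "input shape (%s) does not match spec input %d x %d",
             paste(dim(x), collapse = " x "), sh[1], sh[2],
             class = "vg_contract_error")
  x
}

#' Threshold a probability into a group label
#'
#' Probabilities at or above the threshold map to `patient` (the positive
#' class), below it to `control`. The tie at exactly the threshold is
#' positive by convention.
#'
#' @param probability Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Character vector of group labels.
#' @export
predict_label <- function(probability, threshold = 0.5) {
  check_that(all(probability >= 0 & probability <= 1),
             "probabilities must lie in [0, 1]", class = "vg_contract_error")
  ifelse(probability >= threshold, "patient", "control")
}

#' Predict probabilities for raw (unnormalized) samples
#'
#' Applies the model's stored training-range normalization, then runs an
#' eval-mode forward pass.
#'
#' @param model A trained `vg_model` with a fitted `norm`.
#' @param ds A `vg_dataset` or 6 x T x n array of raw samples.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(model, ds) {
  check_that(!is.null(model$norm), "model has no fitted normalization",
             class = "vg_contract_error")
  forward(model, apply_range(model$norm, if (inherits(ds, "vg_dataset")) ds$x else ds))
}
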