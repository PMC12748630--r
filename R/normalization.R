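#' Fit train-set range normalization
#'
#' Computes the per-channel minimum and maximum over every value of every
#' training sample (6 pairs). Channels with `max == min` are flagged
#' degenerate and assigned a unit denominator so [apply_range()] maps them
#' to a constant 0. Parameters must be fitted on training data only; the
#' cross-validation drivers enforce this by construction.
#'
#' A `global` mode (one min/max across all six channels) is available for
#' completeness; the per-channel mode is the default because accelerometer
#' and gyroscope magnitudes differ by orders of magnitude.
#'
#' @param x A `vg_dataset` or a 6 x T x n array of training samples.
#' @param mode `"channel"` (default) or `"global"`.
#' @return An object of class `vg_norm` with fields `min`, `max`, `scale`
#'   (denominator after degenerate substitution) and `degenerate`.
#' @export
fit_range <- function(x, mode = c("channel", "global")) {
  mode <- match.arg(mode)
  if (inherits(x, "vg_dataset")) x <- x$x
  check_that(length(dim(x)) == 3L && dim(x)[1] == 6L,
             "x must be a 6 x T x n array", class = "vg_contract_error")
  check_that(dim(x)[3] >= 1L, "empty training set",
             class = "vg_contract_error")
  if (mode == "channel") {
    m <- matrix(x, nrow = 6L)
    mn <- apply(m, 1L, min)
    mx <- apply(m, 1L, max)
  } else {
    mn <- rep(min(x), 6L)
    mx <- rep(max(x), 6L)
  }
  degenerate <- mx == mn
  scale <- ifelse(degenerate, 1, mx - mn)
  structure(list(min = mn, max = mx, scale = scale,
                 degenerate = degenerate, mode = mode),
            class = "vg_norm")
}

#' Apply range normalization
#'
#' Maps `value -> (value - min) / (max - min)` per channel. Training values
#' map into `[0, 1]` by construction; held-out values may fall outside and
#' are deliberately **not** clipped.
#'
#' @param params A [fit_range()] result.
#' @param x A `vg_dataset`, a 6 x T x n array, or a single 6 x T matrix.
#' @return The normalized object, same shape/class as the input.
#' @export
apply_range <- function(params, x) {
  stopifnot(inherits(params, "vg_norm"))
  if (inherits(x, "vg_dataset")) {
    x$x <- apply_range(params, x$x)
    return(x)
  }
  if (is.matrix(x)) {
    return((x - params$min) / params$scale)
  }
  check_that(length(dim(x)) == 3L && dim(x)[1] == 6L,
             "x must be 6 x T (x n)", class = "vg_contract_error")
  # first dim is the channel axis, so plain recycling normalizes per channel
  array((x - params$min) / params$scale, dim(x))
}
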