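#' Segmentation parameters
#'
#' Gait cycles are delimited by successive dominant positive peaks of the
#' right-ankle pitch angular velocity (the swing-phase peak of a
#' shank-mounted gyroscope). Candidate peaks are local maxima whose
#' topographic prominence exceeds `min_peak_prominence` times the signal's
#' robust range (95th minus 5th percentile), detected on an optionally
#' moving-average-smoothed copy; cycles whose duration falls outside
#' `[min_cycle_duration_s, max_cycle_duration_s]` are discarded, not merged.
#'
#' @param min_peak_prominence Fraction of the robust range (default 0.3).
#' @param min_cycle_duration_s,max_cycle_duration_s Physiologic duration
#'   window in seconds (defaults 0.6 and 2.0).
#' @param smoothing_window_s Moving-average window in seconds applied only
#'   to the detector's copy of the signal (0 = none; default 0.05).
#' @return An object of class `vg_seg_params`.
#' @export
segmentation_params <- function(min_peak_prominence = 0.3,
                                min_cycle_duration_s = 0.6,
                                max_cycle_duration_s = 2.0,
                                smoothing_window_s = 0.05) {
  p <- list(min_peak_prominence = min_peak_prominence,
            min_cycle_duration_s = min_cycle_duration_s,
            max_cycle_duration_s = max_cycle_duration_s,
            smoothing_window_s = smoothing_window_s)
  class(p) <- "vg_seg_params"
  check_that(p$min_peak_prominence >= 0, "min_peak_prominence must be >= 0")
  check_that(p$min_cycle_duration_s > 0 &&
               p$min_cycle_duration_s < p$max_cycle_duration_s,
             "need 0 < min_cycle_duration_s < max_cycle_duration_s")
  check_that(p$smoothing_window_s >= 0, "smoothing_window_s must be >= 0")
  p
}

# centered moving average with edge truncation (window in samples)
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# topographic prominence of local maxima: for each peak, walk out to the
# nearest higher point on each side and take the higher of the two minima
# in between; edge-bounded sides use the minimum down to the signal edge.
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left_min <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < left_min) left_min <- x[i]
      i <- i - 1L
    }
    right_min <- h
    i <- p + 1L
    while (i <= length(x) && x[i] <= h) {
      if (x[i] < right_min) right_min <- x[i]
      i <- i + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

#' Detect gait-cycle boundaries from the right-ankle pitch signal
#'
#' Returns the half-open sample intervals `[start, end)` between successive
#' retained peaks of the (optionally smoothed) pitch angular-velocity
#' channel. Leading samples before the first peak and trailing samples
#' after the last are discarded (incomplete cycles). A signal with no
#' qualifying peaks yields an empty boundary set, not an error.
#'
#' @param trial A `vg_trial` with `placement == "ankle_right"` and
#'   `frame == "global"`.
#' @param params A [segmentation_params()].
#' @return An object of class `vg_boundaries`: data.frame with integer
#'   columns `start`, `end` (half-open), plus the detection parameters and
#'   retained peak indices as attributes.
#' @export
detect_cycles <- function(trial, params = segmentation_params()) {
  validate_trial(trial)
  check_that(trial$placement == "ankle_right",
             "detect_cycles requires the ankle_right recording, got '%s'",
             trial$placement, class = "vg_contract_error")
  check_that(trial$frame == "global",
             "detect_cycles requires a global-frame recording",
             class = "vg_contract_error")
  x <- trial$channels[.PITCH, ]
  fs <- trial$sampling_rate
  w <- max(1L, as.integer(round(params$smoothing_window_s * fs)))
  xs <- moving_average(x, w)
  cand <- local_maxima(xs)
  peaks <- integer()
  if (length(cand)) {
    prom <- peak_prominences(xs, cand)
    rng <- diff(stats::quantile(xs, c(0.05, 0.95), names = FALSE))
    peaks <- cand[prom >= params$min_peak_prominence * rng & prom > 0]
  }
  starts <- ends <- integer()
  if (length(peaks) >= 2L) {
    dur <- diff(peaks) / fs
    keep <- dur >= params$min_cycle_duration_s &
      dur <= params$max_cycle_duration_s
    starts <- peaks[-length(peaks)][keep]
    ends <- peaks[-1L][keep]
  }
  structure(data.frame(start = starts, end = ends),
            class = c("vg_boundaries", "data.frame"),
            params = params, peaks = peaks,
            source_placement = "ankle_right",
            sampling_rate = fs)
}

#' Slice all placements of a subject x task on shared boundaries
#'
#' Every placement is cut on the *same* boundaries detected from the right
#' ankle, so segment counts are identical across placements by
#' construction. All trials must share subject, task, sampling rate and
#' length.
#'
#' @param trials List of the subject's `vg_trial`s (one per placement).
#' @param boundaries A [detect_cycles()] result.
#' @return Named list (by placement) of lists of 6 x L segment matrices.
#' @export
slice_all_sensors <- function(trials, boundaries) {
  check_that(length(trials) >= 1L, "no trials supplied",
             class = "vg_contract_error")
  lens <- vapply(trials, function(tr) ncol(tr$channels), integer(1))
  subj <- unique(vapply(trials, `[[`, "", "subject_id"))
  task <- unique(vapply(trials, `[[`, "", "task"))
  rate <- unique(vapply(trials, `[[`, numeric(1), "sampling_rate"))
  check_that(length(subj) == 1L && length(task) == 1L && length(rate) == 1L,
             "trials must share subject, task and sampling rate",
             class = "vg_alignment_error")
  check_that(length(unique(lens)) == 1L,
             "trial lengths differ across placements (%s); cannot slice",
             paste(unique(lens), collapse = "/"), class = "vg_alignment_error")
  out <- lapply(trials, function(tr) {
    lapply(seq_len(nrow(boundaries)), function(k) {
      tr$channels[, boundaries$start[k]:(boundaries$end[k] - 1L), drop = FALSE]
    })
  })
  names(out) <- vapply(trials, `[[`, "", "placement")
  out
}

#' Resample a cycle segment to a fixed length
#'
#' Each row is evaluated at `target_length` positions linearly spaced from
#' the first to the last original sample inclusive (closed interval), by
#' piecewise-linear interpolation (`method = "linear"`, the gait-cycle
#' path) or cubic spline interpolation (`method = "cubic"`, used for
#' unsegmented activity windows). Endpoints are reproduced exactly, and an
#' input already of the target length is returned unchanged under linear
#' interpolation.
#'
#' @param segment 6 x L numeric matrix, L >= 2.
#' @param target_length Output length (default 512).
#' @param method `"linear"` or `"cubic"`.
#' @return A 6 x `target_length` matrix.
#' @export
resample_cycle <- function(segment, target_length = 512L,
                           method = c("linear", "cubic")) {
  method <- match.arg(method)
  check_that(is.matrix(segment) && nrow(segment) == 6L,
             "segment must be a 6 x L matrix", class = "vg_contract_error")
  L <- ncol(segment)
  check_that(L >= 2L, "degenerate cycle: need L >= 2, got %d", L,
             class = "vg_degenerate_error")
  if (method == "linear" && L == target_length) return(segment)
  xout <- seq(1, L, length.out = target_length)
  out <- matrix(0, 6L, target_length)
  for (r in seq_len(6L)) {
    out[r, ] <- if (method == "linear") {
      stats::approx(seq_len(L), segment[r, ], xout = xout)$y
    } else {
      stats::spline(seq_len(L), segment[r, ], xout = xout)$y
    }
  }
  rownames(out) <- rownames(segment)
  out
}

new_dataset <- function(x, meta, zero_cycle_subjects = character()) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == nrow(meta))
  structure(list(x = x, meta = meta),
            zero_cycle_subjects = zero_cycle_subjects,
            class = "vg_dataset")
}

#' @export
print.vg_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<vg_dataset> %d samples of %d x %d (%d subjects)\n",
              d[3], d[1], d[2], length(unique(x$meta$subject_id))))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds A `vg_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) dim(ds$x)[3]

#' Subset a cycle dataset by sample index
#' @param ds A `vg_dataset`.
#' @param idx Integer or logical index over samples.
#' @return A `vg_dataset`.
#' @export
subset_dataset <- function(ds, idx) {
  new_dataset(ds$x[, , idx, drop = FALSE],
              ds$meta[idx, , drop = FALSE])
}

#' Build the fixed-length cycle dataset for one placement
#'
#' For each subject: detect cycles on the right-ankle pitch signal, slice
#' the requested placement's recording on those boundaries, and resample
#' every segment to a 6 x `target_length` matrix. One sample is one gait
#' cycle of one subject. Subjects contributing zero cycles are flagged in
#' the `zero_cycle_subjects` attribute.
#'
#' @param cohort A `vg_cohort`.
#' @param placement Placement whose signals populate the samples.
#' @param task Task to segment (default: the cohort's task).
#' @param params A [segmentation_params()].
#' @param target_length Cycle length after resampling (default 512).
#' @return A `vg_dataset` with `x` of dim 6 x target_length x n and `meta`
#'   columns subject_id, group, cycle_index, placement, task.
#' @export
build_cycle_dataset <- function(cohort, placement,
                                task = cohort$config$task,
                                params = segmentation_params(),
                                target_length = 512L) {
  check_that(placement %in% vg_placements(), "unknown placement '%s'",
             placement)
  mats <- list()
  meta <- list()
  zero <- character()
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[i]
    ankle <- get_trial(cohort, sid, "ankle_right", task)
    b <- detect_cycles(ankle, params)
    if (nrow(b) == 0L) {
      zero <- c(zero, sid)
      next
    }
    target <- if (placement == "ankle_right") ankle else {
      get_trial(cohort, sid, placement, task)
    }
    segs <- slice_all_sensors(list(target), b)[[1]]
    for (k in seq_along(segs)) {
      mats[[length(mats) + 1L]] <- resample_cycle(segs[[k]], target_length)
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sid, group = cohort$subjects$group[i],
        cycle_index = k, placement = placement, task = task,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(mats)) {
    vg_stop("no cycles detected for any subject", class = "vg_data_error")
  }
  x <- array(unlist(mats, use.names = FALSE),
             c(6L, target_length, length(mats)))
  meta <- do.call(rbind, meta)
  meta$group <- factor(meta$group, levels = vg_groups())
  new_dataset(x, meta, zero_cycle_subjects = zero)
}

#' Resample every sample of a dataset to a new length
#'
#' Used to bring unsegmented activity windows (e.g. 6 x 300) onto the
#' model's 6 x 512 input grid with cubic interpolation.
#'
#' @param ds A `vg_dataset`.
#' @param target_length New sample length.
#' @param method Interpolation method, see [resample_cycle()].
#' @return A `vg_dataset`.
#' @export
resample_dataset <- function(ds, target_length = 512L, method = "cubic") {
  n <- n_samples(ds)
  x <- array(0, c(6L, target_length, n))
  for (i in seq_len(n)) {
    x[, , i] <- resample_cycle(ds$x[, , i], target_length, method)
  }
  new_dataset(x, ds$meta, attr(ds, "zero_cycle_subjects"))
}
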