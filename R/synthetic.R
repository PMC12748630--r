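#' Configuration for the synthetic gait cohort generator
#'
#' Describes a two-group cohort of quasi-periodic walkers recorded by six
#' body-worn IMUs. Each subject walks at an individual stride frequency;
#' every channel of every placement is a sum of `n_harmonics` sinusoids of
#' the subject's (jittered) stride phase, scaled by a subject-level random
#' effect and, for patients, by a per-channel group effect, plus additive
#' sensor noise. Defaults emulate a vestibular-deficit walking study: 32
#' subjects per group, 500 Hz sampling, ~1 stride/s, an 8 s short walk
#' (about 5-7 cycles/subject; a 30 s duration gives the long task).
#'
#' @param n_per_group Subjects per class (>= 2).
#' @param sampling_rate Sampling rate in Hz.
#' @param stride_freq_mean Mean stride frequency in Hz.
#' @param stride_freq_subject_sd Between-subject SD of stride frequency (Hz).
#' @param n_harmonics Number of stride harmonics per channel.
#' @param group_amplitude_effect Fractional change of patient channel
#'   amplitudes; the per-channel loading is given by `effect_weights`.
#' @param group_variability_effect Multiplier on patient cycle-duration
#'   jitter (1 = same as controls).
#' @param subject_random_effect_sd SD of the per-subject fractional
#'   amplitude random effect.
#' @param cycle_jitter_sd SD of the per-cycle lognormal duration jitter
#'   (on the log-period scale); 0 gives perfectly periodic gait.
#' @param noise_sd Additive noise SD per channel, as a fraction of that
#'   channel's base amplitude.
#' @param trial_duration_s Trial length in seconds (default 8 for the short
#'   task; use 30 for the long task). Must exceed two stride periods.
#' @param task Task label for the generated trials.
#' @param placements Placements to generate (default: all six).
#' @param effect_weights 6 x 6 numeric matrix (placements x channels) of
#'   group-effect loadings; patient amplitudes are multiplied by
#'   `1 - group_amplitude_effect * weight` (negative weights increase
#'   amplitude). Default: strongest loadings on head pitch/roll (reduced
#'   head motion) and on mediolateral trunk acceleration at waist/back
#'   (increased sway), with a mild loading everywhere else so every sensor
#'   carries some signal.
#' @param seed Integer seed; generation is deterministic given the config.
#'
#' @return An object of class `vg_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_per_group = 32L,
                          sampling_rate = 500,
                          stride_freq_mean = 1.0,
                          stride_freq_subject_sd = 0.06,
                          n_harmonics = 3L,
                          group_amplitude_effect = 0.2,
                          group_variability_effect = 1.5,
                          subject_random_effect_sd = 0.08,
                          cycle_jitter_sd = 0.02,
                          noise_sd = 0.05,
                          trial_duration_s = 8,
                          task = vg_tasks()[1],
                          placements = vg_placements(),
                          effect_weights = default_effect_weights(),
                          seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), sampling_rate = sampling_rate,
    stride_freq_mean = stride_freq_mean,
    stride_freq_subject_sd = stride_freq_subject_sd,
    n_harmonics = as.integer(n_harmonics),
    group_amplitude_effect = group_amplitude_effect,
    group_variability_effect = group_variability_effect,
    subject_random_effect_sd = subject_random_effect_sd,
    cycle_jitter_sd = cycle_jitter_sd, noise_sd = noise_sd,
    trial_duration_s = trial_duration_s, task = task,
    placements = placements, effect_weights = effect_weights,
    seed = as.integer(seed))
  class(cfg) <- "vg_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  check_that(cfg$n_per_group >= 2L, "n_per_group must be >= 2, got %d", cfg$n_per_group)
  check_that(cfg$sampling_rate > 0, "sampling_rate must be > 0")
  check_that(cfg$stride_freq_mean > 0, "stride_freq_mean must be > 0")
  check_that(cfg$n_harmonics >= 1L, "n_harmonics must be >= 1")
  check_that(cfg$trial_duration_s > 2 / cfg$stride_freq_mean,
             "trial_duration_s must exceed two stride periods (2/stride_freq_mean)")
  for (f in c("stride_freq_subject_sd", "group_amplitude_effect",
              "group_variability_effect", "subject_random_effect_sd",
              "cycle_jitter_sd", "noise_sd")) {
    check_that(cfg[[f]] >= 0, "%s must be >= 0", f)
  }
  check_that(all(cfg$placements %in% vg_placements()),
             "placements must be a subset of the six canonical placements")
  check_that("ankle_right" %in% cfg$placements,
             "placements must include ankle_right (the segmentation sensor)")
  check_that(cfg$task %in% vg_tasks(), "task must be one of: %s",
             paste(vg_tasks(), collapse = ", "))
  ew <- cfg$effect_weights
  check_that(is.matrix(ew) && all(dim(ew) == c(6L, 6L)),
             "effect_weights must be a 6 x 6 matrix (placements x channels)")
  invisible(cfg)
}

#' Default group-effect loading matrix
#'
#' Rows are the six placements, columns the six channels. Patients' channel
#' amplitudes are multiplied by `1 - effect * weight`, so positive weights
#' shrink a channel and negative weights amplify it. The strongest loadings
#' sit on head pitch/roll angular velocity (patients restrict head motion)
#' and, with negative sign, on mediolateral trunk acceleration at waist and
#' back (increased sway); a mild 0.25 loading everywhere else gives every
#' sensor some discriminative signal.
#'
#' @return A 6 x 6 numeric matrix with dimnames.
#' @export
default_effect_weights <- function() {
  w <- matrix(0.25, 6, 6, dimnames = list(vg_placements(), vg_channels()))
  w["head", c("gyro_pitch", "gyro_roll")] <- 1.0
  w[c("waist", "back"), "acc_ml"] <- -0.6
  w
}

#' Effect weights concentrated on a single placement
#'
#' Convenience for sensor-sweep fixtures: all group signal on one placement,
#' none anywhere else.
#'
#' @param placement The placement carrying the effect.
#' @param weight Loading applied to all six channels of that placement.
#' @return A 6 x 6 numeric matrix.
#' @export
focused_effect_weights <- function(placement, weight = 1.0) {
  check_that(placement %in% vg_placements(), "unknown placement '%s'", placement)
  w <- matrix(0, 6, 6, dimnames = list(vg_placements(), vg_channels()))
  w[placement, ] <- weight
  w
}

# base channel amplitudes per placement (rows) and channel (cols);
# accelerations in m/s^2, angular velocities in deg/s. The ankle pitch
# gyro dominates, as for a shank-mounted sensor during swing.
base_amplitudes <- function() {
  a <- rbind(
    wrist       = c(0.8, 0.6, 1.0, 60, 40, 30),
    ankle_left  = c(2.5, 1.2, 3.0, 250, 60, 40),
    ankle_right = c(2.5, 1.2, 3.0, 250, 60, 40),
    waist       = c(1.0, 0.8, 1.5, 30, 25, 20),
    back        = c(0.8, 0.7, 1.2, 25, 20, 15),
    head        = c(0.6, 0.5, 0.9, 30, 35, 25))
  colnames(a) <- vg_channels()
  a
}

# per-channel mean offsets (gravity on the vertical accelerometer)
base_offsets <- function() {
  o <- rep(0, 6)
  names(o) <- vg_channels()
  o["acc_v"] <- 9.81
  o
}

# harmonic weight profile: the ankle pitch channel is a pure fundamental
# so its swing peak sits exactly at stride phase 0.25 (the segmentation
# oracle relies on this); other channels carry richer harmonic content
harmonic_weights <- function(n_harmonics, ankle_pitch = FALSE) {
  if (ankle_pitch) return(c(1, numeric(n_harmonics - 1L)))
  base <- c(1, 0.45, 0.2)
  w <- base[seq_len(min(n_harmonics, 3L))]
  if (n_harmonics > 3L) w <- c(w, 0.1 / seq_len(n_harmonics - 3L))
  w
}

# deterministic (non-RNG) phase table so channels are mutually distinct;
# ankle pitch phases are zero so its dominant peak sits at stride phase 0.25
channel_phase <- function(p_idx, c_idx, h) {
  2 * pi * (((p_idx * 7L + c_idx * 3L + h * 5L) %% 11L) / 11)
}

# piecewise-linear stride phase over the sample grid given cycle periods
stride_phase <- function(t, periods) {
  tb <- cumsum(c(0, periods))
  k <- findInterval(t, tb, rightmost.closed = FALSE)
  k <- pmin(pmax(k, 1L), length(periods))
  (k - 1) + (t - tb[k]) / periods[k]
}

#' Generate a synthetic two-group IMU gait cohort
#'
#' Simulates `2 * n_per_group` subjects walking for `trial_duration_s`
#' seconds and returns one [trial_recording()] per subject x placement in a
#' common global frame, plus a subject manifest. Each channel is a sum of
#' stride-locked sinusoids with per-cycle lognormal duration jitter, a
#' subject-level amplitude random effect, patient-specific amplitude
#' scaling, and additive Gaussian noise. The right-ankle pitch channel has a
#' single dominant positive peak per stride (at stride phase 0.25), so
#' peak-based cycle segmentation is well posed; with zero jitter the peak
#' times are exactly `(k + 0.25) / stride_frequency`.
#'
#' Generation is fully deterministic given the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return An object of class `vg_cohort`: a list with `subjects` (a
#'   data.frame with subject_id, group, age, sex), `trials` (named list of
#'   `vg_trial` recordings), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_per_group
  ids <- c(sprintf("C%02d", seq_len(n)), sprintf("P%02d", seq_len(n)))
  groups <- rep(vg_groups(), each = n)
  amp0 <- base_amplitudes()[cfg$placements, , drop = FALSE]
  off <- base_offsets()
  t <- seq(0, cfg$trial_duration_s, by = 1 / cfg$sampling_rate)
  t <- t[t < cfg$trial_duration_s]

  subjects <- data.frame(
    subject_id = ids, group = groups,
    age = integer(length(ids)), sex = character(length(ids)),
    stringsAsFactors = FALSE)
  trials <- list()

  for (i in seq_along(ids)) {
    patient <- groups[i] == "patient"
    f <- cfg$stride_freq_mean +
      stats::rnorm(1, 0, cfg$stride_freq_subject_sd)
    f <- min(max(f, 0.5 * cfg$stride_freq_mean), 1.5 * cfg$stride_freq_mean)
    subj_scale <- max(1 + stats::rnorm(1, 0, cfg$subject_random_effect_sd), 0.2)
    subjects$age[i] <- as.integer(round(stats::runif(1, 45, 75)))
    subjects$sex[i] <- sample(c("male", "female"), 1)

    jit_sd <- cfg$cycle_jitter_sd *
      if (patient) cfg$group_variability_effect else 1
    n_cyc <- ceiling(cfg$trial_duration_s * f * 1.5) + 2L
    periods <- (1 / f) * exp(stats::rnorm(n_cyc, 0, jit_sd))
    while (sum(periods) < cfg$trial_duration_s) {
      periods <- c(periods, (1 / f) * exp(stats::rnorm(1, 0, jit_sd)))
    }
    phi <- stride_phase(t, periods)

    for (p in cfg$placements) {
      p_idx <- match(p, vg_placements())
      ch <- matrix(0, 6, length(t), dimnames = list(vg_channels(), NULL))
      for (c_idx in seq_len(6L)) {
        mult <- 1
        if (patient) {
          mult <- max(1 - cfg$group_amplitude_effect *
                        cfg$effect_weights[p_idx, c_idx], 0.05)
        }
        amp <- amp0[p, c_idx] * subj_scale * mult
        ankle_pitch <- p %in% c("ankle_left", "ankle_right") &&
          c_idx == .PITCH
        hw <- harmonic_weights(cfg$n_harmonics, ankle_pitch)
        y <- rep(off[c_idx], length(t))
        for (h in seq_along(hw)) {
          psi <- if (ankle_pitch) 0 else channel_phase(p_idx, c_idx, h)
          y <- y + amp * hw[h] * sin(2 * pi * h * phi + psi)
        }
        if (cfg$noise_sd > 0) {
          y <- y + stats::rnorm(length(t), 0, cfg$noise_sd * amp0[p, c_idx])
        }
        ch[c_idx, ] <- y
      }
      tr <- trial_recording(
        subject_id = ids[i], task = cfg$task, placement = p,
        channels = ch, sampling_rate = cfg$sampling_rate, frame = "global")
      trials[[trial_key(ids[i], cfg$task, p)]] <- tr
    }
  }
  structure(list(subjects = subjects, trials = trials, config = cfg),
            class = "vg_cohort")
}

trial_key <- function(subject_id, task, placement) {
  paste(subject_id, task, placement, sep = ".")
}

#' Retrieve one trial from a cohort
#'
#' @param cohort A `vg_cohort`.
#' @param subject_id,placement,task Identify the trial; `task` defaults to
#'   the cohort's generated task.
#' @return A `vg_trial`.
#' @export
get_trial <- function(cohort, subject_id, placement,
                      task = cohort$config$task) {
  key <- trial_key(subject_id, task, placement)
  tr <- cohort$trials[[key]]
  if (is.null(tr)) vg_stop("no trial '%s' in cohort", key, class = "vg_data_error")
  tr
}

#' @export
print.vg_cohort <- function(x, ...) {
  cat(sprintf("<vg_cohort> %d subjects (%d/group), task %s, %d trials\n",
              nrow(x$subjects), x$config$n_per_group, x$config$task,
              length(x$trials)))
  invisible(x)
}

#' Fixture cohort presets: the zero/weak/medium/strong effect ladder
#'
#' Canonical small-cohort study conditions used by the package's own
#' validation experiments: 8 subjects per group walking 8 s at 250 Hz
#' (about 6 gait cycles each), 5% channel noise, 8% subject amplitude
#' random effects, and a group amplitude effect of 0 (`zero`), 0.05
#' (`weak`), 0.15 (`medium`) or 0.4 (`strong`) under the default effect
#' loadings (strongest on the head sensor). The `zero` preset also
#' equalizes cycle-duration jitter across groups so the two classes are
#' statistically identical.
#'
#' @param level Effect level.
#' @param n_per_group,seed Passed to [cohort_config()].
#' @return A `vg_cohort_config`.
#' @export
cohort_presets <- function(level = c("zero", "weak", "medium", "strong"),
                           n_per_group = 8L, seed = 1L) {
  level <- match.arg(level)
  amp <- c(zero = 0, weak = 0.05, medium = 0.15, strong = 0.4)[[level]]
  var <- c(zero = 1, weak = 1.1, medium = 1.25, strong = 1.5)[[level]]
  cohort_config(n_per_group = n_per_group, sampling_rate = 250,
                trial_duration_s = 8, group_amplitude_effect = amp,
                group_variability_effect = var, noise_sd = 0.05,
                subject_random_effect_sd = 0.08, seed = seed)
}

#' Configuration for synthetic unsegmented activity windows
#'
#' Emulates a single-sensor human-activity-recognition source: fixed-length
#' windows (default 3 s at 100 Hz, i.e. 300 points) of two activity classes
#' (walking-like vs running-like) distinguished by their base movement
#' frequency. Windows are deliberately *not* segmented into gait cycles.
#'
#' @param n_windows_per_class Windows per class (>= 1).
#' @param window_duration_s Window length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param class_freq Length-2 named numeric: base frequency (Hz) of the
#'   `walk` and `run` classes. Equal values make the task unlearnable.
#' @param noise_sd Additive noise SD as a fraction of channel amplitude.
#' @param seed Integer seed.
#' @return An object of class `vg_window_config`.
#' @export
activity_config <- function(n_windows_per_class = 10L,
                            window_duration_s = 3,
                            sampling_rate = 100,
                            class_freq = c(walk = 1.2, run = 2.4),
                            noise_sd = 0.1,
                            seed = 1L) {
  cfg <- list(n_windows_per_class = as.integer(n_windows_per_class),
              window_duration_s = window_duration_s,
              sampling_rate = sampling_rate,
              class_freq = class_freq, noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "vg_window_config"
  check_that(cfg$n_windows_per_class >= 1L, "n_windows_per_class must be >= 1")
  check_that(cfg$window_duration_s > 0, "window_duration_s must be > 0")
  check_that(cfg$sampling_rate > 0, "sampling_rate must be > 0")
  check_that(length(cfg$class_freq) == 2L && all(cfg$class_freq > 0),
             "class_freq must be two positive frequencies")
  check_that(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  cfg
}

#' Generate synthetic activity windows
#'
#' Returns `2 * n_windows_per_class` labeled 6-channel windows of length
#' `round(window_duration_s * sampling_rate)`. Each window mixes the class
#' base frequency and its first harmonic with random per-window phases and
#' additive noise. Deterministic given the config.
#'
#' @param config An [activity_config()].
#' @return A `vg_dataset` whose `x` is a 6 x L x n array and whose
#'   `meta$group` is a factor with levels `walk` (negative class) and
#'   `run` (positive class).
#' @export
generate_activity_windows <- function(config) {
  stopifnot(inherits(config, "vg_window_config"))
  withr::with_seed(config$seed, generate_windows_impl(config))
}

generate_windows_impl <- function(cfg) {
  L <- as.integer(round(cfg$window_duration_s * cfg$sampling_rate))
  n <- 2L * cfg$n_windows_per_class
  t <- seq_len(L) / cfg$sampling_rate
  amp <- c(1, 0.8, 1.2, 0.9, 1.1, 0.7)
  classes <- rep(names(cfg$class_freq), each = cfg$n_windows_per_class)
  x <- array(0, c(6L, L, n))
  for (i in seq_len(n)) {
    f <- cfg$class_freq[[classes[i]]]
    for (c_idx in seq_len(6L)) {
      ph <- stats::runif(2, 0, 2 * pi)
      y <- amp[c_idx] * (sin(2 * pi * f * t + ph[1]) +
                           0.35 * sin(4 * pi * f * t + ph[2]))
      if (cfg$noise_sd > 0) {
        y <- y + stats::rnorm(L, 0, cfg$noise_sd * amp[c_idx])
      }
      x[c_idx, , i] <- y
    }
  }
  meta <- data.frame(
    subject_id = sprintf("W%04d", seq_len(n)),
    group = factor(classes, levels = names(cfg$class_freq)),
    cycle_index = seq_len(n),
    placement = "waist", task = "activity_window",
    stringsAsFactors = FALSE)
  new_dataset(x, meta)
}
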