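zero_jitter_cohort <- function(duration = 10, n = 2L) {
  generate_cohort(cohort_config(
    n_per_group = n, sampling_rate = 250, trial_duration_s = duration,
    stride_freq_mean = 1.0, stride_freq_subject_sd = 0,
    cycle_jitter_sd = 0, group_variability_effect = 1, noise_sd = 0.02,
    seed = 13L))
}

test_that("zero-jitter trials segment into the known interior cycle count", {
  co <- zero_jitter_cohort()
  for (id in co$subjects$subject_id) {
    b <- detect_cycles(get_trial(co, id, "ankle_right"))
    # peaks at t = 0.25 ... 9.25 -> 10 peaks, 9 complete [peak, peak) cycles
    expect_equal(nrow(b), 9L)
    expect_true(all(b$end > b$start))
    expect_true(all(diff(b$start) > 0))
    durations <- (b$end - b$start) / 250
    expect_equal(durations, rep(1, 9L), tolerance = 0.02)
  }
})

test_that("degenerate signals yield empty boundaries, wrong placement errors", {
  flat <- trial_recording("S", "level_walk_short", "ankle_right",
                          matrix(0, 6, 500), 100, "global")
  expect_equal(nrow(detect_cycles(flat)), 0L)
  co <- unit_cohort()
  expect_error(detect_cycles(get_trial(co, "C01", "wrist")),
               "ankle_right", class = "vg_contract_error")
})

test_that("low-prominence wiggles between true peaks do not add boundaries", {
  fs <- 200
  t <- seq(0, 8, by = 1 / fs)[-1]
  base <- sin(2 * pi * t)
  wiggled <- base + 0.04 * sin(2 * pi * 11 * t)
  mk <- function(x) trial_recording("S", "level_walk_short", "ankle_right",
                                    rbind(0, 0, 0, x, 0, 0), fs, "global")
  params <- segmentation_params(min_peak_prominence = 0.3,
                                smoothing_window_s = 0)
  b0 <- detect_cycles(mk(base), params)
  b1 <- detect_cycles(mk(wiggled), params)
  expect_equal(nrow(b1), nrow(b0))
  # the wiggle may nudge each true peak slightly but adds no boundaries
  expect_true(all(abs(b1$start - b0$start) <= 0.1 * fs))
})

test_that("cycles outside the duration window are discarded, not merged", {
  fs <- 100
  # peaks at 1, 2, 2.2, 3.2 s: the 1 s gaps pass, the 0.2 s gap is dropped
  t <- seq(0, 4, by = 1 / fs)[-1]
  x <- numeric(length(t))
  for (pk in c(1, 2, 2.2, 3.2)) x <- x + exp(-((t - pk) / 0.03)^2)
  tr <- trial_recording("S", "level_walk_short", "ankle_right",
                        rbind(0, 0, 0, x, 0, 0), fs, "global")
  b <- detect_cycles(tr, segmentation_params(min_cycle_duration_s = 0.6,
                                             max_cycle_duration_s = 2.0,
                                             smoothing_window_s = 0))
  expect_equal(nrow(b), 2L)
  expect_equal(b$start / fs, c(1, 2.2), tolerance = 0.02)
})

test_that("all placements are sliced on the shared ankle boundaries", {
  co <- unit_cohort()
  trials <- lapply(vg_placements(), function(p) get_trial(co, "C01", p))
  b <- detect_cycles(trials[[which(vg_placements() == "ankle_right")]])
  segs <- slice_all_sensors(trials, b)
  expect_named(segs, vg_placements())
  counts <- lengths(segs)
  expect_true(all(counts == nrow(b)))
  # empty boundaries: zero segments, no error
  empty <- b[0, ]
  attributes(empty) <- attributes(b)
  expect_true(all(lengths(slice_all_sensors(trials, b[0, ])) == 0L))
  # truncated trial across placements is an alignment error
  short <- trials[[1]]
  short$channels <- short$channels[, 1:100]
  expect_error(slice_all_sensors(c(list(short), trials[-1]), b),
               "lengths differ", class = "vg_alignment_error")
})

test_that("resampling is exact on identity, affine, and smooth inputs", {
  m <- matrix(rnorm(6 * 512), 6, 512)
  expect_identical(resample_cycle(m, 512L), m)
  ramp <- matrix(rep(seq(0, 3, length.out = 4), each = 6), 6, 4)
  out <- resample_cycle(ramp, 512L)
  expect_equal(out[1, ], seq(0, 3, length.out = 512))
  expect_equal(out[, 1], ramp[, 1])    # endpoints preserved exactly
  expect_equal(out[, 512], ramp[, 4])
  # monotone rows stay monotone under linear interpolation
  expect_true(all(diff(out[1, ]) >= 0))
  # sine oracle: closed-form comparison at the target times
  L <- 1000L
  tt <- seq(0, 1, length.out = L)
  sine <- matrix(rep(sin(2 * pi * tt), each = 6), 6, L, byrow = FALSE)
  res <- resample_cycle(sine, 512L)
  t512 <- seq(0, 1, length.out = 512)
  expect_lt(max(abs(res[1, ] - sin(2 * pi * t512))), 1e-4)
  expect_error(resample_cycle(sine[, 1, drop = FALSE]), "L >= 2",
               class = "vg_degenerate_error")
})

test_that("cubic resampling reproduces smooth signals more closely", {
  L <- 60L
  tt <- seq(0, 1, length.out = L)
  sine <- matrix(rep(sin(2 * pi * tt), each = 6), 6, L)
  t512 <- seq(0, 1, length.out = 512)
  lin <- max(abs(resample_cycle(sine, 512L, "linear")[1, ] - sin(2 * pi * t512)))
  cub <- max(abs(resample_cycle(sine, 512L, "cubic")[1, ] - sin(2 * pi * t512)))
  expect_lt(cub, lin)
})

test_that("cycle datasets share per-subject counts across placements", {
  co <- unit_cohort()
  ds_wrist <- build_cycle_dataset(co, "wrist")
  ds_head <- build_cycle_dataset(co, "head")
  expect_equal(dim(ds_wrist$x)[1:2], c(6L, 512L))
  expect_true(all(is.finite(ds_wrist$x)))
  counts_w <- table(ds_wrist$meta$subject_id)
  counts_h <- table(ds_head$meta$subject_id)
  expect_equal(as.vector(counts_w), as.vector(counts_h))
  expect_equal(names(counts_w), names(counts_h))
  # labels match the manifest group of each subject
  lab <- unique(ds_wrist$meta[, c("subject_id", "group")])
  man <- co$subjects[match(lab$subject_id, co$subjects$subject_id), ]
  expect_equal(as.character(lab$group), man$group)
})

test_that("subjects too short to contain a cycle are flagged, not dropped silently", {
  co <- unit_cohort()
  for (p in vg_placements()) {
    key <- vestgait:::trial_key("C02", co$config$task, p)
    co$trials[[key]]$channels <- co$trials[[key]]$channels[, 1:200]
  }
  ds <- build_cycle_dataset(co, "wrist")
  expect_true("C02" %in% attr(ds, "zero_cycle_subjects"))
  expect_false("C02" %in% ds$meta$subject_id)
})
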