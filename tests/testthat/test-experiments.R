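test_that("transfer deltas satisfy finetuned = baseline + delta exactly", {
  base <- vg_reference("sensor_accuracy")
  base_short <- aggregate_sensor_table(data.frame(
    sensor = base$sensor[base$task == "level_walk_short"],
    control = base$control[base$task == "level_walk_short"],
    patient = base$patient[base$task == "level_walk_short"]))
  ft <- vg_reference("transfer_accuracy")
  kuhar <- aggregate_sensor_table(data.frame(
    sensor = ft$sensor[ft$scenario == "activity_windows"],
    control = ft$control[ft$scenario == "activity_windows"],
    patient = ft$patient[ft$scenario == "activity_windows"]))
  deltas <- transfer_delta(kuhar, base_short)
  expect_equal(deltas$control_delta[deltas$sensor == "wrist"], 0.0743)
  expect_equal(deltas$control + 0, base_short$control[
    match(deltas$sensor, base_short$sensor)] + deltas$control_delta)
  scds <- aggregate_sensor_table(data.frame(
    sensor = ft$sensor[ft$scenario == "pathology_cohort"],
    control = ft$control[ft$scenario == "pathology_cohort"],
    patient = ft$patient[ft$scenario == "pathology_cohort"]))
  d2 <- transfer_delta(scds, base_short)
  expect_equal(d2$control_delta[d2$sensor == "Mean"], 0.0998)
  expect_equal(d2$patient_delta[d2$sensor == "Mean"], 0.0644)
})

test_that("pathology pretraining validation mean matches the printed table", {
  pre <- vg_reference("pretrain_validation")
  scds <- pre$performance[pre$dataset == "pathology_cohort"]
  expect_equal(round(mean(scds), 4), 0.7180)
})

test_that("subject subsampling is stratified and without replacement", {
  ds <- strong_head_ds()
  for (f in c(0.25, 0.5, 0.75)) {
    sub <- withr::with_seed(3L, vestgait:::draw_subject_subset(ds, f))
    kept <- unique(sub$meta[, c("subject_id", "group")])
    expect_equal(as.vector(table(kept$group)),
                 rep(max(round(f * 8), 2), 2))
    expect_equal(anyDuplicated(kept$subject_id), 0L)
  }
  expect_error(withr::with_seed(1L, vestgait:::draw_subject_subset(ds, 0.1)),
               "< 2 subjects", class = "vg_contract_error")
})

test_that("sample subsampling keeps every subject with at least one cycle", {
  ds <- strong_head_ds()
  sub <- withr::with_seed(5L, vestgait:::draw_sample_subset(ds, 0.25))
  counts_before <- table(ds$meta$subject_id)
  counts_after <- table(sub$meta$subject_id)
  expect_setequal(names(counts_after), names(counts_before))
  expect_true(all(counts_after >= 1))
  expect_equal(as.vector(counts_after),
               as.vector(pmax(round(0.25 * counts_before), 1)))
})

test_that("fraction 1 reproduces the unablated baseline exactly", {
  ds <- strong_head_ds()
  small <- subset_dataset(ds, ds$meta$subject_id %in%
                            c("C01", "C02", "C03", "P01", "P02", "P03"))
  spec <- tiny_spec()
  cfg <- tiny_config(epochs = 4L)
  baseline <- run_loocv(small, spec, cfg)
  ab <- ablate(small, ablation_config("subjects", fractions = 1,
                                      iterations = 1L, seed = 2L),
               spec, cfg)
  expect_equal(ab$table$mean, baseline$overall)
  ab2 <- ablate(small, ablation_config("samples", fractions = 1,
                                       iterations = 1L, seed = 2L),
                spec, cfg)
  expect_equal(ab2$table$mean, baseline$overall)
})

test_that("a sensor sweep ranks the placement carrying the group effect first", {
  cfg_cohort <- cohort_config(
    n_per_group = 4L, sampling_rate = 250, trial_duration_s = 8,
    group_amplitude_effect = 0.4, noise_sd = 0.05,
    effect_weights = focused_effect_weights("head"), seed = 17L)
  co <- generate_cohort(cfg_cohort)
  sw <- sensor_sweep(co, tiny_spec(), tiny_config(epochs = 5L),
                     placements = c("head", "wrist"))
  expect_named(sw$reports, c("head", "wrist"))
  expect_gte(sw$reports[["head"]]$overall, sw$reports[["wrist"]]$overall)
  expect_gte(sw$reports[["head"]]$overall, 0.75)
  # identical call reproduces the sweep
  sw2 <- sensor_sweep(co, tiny_spec(), tiny_config(epochs = 5L),
                      placements = c("head", "wrist"))
  expect_equal(sw$table, sw2$table)
})

test_that("transfer experiment wires pretraining into per-fold fine-tuning", {
  co <- generate_cohort(cohort_presets("strong", n_per_group = 3L,
                                       seed = 19L))
  base_tab <- data.frame(sensor = "head", control = 0.5, patient = 0.5)
  tr <- transfer_experiment(
    co, activity_source(), tiny_spec(),
    pretrain_cfg = train_config(epochs = 6L, batch_size = 64L,
                                learning_rate = 0.01, seed = 5L),
    finetune_cfg = tiny_finetune(),
    baseline_table = base_tab, placements = "head", n_folds = 3L)
  expect_gte(tr$pretrain$val_accuracy, 0.8)
  expect_equal(tr$deltas$control,
               base_tab$control + tr$deltas$control_delta)
  expect_true(all(c("head", "Mean") %in% tr$table$sensor))
})
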