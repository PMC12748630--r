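test_that("accuracy and F1 follow the confusion-count formulas", {
  expect_equal(accuracy(confusion_counts(1, 1, 0, 0)), 1)
  expect_equal(accuracy(confusion_counts(3, 2, 1, 2)), 0.625)
  expect_equal(accuracy(confusion_counts(0, 0, 1, 1)), 0)
  expect_error(accuracy(confusion_counts(0, 0, 0, 0)), "zero total",
               class = "vg_undefined_metric")
  f <- f1_score(confusion_counts(3, 2, 1, 2))
  expect_equal(f$f1, 6 / 9)
  expect_false(f$undefined)
  expect_equal(f1_score(confusion_counts(5, 5, 0, 0))$f1, 1)
  expect_true(f1_score(confusion_counts(0, 4, 0, 0))$undefined)
})

test_that("per-subject accuracy is the fraction of correctly labeled cycles", {
  expect_equal(subject_accuracy(rep("patient", 5), "patient"), 1)
  expect_equal(subject_accuracy(c("patient", "patient", "control",
                                  "control", "control"), "patient"), 0.4)
  expect_equal(subject_accuracy("control", "patient"), 0)
  expect_error(subject_accuracy(character(), "patient"), "zero cycles",
               class = "vg_undefined_metric")
})

test_that("paired folds hold out each subject exactly once", {
  subj <- data.frame(subject_id = c("C2", "C1", "P1", "P2"),
                     group = c("control", "control", "patient", "patient"))
  folds <- make_loocv_folds(subj)
  expect_length(folds, 2L)
  expect_equal(folds[[1]], list(control = "C1", patient = "P1"))
  expect_equal(folds[[2]], list(control = "C2", patient = "P2"))
  big <- data.frame(subject_id = c(sprintf("C%02d", 1:32),
                                   sprintf("P%02d", 1:32)),
                    group = rep(c("control", "patient"), each = 32))
  expect_length(make_loocv_folds(big), 32L)
  held <- unlist(lapply(make_loocv_folds(big), unlist))
  expect_setequal(held, big$subject_id)
  expect_equal(anyDuplicated(held), 0L)
  # unequal groups: paired folds then singletons, with a warning
  uneq <- data.frame(subject_id = c("C1", "C2", "C3", "P1", "P2"),
                     group = c(rep("control", 3), rep("patient", 2)))
  expect_warning(folds_u <- make_loocv_folds(uneq), "unequal")
  expect_length(folds_u, 3L)
  expect_true(is.na(folds_u[[3]]$patient))
  expect_error(make_loocv_folds(uneq[c(1, 4, 5), ]), ">= 2",
               class = "vg_contract_error")
})

test_that("leave-one-out reports are deterministic and leakage-free", {
  ds <- strong_head_ds()
  small <- subset_dataset(ds, ds$meta$subject_id %in%
                            c("C01", "C02", "C03", "P01", "P02", "P03"))
  spec <- tiny_spec()
  cfg <- tiny_config(epochs = 4L)
  r1 <- run_loocv(small, spec, cfg)
  r2 <- run_loocv(small, spec, cfg)
  expect_identical(r1$per_subject, r2$per_subject)
  expect_equal(nrow(r1$per_subject), 6L)
  expect_setequal(r1$per_subject$subject_id, unique(small$meta$subject_id))
  # aggregation identity: overall = mean of the two group means
  expect_equal(r1$overall, mean(c(r1$control_mean, r1$patient_mean)))
  # pooled confusion total equals the number of held-out cycles
  cc <- r1$confusion
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n_samples(small))
  expect_true(all(r1$per_subject$accuracy >= 0 & r1$per_subject$accuracy <= 1))
})

test_that("sensor tables aggregate with an unweighted Mean row", {
  tab <- aggregate_sensor_table(data.frame(
    sensor = vg_placements(),
    control = c(0.6, 0.5, 0.7, 0.55, 0.65, 0.6),
    patient = c(0.5, 0.6, 0.6, 0.65, 0.55, 0.7)))
  expect_equal(tab$average, (tab$control + tab$patient) / 2)
  mean_row <- tab[tab$sensor == "Mean", ]
  expect_equal(mean_row$control, mean(tab$control[tab$sensor != "Mean"]))
  # single placement: Mean row equals that placement's row
  expect_warning(
    one <- aggregate_sensor_table(data.frame(sensor = "wrist",
                                             control = 0.7, patient = 0.6)),
    "incomplete")
  expect_equal(one$control[2], one$control[1])
})

test_that("published sensor accuracies reproduce the printed aggregates", {
  ref <- vg_reference("sensor_accuracy")
  tabs <- lapply(split(ref, ref$task), function(d) {
    aggregate_sensor_table(data.frame(sensor = d$sensor,
                                      control = d$control,
                                      patient = d$patient))
  })
  short <- tabs[["level_walk_short"]]
  expect_equal(short$control[short$sensor == "Mean"], 0.6005)
  expect_equal(short$average[short$sensor == "Mean"], 0.6062)
  overall <- aggregate_task_table(tabs)
  both <- overall[overall$task == "Average of both tasks", ]
  expect_equal(both$control, 0.6235)
  expect_equal(both$patient, 0.6233)
  expect_equal(both$average, 0.6234)
})

test_that("clinical score summaries reproduce the printed mean and SD", {
  fga <- vg_reference("fga_scores")
  ctrl <- clinical_score_summary(setNames(fga$control, fga$score))
  expect_equal(ctrl$mean_display, 2.81)
  expect_equal(ctrl$sd_display, 0.40)
  pat <- clinical_score_summary(setNames(fga$patient, fga$score))
  expect_equal(pat$mean_display, 2.81)
  expect_equal(pat$sd_display, 0.47)
  all3 <- clinical_score_summary(c("3" = 12))
  expect_equal(all3$mean_display, 3)
  expect_equal(all3$sd_display, 0)
  expect_error(clinical_score_summary(c("2" = 0, "3" = 0)), "positive total",
               class = "vg_contract_error")
})

test_that("sample-share tables reproduce the printed percentages", {
  counts <- vg_reference("sample_counts")
  shares <- sample_share_table(counts)
  expect_equal(shares$pct[shares$task == "level_walk_short" &
                            shares$type == "patient"], 50.96)
  expect_equal(shares$pct[shares$task == "slow_blink_walk_long" &
                            shares$type == "control"], 49.53)
  pre <- sample_share_table(vg_reference("pretrain_sample_counts"),
                            by = "dataset")
  expect_equal(pre$pct[pre$type == "walking"], 59.72)
  expect_equal(pre$pct[pre$type == "running"], 40.28)
})
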