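#' Confusion counts and accuracy
#'
#' The positive class is `patient`. `accuracy()` is
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return `confusion_counts()` returns a named list of class
#'   `vg_confusion`; `accuracy()` a value in `[0, 1]`.
#' @export
confusion_counts <- function(tp = 0L, tn = 0L, fp = 0L, fn = 0L) {
  counts <- list(tp = tp, tn = tn, fp = fp, fn = fn)
  check_that(all(unlist(counts) >= 0), "confusion counts must be >= 0",
             class = "vg_contract_error")
  structure(counts, class = "vg_confusion")
}

#' @param counts A [confusion_counts()].
#' @rdname confusion_counts
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  check_that(total > 0, "accuracy undefined: zero total count",
             class = "vg_undefined_metric")
  (counts$tp + counts$tn) / total
}

#' F1 score from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)` on pooled cycle-level counts. Returns `NA`
#' with an `undefined` flag when no positives are predicted or present.
#'
#' @param counts A [confusion_counts()] (or a `vg_report`, whose pooled
#'   counts are used).
#' @return A list with `f1` (possibly `NA`), `undefined`, and the counts.
#' @export
f1_score <- function(counts) {
  if (inherits(counts, "vg_report")) counts <- counts$confusion
  denom <- 2 * counts$tp + counts$fp + counts$fn
  if (denom == 0) {
    return(list(f1 = NA_real_, undefined = TRUE, counts = counts))
  }
  list(f1 = 2 * counts$tp / denom, undefined = FALSE, counts = counts)
}

#' Per-subject cycle accuracy
#'
#' Fraction of one subject's cycles classified with the subject's true
#' label. Zero cycles is a contract error (such subjects are flagged by
#' the dataset builder and excluded upstream, never silently scored 0).
#'
#' @param predicted Character vector of predicted labels for the subject's
#'   cycles.
#' @param true_label The subject's group.
#' @return Value in `[0, 1]`.
#' @export
subject_accuracy <- function(predicted, true_label) {
  check_that(length(predicted) >= 1L,
             "subject has zero cycles; accuracy undefined",
             class = "vg_undefined_metric")
  mean(predicted == true_label)
}

#' Paired leave-one-out folds
#'
#' One fold per per-group rank: each group is sorted by subject id and
#' paired by rank, so every subject is held out exactly once and folds are
#' deterministic. With unequal group sizes, `min(n)` paired folds are
#' followed by singleton folds for the larger group's leftovers, with a
#' warning.
#'
#' @param subjects Manifest data frame (columns subject_id, group) or a
#'   `vg_dataset` (its distinct subjects are used).
#' @return List of folds, each `list(control = id-or-NA, patient =
#'   id-or-NA)`.
#' @export
make_loocv_folds <- function(subjects) {
  if (inherits(subjects, "vg_dataset")) {
    subjects <- unique(subjects$meta[, c("subject_id", "group")])
  }
  controls <- sort(subjects$subject_id[subjects$group == "control"])
  patients <- sort(subjects$subject_id[subjects$group == "patient"])
  check_that(length(controls) >= 2L && length(patients) >= 2L,
             "need >= 2 subjects per group for paired leave-one-out",
             class = "vg_contract_error")
  n <- min(length(controls), length(patients))
  folds <- lapply(seq_len(n), function(i) {
    list(control = controls[i], patient = patients[i])
  })
  if (length(controls) != length(patients)) {
    warning("unequal group sizes; leftover subjects held out in singleton folds")
    extra <- if (length(controls) > n) {
      lapply(controls[(n + 1L):length(controls)],
             function(id) list(control = id, patient = NA_character_))
    } else {
      lapply(patients[(n + 1L):length(patients)],
             function(id) list(control = NA_character_, patient = id))
    }
    folds <- c(folds, extra)
  }
  folds
}

#' Run paired leave-one-out cross-validation
#'
#' For each fold: fit the range normalization on the training cycles only,
#' train a fresh model (or fine-tune the given checkpoint with a frozen
#' convolutional stage), predict every cycle of the held-out control and
#' patient, and record per-subject accuracies. Fold `i` derives its
#' initialization and training seeds as `seed + i`, so the whole run is
#' reproducible. Train/test subject disjointness is asserted at runtime.
#'
#' Final accuracies are the mean of per-subject means within each group;
#' the overall value is the mean of the two group means.
#'
#' @param ds A `vg_dataset` with >= 2 subjects per group.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param checkpoint Optional pretrained `vg_model`/`vg_pretrain`; when
#'   given, each fold fine-tunes it (dense stage only) instead of training
#'   from scratch, using `finetune_cfg`.
#' @param finetune_cfg A [finetune_config()], used with `checkpoint`.
#' @return An object of class `vg_report`: `per_subject` data frame
#'   (subject_id, group, n_cycles, accuracy), `control_mean`,
#'   `patient_mean`, `overall`, pooled `confusion`, `predictions`, and
#'   identifiers.
#' @export
run_loocv <- function(ds, spec, config = train_config(),
                      checkpoint = NULL, finetune_cfg = finetune_config()) {
  if (inherits(checkpoint, "vg_pretrain")) checkpoint <- checkpoint$model
  folds <- make_loocv_folds(ds)
  subj <- ds$meta$subject_id
  per_subject <- list()
  preds <- list()
  cc <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(folds)) {
    held <- stats::na.omit(unlist(folds[[i]], use.names = FALSE))
    test_idx <- which(subj %in% held)
    train_idx <- which(!subj %in% held)
    stopifnot(length(intersect(subj[train_idx], subj[test_idx])) == 0L)
    norm <- fit_range(ds$x[, , train_idx, drop = FALSE])
    xtr <- apply_range(norm, ds$x[, , train_idx, drop = FALSE])
    ytr <- as_binary_labels(ds$meta$group[train_idx])
    if (is.null(checkpoint)) {
      m <- build_model(modify_seed(spec, spec$seed + i))
      cfg_i <- config
      cfg_i$seed <- as.integer((config$seed + i) %% .Machine$integer.max)
      m <- train_model(m, xtr, ytr, cfg_i)
    } else {
      cfg_i <- finetune_cfg
      cfg_i$seed <- as.integer((finetune_cfg$seed + i) %% .Machine$integer.max)
      m <- finetune_model(checkpoint, xtr, ytr, cfg_i)
    }
    m$norm <- norm
    for (id in held) {
      idx <- which(subj == id)
      if (!length(idx)) next
      p <- forward(m, apply_range(norm, ds$x[, , idx, drop = FALSE]))
      lab <- predict_label(p, spec$threshold)
      truth <- as.character(ds$meta$group[idx][1])
      per_subject[[id]] <- data.frame(
        subject_id = id, group = truth, n_cycles = length(idx),
        accuracy = subject_accuracy(lab, truth), stringsAsFactors = FALSE)
      preds[[id]] <- data.frame(subject_id = id, group = truth,
                                cycle_index = ds$meta$cycle_index[idx],
                                prob = p, label = lab,
                                stringsAsFactors = FALSE)
      cc["tp"] <- cc["tp"] + sum(lab == "patient" & truth == "patient")
      cc["tn"] <- cc["tn"] + sum(lab == "control" & truth == "control")
      cc["fp"] <- cc["fp"] + sum(lab == "patient" & truth == "control")
      cc["fn"] <- cc["fn"] + sum(lab == "control" & truth == "patient")
    }
  }
  per_subject <- do.call(rbind, per_subject)
  rownames(per_subject) <- NULL
  ctrl <- per_subject$accuracy[per_subject$group == "control"]
  pat <- per_subject$accuracy[per_subject$group == "patient"]
  report <- structure(list(
    per_subject = per_subject,
    control_mean = mean(ctrl), patient_mean = mean(pat),
    overall = mean(c(mean(ctrl), mean(pat))),
    confusion = confusion_counts(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]]),
    predictions = do.call(rbind, preds),
    placement = ds$meta$placement[1], task = ds$meta$task[1],
    n_folds = length(folds)), class = "vg_report")
  report
}

#' @export
print.vg_report <- function(x, ...) {
  cat(sprintf(
    "<vg_report> %s / %s: control %.4f, patient %.4f, overall %.4f (%d folds)\n",
    x$task, x$placement, x$control_mean, x$patient_mean, x$overall,
    x$n_folds))
  invisible(x)
}

#' Aggregate per-sensor accuracies into a summary table
#'
#' Accepts either a named list of `vg_report`s (one per placement) or a
#' data frame with columns `sensor`, `control`, `patient`. Adds an
#' `average` column (mean of the two group columns per row) and a final
#' `Mean` row (unweighted arithmetic mean over placements, per column).
#' A missing placement triggers an incomplete-table warning.
#'
#' @param x Reports or a sensor/control/patient data frame.
#' @param digits Rounding for display (default 4, `NA` = none).
#' @return A data frame with rows per sensor plus `Mean`.
#' @export
aggregate_sensor_table <- function(x, digits = 4L) {
  if (!is.data.frame(x)) {
    tab <- data.frame(
      sensor = vapply(x, function(r) as.character(r$placement), ""),
      control = vapply(x, function(r) r$control_mean, numeric(1)),
      patient = vapply(x, function(r) r$patient_mean, numeric(1)),
      stringsAsFactors = FALSE)
  } else {
    tab <- x[, c("sensor", "control", "patient")]
  }
  if (!all(vg_placements() %in% tab$sensor)) {
    warning(sprintf("incomplete sensor table: missing %s",
                    paste(setdiff(vg_placements(), tab$sensor), collapse = ", ")))
  }
  tab$average <- (tab$control + tab$patient) / 2
  mean_row <- data.frame(sensor = "Mean",
                         control = mean(tab$control),
                         patient = mean(tab$patient),
                         average = mean(tab$average),
                         stringsAsFactors = FALSE)
  out <- rbind(tab, mean_row)
  rownames(out) <- NULL
  if (!is.na(digits)) {
    num <- c("control", "patient", "average")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' Average the Mean rows of several per-task sensor tables
#'
#' Builds the cross-task summary: one `Mean` row per task plus an
#' `Average of both tasks` row containing the unweighted means of the
#' per-task Mean rows.
#'
#' @param tables Named list of [aggregate_sensor_table()] outputs (one per
#'   task).
#' @param digits Rounding for display.
#' @return A data frame with one row per task plus the overall row.
#' @export
aggregate_task_table <- function(tables, digits = 4L) {
  rows <- lapply(names(tables), function(nm) {
    m <- tables[[nm]][tables[[nm]]$sensor == "Mean", ]
    data.frame(task = nm, control = m$control, patient = m$patient,
               average = m$average, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  overall <- data.frame(task = "Average of both tasks",
                        control = mean(tab$control),
                        patient = mean(tab$patient),
                        average = mean(tab$average),
                        stringsAsFactors = FALSE)
  out <- rbind(tab, overall)
  if (!is.na(digits)) {
    num <- c("control", "patient", "average")
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' Summarize an integer clinical-score distribution
#'
#' Weighted mean and sample standard deviation (n - 1 denominator) of an
#' integer score (0-3 for a Functional Gait Assessment item) given counts
#' per score value.
#'
#' @param counts Named numeric vector: names are score values, entries the
#'   number of subjects with that score.
#' @param digits Rounding for the display fields (default 2).
#' @return List with `mean`, `sd`, `n`, and rounded `mean_display`,
#'   `sd_display`.
#' @export
clinical_score_summary <- function(counts, digits = 2L) {
  scores <- as.numeric(names(counts))
  check_that(!anyNA(scores), "counts must be named by score values")
  check_that(all(counts >= 0) && sum(counts) > 0,
             "need non-negative counts with a positive total",
             class = "vg_contract_error")
  n <- sum(counts)
  m <- sum(scores * counts) / n
  v <- if (n > 1) sum(counts * (scores - m)^2) / (n - 1) else 0
  s <- sqrt(v)
  list(mean = m, sd = s, n = n,
       mean_display = round(m, digits), sd_display = round(s, digits))
}

#' Percentage shares of sample counts within a grouping
#'
#' Adds a `pct` column: each row's `n_samples` as a percentage of the
#' total row (`type == total_label`) of its `by` group, rounded to 2
#' decimals as in the study tables.
#'
#' @param df Data frame with columns `by` (grouping), `type`, `n_samples`.
#' @param by Grouping column name (default `"task"`).
#' @param total_label `type` value of the total row (default `"All"`).
#' @return `df` with a `pct` column.
#' @export
sample_share_table <- function(df, by = "task", total_label = "All") {
  totals <- df$n_samples[df$type == total_label]
  names(totals) <- df[[by]][df$type == total_label]
  check_that(!anyNA(totals[df[[by]]]), "every %s group needs an '%s' row",
             by, total_label)
  df$pct <- round(100 * df$n_samples / totals[df[[by]]], 2)
  df
}
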