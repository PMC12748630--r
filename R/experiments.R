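#' Sensor-placement sweep
#'
#' One independent leave-one-out cross-validation per placement with an
#' identical model spec and training configuration, plus the aggregated
#' summary table.
#'
#' @param cohort A `vg_cohort`.
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @param placements Placements to sweep (default: all six).
#' @param seg_params A [segmentation_params()].
#' @return List of class `vg_sweep`: `reports` (named by placement) and
#'   `table` ([aggregate_sensor_table()] output).
#' @export
sensor_sweep <- function(cohort, spec, config = train_config(),
                         placements = vg_placements(),
                         seg_params = segmentation_params()) {
  reports <- lapply(placements, function(p) {
    ds <- build_cycle_dataset(cohort, p, params = seg_params,
                              target_length = spec$input_shape[2])
    run_loocv(ds, spec, config)
  })
  names(reports) <- placements
  structure(list(reports = reports,
                 table = suppressWarnings(aggregate_sensor_table(reports))),
            class = "vg_sweep")
}

#' Element-wise deltas of a fine-tuned table against a baseline
#'
#' Cells satisfy `finetuned = baseline + delta` exactly; rows are matched
#' by sensor name. Mean rows, when present in both, are differenced too.
#'
#' @param finetuned,baseline Data frames with columns `sensor`, `control`,
#'   `patient` (e.g. [aggregate_sensor_table()] outputs).
#' @return Data frame with sensor, the fine-tuned accuracies, and
#'   `control_delta` / `patient_delta` columns.
#' @export
transfer_delta <- function(finetuned, baseline) {
  idx <- match(finetuned$sensor, baseline$sensor)
  check_that(!anyNA(idx), "baseline table lacks sensors: %s",
             paste(finetuned$sensor[is.na(idx)], collapse = ", "))
  data.frame(sensor = finetuned$sensor,
             control = finetuned$control, patient = finetuned$patient,
             control_delta = finetuned$control - baseline$control[idx],
             patient_delta = finetuned$patient - baseline$patient[idx],
             stringsAsFactors = FALSE)
}

#' Transfer-learning experiment
#'
#' Pretrains on a source dataset, then per placement runs a leave-one-out
#' cross-validation in which every fold fine-tunes the shared checkpoint
#' (convolutional stage frozen, dense stage retrained), and reports deltas
#' against a supplied baseline table.
#'
#' @param cohort Target `vg_cohort`.
#' @param source A `vg_dataset` already on the model's input grid (use
#'   [resample_dataset()] with cubic interpolation for activity windows).
#' @param spec A [model_spec()].
#' @param pretrain_cfg [train_config()] for pretraining (activity sources
#'   conventionally use `learning_rate = 0.001`).
#' @param finetune_cfg A [finetune_config()].
#' @param baseline_table Baseline [aggregate_sensor_table()] (or any
#'   sensor/control/patient data frame) for the delta columns; `NULL`
#'   skips deltas.
#' @param placements Placements to evaluate.
#' @param n_folds,fold_unit Source-validation folding, see
#'   [pretrain_model()].
#' @param seg_params A [segmentation_params()].
#' @return List of class `vg_transfer`: `pretrain` (checkpoint +
#'   source validation accuracy), `reports`, `table`, and `deltas`.
#' @export
transfer_experiment <- function(cohort, source, spec,
                                pretrain_cfg = train_config(),
                                finetune_cfg = finetune_config(),
                                baseline_table = NULL,
                                placements = vg_placements(),
                                n_folds = 5L, fold_unit = "sample",
                                seg_params = segmentation_params()) {
  pre <- pretrain_model(source, spec, pretrain_cfg, n_folds = n_folds,
                        fold_unit = fold_unit)
  reports <- lapply(placements, function(p) {
    ds <- build_cycle_dataset(cohort, p, params = seg_params,
                              target_length = spec$input_shape[2])
    run_loocv(ds, spec, checkpoint = pre$model, finetune_cfg = finetune_cfg)
  })
  names(reports) <- placements
  tab <- suppressWarnings(aggregate_sensor_table(reports, digits = NA))
  deltas <- if (is.null(baseline_table)) NULL else {
    transfer_delta(tab[tab$sensor != "Mean", ],
                   baseline_table[baseline_table$sensor != "Mean", ])
  }
  structure(list(pretrain = pre, reports = reports, table = tab,
                 deltas = deltas),
            class = "vg_transfer")
}

#' Ablation configuration
#'
#' @param mode `"subjects"` (subsample subjects per class) or `"samples"`
#'   (keep a fraction of each subject's cycles).
#' @param fractions Fractions in (0, 1]; 1 reproduces the unablated
#'   baseline exactly.
#' @param iterations Random redraws per fraction (default 15).
#' @param seed Master seed; iteration `i` draws with seed `seed + i`.
#' @return An object of class `vg_ablation_config`.
#' @export
ablation_config <- function(mode = c("subjects", "samples"),
                            fractions = c(0.25, 0.5, 0.75),
                            iterations = 15L, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, fractions = fractions,
              iterations = as.integer(iterations), seed = as.integer(seed))
  class(cfg) <- "vg_ablation_config"
  check_that(all(fractions > 0 & fractions <= 1),
             "fractions must lie in (0, 1]")
  check_that(cfg$iterations >= 1L, "iterations must be >= 1")
  cfg
}

# label-stratified subject subsample, uniform without replacement
draw_subject_subset <- function(ds, fraction) {
  subj <- unique(ds$meta[, c("subject_id", "group")])
  keep <- unlist(lapply(vg_groups(), function(g) {
    ids <- sort(subj$subject_id[subj$group == g])
    k <- as.integer(round(fraction * length(ids)))
    check_that(k >= 2L,
               "fraction %.2f leaves < 2 subjects in group %s", fraction, g,
               class = "vg_contract_error")
    if (k == length(ids)) ids else sample(ids, k)
  }), use.names = FALSE)
  subset_dataset(ds, ds$meta$subject_id %in% keep)
}

# keep a fraction of each subject's cycles (>= 1), uniform w/o replacement
draw_sample_subset <- function(ds, fraction) {
  idx <- unlist(lapply(split(seq_len(n_samples(ds)), ds$meta$subject_id),
                       function(ii) {
                         k <- max(round(fraction * length(ii)), 1L)
                         if (k == length(ii)) ii else sample(ii, k)
                       }), use.names = FALSE)
  subset_dataset(ds, sort(idx))
}

#' Subject / sample ablation experiment
#'
#' For each fraction and iteration, draws a label-stratified subject
#' subset (mode `"subjects"`) or retains a fraction of every subject's
#' cycles, at least one (mode `"samples"`), reruns the leave-one-out
#' evaluation on the subset, and reports the mean and sample standard
#' deviation of the overall accuracy across iterations. Iteration `i`
#' draws under seed `config$seed + i`; model/training seeds are untouched,
#' so `fractions = 1` reproduces the unablated baseline exactly.
#'
#' @param ds A `vg_dataset` (typically the wrist placement).
#' @param ablation An [ablation_config()].
#' @param spec A [model_spec()].
#' @param config A [train_config()].
#' @return List of class `vg_ablation`: `table` (fraction, mean, sd,
#'   iterations) and `accuracies` (iterations x fractions matrix).
#' @export
ablate <- function(ds, ablation, spec, config = train_config()) {
  acc <- matrix(NA_real_, ablation$iterations, length(ablation$fractions),
                dimnames = list(NULL, paste0(100 * ablation$fractions, "%")))
  for (fi in seq_along(ablation$fractions)) {
    f <- ablation$fractions[fi]
    for (i in seq_len(ablation$iterations)) {
      sub <- withr::with_seed(ablation$seed + i, {
        if (ablation$mode == "subjects") draw_subject_subset(ds, f)
        else draw_sample_subset(ds, f)
      })
      acc[i, fi] <- run_loocv(sub, spec, config)$overall
    }
  }
  tab <- data.frame(fraction = ablation$fractions,
                    mean = colMeans(acc),
                    sd = apply(acc, 2L, stats::sd),
                    iterations = ablation$iterations)
  rownames(tab) <- NULL
  structure(list(table = tab, accuracies = acc, mode = ablation$mode),
            class = "vg_ablation")
}
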