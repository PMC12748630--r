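#' Bundled benchmark summary tables
#'
#' Small plain-text tables transcribed from a published clinical study of
#' wearable-IMU gait classification in vestibular schwannoma, bundled so
#' the package's table-arithmetic functions (sensor aggregation, transfer
#' deltas, sample shares, clinical-score summaries) can be exercised and
#' checked against printed results. Available names:
#'
#' * `sensor_accuracy` — leave-one-out accuracy by task, sensor and group.
#' * `pretrain_validation` — source-dataset validation performance of the
#'   pathology pretraining source by sensor.
#' * `transfer_accuracy` — fine-tuned accuracies by pretraining scenario,
#'   sensor and group.
#' * `fga_scores` — Functional Gait Assessment item-1 score counts per
#'   group.
#' * `sample_counts` — subjects and gait-cycle samples by task and group.
#' * `pretrain_sample_counts` — samples by pretraining source and activity.
#'
#' @param name One of the table names above.
#' @return A data frame.
#' @export
vg_reference <- function(name = c("sensor_accuracy", "pretrain_validation",
                                  "transfer_accuracy", "fga_scores",
                                  "sample_counts", "pretrain_sample_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("reference_", name, ".csv"),
                      package = "vestgait", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
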