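# Shared fixtures for the suite. Model and training configurations are
# reduced-budget versions of the defaults (small filter counts, few
# epochs, learning rate 0.01) so cross-validation runs complete quickly;
# the synthetic study conditions themselves come from cohort_presets().
# Expensive fixtures are memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tiny_spec <- function(seed = 5L) {
  model_spec(filters = c(4L, 8L, 8L, 16L), dense_sizes = c(32L, 16L),
             seed = seed)
}

tiny_config <- function(seed = 5L, epochs = 8L) {
  train_config(epochs = epochs, batch_size = 64L, learning_rate = 0.01,
               seed = seed)
}

tiny_finetune <- function(seed = 9L, epochs = 5L) {
  finetune_config(epochs = epochs, learning_rate = 0.01, batch_size = 64L,
                  seed = seed)
}

# small cohort for unit tests (not the preset ladder)
unit_cohort <- function() {
  memo("unit_cohort", generate_cohort(
    cohort_config(n_per_group = 3L, sampling_rate = 250,
                  trial_duration_s = 8, group_amplitude_effect = 0.3,
                  noise_sd = 0.05, seed = 7L)))
}

strong_head_ds <- function() {
  memo("strong_head_ds", {
    co <- generate_cohort(cohort_presets("strong", seed = 11L))
    build_cycle_dataset(co, "head")
  })
}

activity_source <- function() {
  memo("activity_source", {
    aw <- generate_activity_windows(
      activity_config(n_windows_per_class = 40L, seed = 3L))
    resample_dataset(aw, 512L, "cubic")
  })
}

pretrained_checkpoint <- function() {
  memo("pretrained_checkpoint", {
    pretrain_model(activity_source(), tiny_spec(),
                   train_config(epochs = 10L, batch_size = 64L,
                                learning_rate = 0.01, seed = 5L),
                   n_folds = 3L)
  })
}
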