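# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

## tiny cohorts for unit tests
tiny_train <- function() cached("tiny_train",
  generate_separate_dataset(n_subjects = 2, reps_per_task = 2, seed = 42))

tiny_test <- function() cached("tiny_test",
  generate_continuous_dataset(n_subjects = 2, reps = 1, seed = 42))

tiny_stats <- function() cached("tiny_stats",
  normalization_stats(tiny_train()$recordings))

tiny_train_tensor <- function() cached("tiny_train_tensor",
  suppressWarnings(assemble(tiny_train(), "RW+RP+LP+S", augment = TRUE,
                            seed = 1, stats = tiny_stats())))

tiny_test_tensor <- function() cached("tiny_test_tensor",
  suppressWarnings(assemble(tiny_test(), "RW+RP+LP+S", augment = FALSE,
                            stats = tiny_stats())))

## a small synthetic window tensor built directly (no generator), for fast
## model-contract tests
toy_tensor <- function(nw = 24, nc = 3L, seed = 1) {
  set.seed(seed)
  labs <- rep(activity_labels(), length.out = nw)
  arr <- function() array(stats::rnorm(nw * 128 * nc), c(nw, 128, nc))
  window_tensor(arr(), arr(), arr(), labs,
                trial_ids = paste0("t", seq_len(nw)),
                sites = sensor_sites()[seq_len(nc / 3)])
}

## ground-truth label per trial of a tensor
tensor_truth <- function(tensor) {
  tapply(as.character(tensor$labels), tensor$trial_ids, function(x) x[1])
}
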