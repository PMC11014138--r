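# The reference continuous-recognition experiment, shared by the end-to-end
# acceptance tests. Train on the separate-execution protocol, evaluate every
# fold's model on the continuous circuit. Sizes are the package's reference
# configuration (see the methods vignette): 5 training subjects x 2
# repetitions, 4 test subjects x 2 circuits, master seed 42, 10 stratified
# folds, epochs capped at 12 with patience 10, batch 64, Adam lr 0.001.
# Computed once per arm (with / without flip augmentation) and cached.

ref_config <- list(train_subjects = 5L, train_reps = 2L,
                   test_subjects = 4L, test_reps = 2L,
                   master_seed = 42L, n_folds = 10L,
                   epochs = 12L, patience = 10L)

ref_datasets <- function() cached("ref_datasets", {
  cfg <- ref_config
  train <- generate_separate_dataset(cfg$train_subjects, cfg$train_reps,
                                     seed = cfg$master_seed)
  test <- generate_continuous_dataset(cfg$test_subjects, cfg$test_reps,
                                      seed = cfg$master_seed)
  list(train = train, test = test,
       stats = normalization_stats(train$recordings))
})

## one arm of the experiment; returns a per-fold metric data.frame
ref_experiment <- function(flip = TRUE) cached(paste0("ref_", flip), {
  cfg <- ref_config
  d <- ref_datasets()
  rules <- if (flip) default_flip_rules() else list()
  wt <- suppressWarnings(assemble(d$train, "RW+RP+LP+S", augment = TRUE,
                                  seed = cfg$master_seed, rules = rules,
                                  stats = d$stats))
  wte <- suppressWarnings(assemble(d$test, "RW+RP+LP+S", augment = FALSE,
                                   stats = d$stats))
  plan <- make_folds(wt, n_folds = cfg$n_folds, seed = cfg$master_seed)
  truth <- tensor_truth(wte)
  res <- NULL
  for (f in seq_len(cfg$n_folds)) {
    m <- build_model(Nc = 12L, seed = cfg$master_seed + 100L + f)
    sp <- train_spec(epochs = cfg$epochs, early_stop_patience = cfg$patience,
                     seed = cfg$master_seed + 200L + f)
    m <- train_model(m, wt, plan$folds[[f]], sp, fold_id = f)
    pr <- predict_subwindows(m, wte)
    g <- group_predictions(pr$probs, wte$trial_ids)
    cls <- truth[g$trial_id]
    ok <- as.character(g$label) == cls
    res <- rbind(res, data.frame(
      fold = f,
      sub_accuracy = accuracy(wte$labels, pr$labels),
      grouped_accuracy = 100 * mean(ok),
      tn_s2s_grouped = 100 * mean(ok[cls %in% c("TN", "S2S")])))
  }
  res
})
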