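# Grouped-window classification strategy, performance metrics, and the
# sensor-combination comparison statistics (Friedman across folds, pairwise
# post-hoc with Bonferroni correction).

#' Average sub-window predictions per trial
#'
#' The grouped-window strategy: one prediction per trial, its probability
#' vector the arithmetic mean of the trial's sub-window probability rows and
#' its label the argmax of that mean (ties towards the lowest class index).
#' Trials appear in order of first appearance.
#'
#' @param sub_probs `Nw x 4` matrix of sub-window probabilities.
#' @param trial_ids length-`Nw` trial identity vector.
#' @param vote use majority vote over hard sub-window labels instead of the
#'   probability mean (configurable alternative; ties resolved by the mean).
#' @return A data.frame with one row per trial: `trial_id`,
#'   `n_subwindows`, mean probabilities `p_LD`, `p_S2S`, `p_TN`, `p_W`, and
#'   the grouped `label`.
#' @export
group_predictions <- function(sub_probs, trial_ids, vote = FALSE) {
  if (length(trial_ids) != nrow(sub_probs)) {
    stop("trial_ids must have one entry per probability row")
  }
  if (nrow(sub_probs) == 0L) {
    return(data.frame(trial_id = character(0), n_subwindows = integer(0),
                      p_LD = numeric(0), p_S2S = numeric(0),
                      p_TN = numeric(0), p_W = numeric(0),
                      label = factor(character(0), levels = activity_labels())))
  }
  if (any(!nzchar(trial_ids))) stop("empty trial_id")
  trials <- unique(trial_ids)
  rows <- lapply(trials, function(tr) {
    p <- sub_probs[trial_ids == tr, , drop = FALSE]
    mp <- colMeans(p)
    if (vote) {
      hard <- table(factor(activity_labels()[max.col(p, ties.method = "first")],
                           levels = activity_labels()))
      top <- names(hard)[hard == max(hard)]
      lab <- if (length(top) == 1L) top else
        activity_labels()[which.max(mp)]
    } else {
      lab <- activity_labels()[which.max(mp)] # which.max: first of ties
    }
    c(list(trial_id = tr, n_subwindows = nrow(p)),
      as.list(stats::setNames(mp, paste0("p_", activity_labels()))),
      list(label = lab))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$label <- factor(out$label, levels = activity_labels())
  rownames(out) <- NULL
  out
}

#' Classification accuracy (percent)
#'
#' Fraction of correctly classified units, times 100.
#'
#' @param truth,predicted equal-length label vectors.
#' @return Accuracy in percent.
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(truth) == 0L) stop("no units to score")
  100 * mean(as.character(truth) == as.character(predicted))
}

#' Confusion matrix
#'
#' 4 x 4 integer counts, rows ground truth, columns predictions, both in
#' class encoding order. Its trace over its total equals accuracy/100.
#'
#' @inheritParams accuracy
#' @return Integer matrix with class dimnames.
#' @export
confusion <- function(truth, predicted) {
  truth <- activity_factor(truth)
  predicted <- activity_factor(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  m <- table(truth = truth, predicted = predicted)
  matrix(as.integer(m), 4, 4, dimnames = list(truth = activity_labels(),
                                              predicted = activity_labels()))
}

#' Inference timing
#'
#' Wall-clock time to produce a prediction: per single sub-window
#' (`strategy = "sub"`) or per trial, from presenting all the trial's
#' sub-windows to the averaged grouped label (`strategy = "grouped"`). One
#' discarded warm-up pass precedes measurement. Values are
#' hardware-dependent and reported, never asserted against external tables.
#'
#' @param model a trained [char_model].
#' @param tensor a [window_tensor()]; the first trial is timed.
#' @param strategy `"sub"` or `"grouped"`.
#' @param repetitions number of timed repetitions.
#' @return List with `mean`, `sd` (0 when `repetitions = 1`), `times`
#'   (seconds) and `window_type`.
#' @export
time_inference <- function(model, tensor, strategy = c("sub", "grouped"),
                           repetitions = 5L) {
  strategy <- match.arg(strategy)
  stopifnot(n_windows(tensor) >= 1L)
  tr <- tensor$trial_ids[1]
  unit <- if (strategy == "sub") tensor_subset(tensor, 1L) else
    tensor_subset(tensor, which(tensor$trial_ids == tr))
  invisible(predict_subwindows(model, unit)) # warm-up
  times <- vapply(seq_len(repetitions), function(i) {
    t0 <- proc.time()[["elapsed"]]
    p <- predict_subwindows(model, unit)
    if (strategy == "grouped") invisible(group_predictions(p$probs, unit$trial_ids))
    proc.time()[["elapsed"]] - t0
  }, double(1))
  list(mean = mean(times), sd = if (repetitions > 1L) stats::sd(times) else 0,
       times = times, window_type = strategy)
}

#' Friedman rank test across matched blocks
#'
#' Nonparametric test for differences among `k` treatments (sensor
#' combinations) over `n` matched blocks (cross-validation folds). Within
#' each block, observations are ranked (mean ranks on ties) and the
#' statistic `chi2 = 12 n / (k (k+1)) * sum_j (Rbar_j - (k+1)/2)^2` is
#' referred to the chi-squared distribution with `k - 1` degrees of
#' freedom.
#'
#' @param metric_matrix `n x k` numeric matrix, blocks in rows.
#' @return List with `statistic`, `df`, `p_value` and `mean_ranks`.
#' @export
friedman_test <- function(metric_matrix) {
  m <- as.matrix(metric_matrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments")
  ranks <- t(apply(m, 1, rank)) # mean ranks on ties
  rbar <- colMeans(ranks)
  stat <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  list(statistic = stat, df = k - 1L,
       p_value = stats::pchisq(stat, df = k - 1L, lower.tail = FALSE),
       mean_ranks = rbar)
}

#' Pairwise post-hoc comparisons with Bonferroni correction
#'
#' All `k (k-1) / 2` paired two-sided tests between treatment columns
#' (Wilcoxon signed-rank by default, sign test as the configurable
#' alternative); adjusted p = `min(1, raw * k(k-1)/2)`; a pair is declared
#' significant iff its adjusted p is below `alpha`.
#'
#' @inheritParams friedman_test
#' @param alpha significance level.
#' @param method `"wilcoxon"` or `"sign"`.
#' @return List with symmetric matrices `raw_p` and `adjusted_p` (unit
#'   diagonal), logical `significant`, the Bonferroni multiplier
#'   `n_comparisons`, and `alpha`.
#' @export
posthoc_pairwise <- function(metric_matrix, alpha = 0.05,
                             method = c("wilcoxon", "sign")) {
  method <- match.arg(method)
  m <- as.matrix(metric_matrix)
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 treatments")
  cmp <- k * (k - 1) / 2
  raw <- matrix(1, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- m[, i] - m[, j]
      p <- if (all(d == 0)) 1 else if (method == "wilcoxon") {
        suppressWarnings(stats::wilcox.test(m[, i], m[, j], paired = TRUE,
                                            exact = nrow(m) <= 25)$p.value)
      } else {
        s <- d[d != 0]
        if (length(s) == 0L) 1 else
          stats::binom.test(sum(s > 0), length(s))$p.value
      }
      raw[i, j] <- raw[j, i] <- p
    }
  }
  adj <- raw * cmp
  adj[adj > 1] <- 1
  diag(adj) <- 1
  sig <- adj < alpha
  diag(sig) <- FALSE
  list(raw_p = raw, adjusted_p = adj, significant = sig,
       n_comparisons = cmp, alpha = alpha)
}

#' Full sensor-combination evaluation
#'
#' For every sensor combination: assemble the augmented training tensor from
#' the separate-execution dataset, plan stratified folds, train one model
#' per fold, and evaluate each on the (non-augmented) continuous test
#' tensor: sub-window accuracy, grouped accuracy over the annotated circuit
#' segments, grouped confusion matrices and inference timings. With at
#' least two combinations, fold-paired Friedman and Bonferroni post-hoc
#' statistics are computed on grouped accuracy and on grouped inference
#' time.
#'
#' @param train_data,test_data datasets (`recordings` + `annotations`), e.g.
#'   from [generate_separate_dataset()] / [generate_continuous_dataset()].
#' @param combos list of [sensor_combination()]s (or names).
#' @param n_folds folds per combination.
#' @param spec a [train_spec()].
#' @param seed master seed; all fold/model seeds derive from it.
#' @param augment apply flip + scale-balance augmentation to training data.
#' @param flip_mode,time_repetitions tuning knobs passed through.
#' @return An object of class `eval_report`.
#' @export
run_full_evaluation <- function(train_data, test_data,
                                combos = studied_combinations(),
                                n_folds = 10L, spec = train_spec(),
                                seed = 1L, augment = TRUE,
                                flip_mode = "append", time_repetitions = 3L) {
  combos <- lapply(combos, function(cc)
    if (inherits(cc, "sensor_combination")) cc else sensor_combination(cc))
  if (length(combos) == 0L) stop("no sensor combinations given")
  names(combos) <- vapply(combos, `[[`, "", "name")

  metrics <- list()
  confusions <- list()
  train_stats <- normalization_stats(train_data$recordings)
  for (cmb in combos) {
    train_tensor <- suppressWarnings(
      assemble(train_data, cmb, augment = augment, flip_mode = flip_mode,
               seed = stable_seed(seed, "assemble", cmb$name),
               stats = train_stats))
    test_tensor <- suppressWarnings(
      assemble(test_data, cmb, augment = FALSE, stats = train_stats))
    plan <- make_folds(train_tensor, n_folds = n_folds,
                       seed = stable_seed(seed, "folds", cmb$name))
    confusions[[cmb$name]] <- list()
    for (f in seq_len(n_folds)) {
      fold_seed <- stable_seed(seed, "fit", cmb$name, f)
      model <- build_model(Nc = cmb$n_channels, seed = fold_seed,
                           sites = cmb$sites)
      fspec <- spec
      fspec$seed <- fold_seed
      model <- train_model(model, train_tensor, plan$folds[[f]], fspec,
                           fold_id = f)
      pred <- predict_subwindows(model, test_tensor)
      sub_acc <- accuracy(test_tensor$labels, pred$labels)
      grouped <- group_predictions(pred$probs, test_tensor$trial_ids)
      truth <- truth_per_trial(test_tensor)
      g_acc <- accuracy(truth[grouped$trial_id], grouped$label)
      confusions[[cmb$name]][[f]] <-
        confusion(truth[grouped$trial_id], grouped$label)
      t_sub <- time_inference(model, test_tensor, "sub", time_repetitions)
      t_grp <- time_inference(model, test_tensor, "grouped", time_repetitions)
      metrics[[length(metrics) + 1L]] <- data.frame(
        combo = cmb$name, fold = f,
        sub_accuracy = sub_acc, grouped_accuracy = g_acc,
        it_sub_mean = t_sub$mean, it_sub_sd = t_sub$sd,
        it_grouped_mean = t_grp$mean, it_grouped_sd = t_grp$sd,
        best_epoch = model$best_epoch, stopped_epoch = model$stopped_epoch)
    }
  }
  metrics <- do.call(rbind, metrics)

  statistics <- NULL
  if (length(combos) >= 2L) {
    to_matrix <- function(col) {
      m <- matrix(metrics[[col]], nrow = n_folds, ncol = length(combos),
                  dimnames = list(NULL, names(combos)))
      m
    }
    acc_m <- to_matrix("grouped_accuracy")
    it_m <- to_matrix("it_grouped_mean")
    statistics <- list(
      grouped_accuracy = list(friedman = friedman_test(acc_m),
                              posthoc = posthoc_pairwise(acc_m)),
      grouped_inference_time = list(friedman = friedman_test(it_m),
                                    posthoc = posthoc_pairwise(it_m)))
  } else {
    message("fewer than two sensor combinations: statistics section omitted")
  }

  structure(list(combos = names(combos), n_folds = as.integer(n_folds),
                 metrics = metrics, confusions = confusions,
                 statistics = statistics, seed = seed,
                 train_spec = unclass(spec)),
            class = "eval_report")
}

## ground-truth label per test trial id
truth_per_trial <- function(tensor) {
  lab <- tapply(as.character(tensor$labels), tensor$trial_ids,
                function(x) x[1])
  stats::setNames(as.character(lab), names(lab))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d combination(s) x %d folds\n",
              length(x$combos), x$n_folds))
  agg <- stats::aggregate(cbind(sub_accuracy, grouped_accuracy) ~ combo,
                          data = x$metrics, FUN = mean)
  print(agg, row.names = FALSE)
  if (!is.null(x$statistics)) {
    fr <- x$statistics$grouped_accuracy$friedman
    cat(sprintf("Friedman on grouped accuracy: chi2 = %.3f, df = %d, p = %.4g\n",
                fr$statistic, fr$df, fr$p_value))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
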