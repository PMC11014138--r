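# Model construction, fold planning, training and prediction. The network
# topology is fixed (the reported winning configuration of the architecture
# search): per branch conv(128,k5)-conv(128,k3)-pool-conv(64,k5)-conv(64,k3)
# -pool-flatten; branches concatenated; dense(128)-dropout(0.2)-dense(128)-
# softmax(4). Valid padding, pool size/stride 2/2, ReLU activations.

#' Architecture specification
#'
#' The fixed multi-branch topology. Exposed as data so the audit tools and
#' the builder share one source of truth.
#'
#' @param dropout dropout rate after the first dense layer.
#' @return An object of class `char_model_spec`.
#' @export
char_model_spec <- function(dropout = 0.2) {
  structure(list(
    branch_conv = data.frame(filters = c(128L, 128L, 64L, 64L),
                             kernel = c(5L, 3L, 5L, 3L),
                             pool_after = c(FALSE, TRUE, FALSE, TRUE)),
    dense = c(128L, 128L),
    dropout = dropout,
    n_classes = 4L,
    window = 128L,
    pool = 2L),
    class = "char_model_spec")
}

#' Training hyper-parameters
#'
#' Defaults follow the reported winning configuration: 200 epochs, batch
#' size 64, Adam with learning rate 0.001, early stopping on validation
#' loss with patience 10 and best-weight restoration.
#'
#' @param epochs,batch_size,learning_rate,early_stop_patience,seed as named.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(epochs = 200L, batch_size = 64L, learning_rate = 0.001,
                       early_stop_patience = 10L, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            early_stop_patience >= 1)
  if (early_stop_patience >= epochs) {
    stop("early_stop_patience must be smaller than epochs")
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "train_spec")
}

glorot <- function(n_out, n_in, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Build an (untrained) model
#'
#' Initialises the three identical-topology branches plus the dense head for
#' a given per-branch channel count. Glorot-uniform weights, zero biases,
#' deterministic under `seed`.
#'
#' @param spec a [char_model_spec()].
#' @param Nc per-branch channel count, a positive multiple of 3
#'   (3 x number of sites in the sensor combination).
#' @param seed integer seed for the parameter initialisation.
#' @param sites optional site codes the model expects (for bookkeeping).
#' @return An object of class `char_model`.
#' @export
build_model <- function(spec = char_model_spec(), Nc, seed = 1L, sites = NULL) {
  Nc <- as.integer(Nc)
  if (Nc <= 0L || Nc %% 3L != 0L) stop("Nc must be a positive multiple of 3")
  set.seed(as.integer(seed %% 2147483647))
  weights <- list()
  for (br in c("acc", "gyro", "mag")) {
    cin <- Nc
    for (l in seq_len(nrow(spec$branch_conv))) {
      cout <- spec$branch_conv$filters[l]
      k <- spec$branch_conv$kernel[l]
      weights[[paste0(br, "_W", l)]] <-
        glorot(cout, k * cin, fan_in = k * cin, fan_out = k * cout)
      weights[[paste0(br, "_b", l)]] <- numeric(cout)
      cin <- cout
    }
  }
  flat <- branch_flat_length(spec)
  sizes <- c(3L * flat, spec$dense, spec$n_classes)
  dn <- c("Wd1", "Wd2", "Wo")
  bn <- c("bd1", "bd2", "bo")
  for (i in 1:3) {
    weights[[dn[i]]] <- glorot(sizes[i + 1], sizes[i],
                               fan_in = sizes[i], fan_out = sizes[i + 1])
    weights[[bn[i]]] <- numeric(sizes[i + 1])
  }
  structure(list(spec = spec, Nc = Nc, sites = sites, weights = weights,
                 history = NULL, fold_id = NA_integer_, trained = FALSE),
            class = "char_model")
}

## closed-form per-branch flattened length under valid padding and pool 2/2
branch_flat_length <- function(spec = char_model_spec()) {
  t <- spec$window
  for (l in seq_len(nrow(spec$branch_conv))) {
    t <- t - spec$branch_conv$kernel[l] + 1L
    if (spec$branch_conv$pool_after[l]) t <- t %/% spec$pool
  }
  t * spec$branch_conv$filters[nrow(spec$branch_conv)]
}

#' @export
print.char_model <- function(x, ...) {
  cat(sprintf("<char_model> Nc=%d per branch, %s, %s parameters\n",
              x$Nc, if (x$trained) "trained" else "untrained",
              format(n_model_params(x), big.mark = ",")))
  invisible(x)
}

#' Model audit helpers
#'
#' `n_model_params()` counts all weights and biases;
#' `model_layer_summary()` reports, per branch layer, the output shape as
#' computed by the forward machinery itself plus the parameter count of
#' each weight tensor, for comparison with an independent shape trace.
#'
#' @param model a [build_model()] result.
#' @return `n_model_params()`: integer. `model_layer_summary()`: list with
#'   `branch_trace` (channels x time after each branch stage, from the C++
#'   forward pass), `flat_per_branch`, `concat_length`, and `param_counts`
#'   (named vector, one entry per weight/bias tensor).
#' @export
n_model_params <- function(model) {
  sum(vapply(model$weights, length, double(1)))
}

#' @rdname n_model_params
#' @export
model_layer_summary <- function(model) {
  tr <- cnn_branch_trace_cpp(model$weights, model$Nc)
  rownames(tr) <- c("input", "conv1", "conv2", "pool1", "conv3", "conv4",
                    "pool2")
  flat <- tr["pool2", "channels"] * tr["pool2", "time"]
  list(branch_trace = tr,
       flat_per_branch = flat,
       concat_length = 3L * flat,
       param_counts = vapply(model$weights, length, double(1)))
}

base_trial <- function(trial_ids) sub("#.*$", "", trial_ids)

#' Plan stratified train/validation folds
#'
#' Ten (by default) independent stratified 75/25 train/validation
#' resamplings of the training windows. Stratification is at trial
#' granularity: all windows of a trial — including its augmentation copies,
#' which share the base trial identity — are co-assigned, so no trial
#' straddles train and validation (overlapping windows cannot leak).
#'
#' @param tensor the assembled training [window_tensor()].
#' @param n_folds number of resamplings.
#' @param val_fraction validation share of each class's trials.
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list of folds, each with `train`
#'   and `val` window index vectors.
#' @export
make_folds <- function(tensor, n_folds = 10L, val_fraction = 0.25, seed = 1L) {
  bt <- base_trial(tensor$trial_ids)
  lab <- as.character(tensor$labels)
  trial_label <- tapply(lab, bt, function(x) x[1])
  classes <- activity_labels()[activity_labels() %in% unique(lab)]
  for (cl in classes) {
    n_tr <- sum(trial_label == cl)
    if (n_tr < n_folds) {
      stop("class ", cl, " has only ", n_tr, " trials; ", n_folds,
           " are required for fold planning")
    }
  }
  set.seed(as.integer(seed %% 2147483647))
  folds <- lapply(seq_len(n_folds), function(f) {
    val_trials <- unlist(lapply(classes, function(cl) {
      trs <- names(trial_label)[trial_label == cl]
      n_val <- max(1L, round(val_fraction * length(trs)))
      sample(trs, n_val)
    }))
    is_val <- bt %in% val_trials
    list(train = which(!is_val), val = which(is_val))
  })
  structure(list(folds = folds, n_folds = as.integer(n_folds),
                 val_fraction = val_fraction, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds, validation fraction %.2f\n",
              x$n_folds, x$val_fraction))
  invisible(x)
}

tensor_labels_int <- function(tensor) as.integer(tensor$labels) - 1L

#' Train the model on one fold
#'
#' Minibatch Adam on categorical cross-entropy with the fold's validation
#' windows monitored each epoch; training stops once validation loss fails
#' to improve for `early_stop_patience` consecutive epochs and the
#' best-loss weights are restored. The per-epoch history is recorded on the
#' returned model.
#'
#' @param model an untrained (or trained) [build_model()] result.
#' @param tensor the training [window_tensor()] (assembled with
#'   augmentation for training data).
#' @param fold one element of a [make_folds()] plan (list with `train` and
#'   `val` indices); pass `NULL` to train on everything with a 25% tail
#'   split.
#' @param spec a [train_spec()].
#' @param fold_id integer recorded on the model.
#' @return The trained `char_model`.
#' @export
train_model <- function(model, tensor, fold, spec = train_spec(),
                        fold_id = NA_integer_) {
  stopifnot(inherits(model, "char_model"), inherits(tensor, "window_tensor"),
            inherits(spec, "train_spec"))
  if (tensor$Nc != model$Nc) {
    stop("tensor channel count (", tensor$Nc, ") does not match model Nc (",
         model$Nc, ")")
  }
  if (is.null(fold)) {
    n <- n_windows(tensor)
    cut <- floor(0.75 * n)
    fold <- list(train = seq_len(cut), val = (cut + 1L):n)
  }
  tr <- tensor_subset(tensor, fold$train)
  va <- tensor_subset(tensor, fold$val)
  res <- cnn_train_cpp(model$weights,
                       tr$acc, tr$gyro, tr$mag, tensor_labels_int(tr),
                       va$acc, va$gyro, va$mag, tensor_labels_int(va),
                       epochs = spec$epochs, batch_size = spec$batch_size,
                       lr = spec$learning_rate,
                       patience = spec$early_stop_patience,
                       dropout = model$spec$dropout, seed = spec$seed)
  model$weights <- res$weights
  model$history <- res$history
  model$best_epoch <- res$best_epoch
  model$stopped_epoch <- res$stopped_epoch
  model$fold_id <- fold_id
  model$trained <- TRUE
  model
}

#' Per-sub-window class probabilities
#'
#' Forward pass over every window of the tensor. Predicted labels are the
#' argmax of each probability row, ties broken towards the lowest class
#' index.
#'
#' @param model a trained [char_model].
#' @param tensor a [window_tensor()] matching the model's channel count.
#' @return List with `probs` (`Nw x 4` row-stochastic matrix, columns in
#'   class encoding order) and `labels` (factor).
#' @export
predict_subwindows <- function(model, tensor) {
  stopifnot(inherits(model, "char_model"), inherits(tensor, "window_tensor"))
  if (tensor$Nc != model$Nc) {
    stop("tensor channel count (", tensor$Nc, ") does not match model Nc (",
         model$Nc, ")")
  }
  if (n_windows(tensor) == 0L) {
    probs <- matrix(numeric(0), 0, 4, dimnames = list(NULL, activity_labels()))
    return(list(probs = probs,
                labels = factor(character(0), levels = activity_labels())))
  }
  probs <- cnn_forward_cpp(model$weights, tensor$acc, tensor$gyro, tensor$mag)
  colnames(probs) <- activity_labels()
  idx <- max.col(probs, ties.method = "first")
  list(probs = probs,
       labels = factor(activity_labels()[idx], levels = activity_labels()))
}
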