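# Preprocessing chain: per-channel min-max normalization, annotation-driven
# segment extraction, resampling to an integer multiple of the window width,
# overlapping windowing, magnetometer flip augmentation and magnitude-scaling
# class balancing, assembled per sensor combination into per-modality window
# tensors of shape (Nw, Wl, Nc).

#' Min-max normalize a recording
#'
#' Each channel is mapped to `[-1, 1]` with its own minimum and maximum
#' (`x -> 2 (x - min) / (max - min) - 1`), so min maps to -1 and max to +1
#' exactly. Statistics are per recording unless `stats` supplies externally
#' computed ranges (e.g. training-global ones). A constant channel is mapped
#' to all zeros with a warning.
#'
#' @param rec an [imu_recording()].
#' @param stats optional list as returned by [normalization_stats()]; when
#'   given, its ranges are used instead of the recording's own.
#' @return The normalized recording (blocks flagged `normalized`).
#' @export
normalize <- function(rec, stats = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  degenerate <- character(0)
  for (s in names(rec$sites)) {
    blk <- rec$sites[[s]]
    for (m in imu_modalities()) {
      x <- blk[[m]]
      for (a in seq_len(3)) {
        if (is.null(stats)) {
          lo <- min(x[, a]); hi <- max(x[, a])
        } else {
          lo <- stats[[s]][[m]]["min", a]; hi <- stats[[s]][[m]]["max", a]
        }
        if (hi == lo) {
          x[, a] <- 0
          degenerate <- c(degenerate, paste(s, m, imu_axes()[a], sep = "_"))
        } else {
          x[, a] <- 2 * (x[, a] - lo) / (hi - lo) - 1
        }
      }
      blk[[m]] <- x
    }
    blk$normalized <- TRUE
    rec$sites[[s]] <- blk
  }
  if (length(degenerate) > 0L) {
    warning("constant channel(s) mapped to zero: ",
            paste(degenerate, collapse = ", "))
  }
  rec
}

#' @rdname normalize
#' @param recordings list of recordings over which to pool per-channel
#'   min/max (the training-global alternative to per-recording statistics).
#' @return `normalization_stats()`: nested list `site -> modality ->`
#'   2 x 3 matrix with rows `min`, `max`.
#' @export
normalization_stats <- function(recordings) {
  sites <- names(recordings[[1]]$sites)
  out <- list()
  for (s in sites) {
    out[[s]] <- list()
    for (m in imu_modalities()) {
      mins <- apply(do.call(rbind, lapply(recordings, function(r)
        apply(r$sites[[s]][[m]], 2, min))), 2, min)
      maxs <- apply(do.call(rbind, lapply(recordings, function(r)
        apply(r$sites[[s]][[m]], 2, max))), 2, max)
      out[[s]][[m]] <- rbind(min = mins, max = maxs)
    }
  }
  out
}

#' Extract annotated segments from a recording
#'
#' Returns one multi-site slice per annotation (`[start, end)`, 0-based);
#' everything unannotated (static postures, transitions) is discarded.
#'
#' @param rec an [imu_recording()].
#' @param annotations annotation rows referring to `rec`.
#' @return List of segments, each `list(sites =, label =, trial_id =,
#'   n_samples =)`.
#' @export
extract_segments <- function(rec, annotations) {
  stopifnot(inherits(rec, "imu_recording"))
  ann <- annotations[annotations$recording_id == rec$recording_id, , drop = FALSE]
  if (nrow(ann) == 0L) return(list())
  if (any(ann$end_sample > rec$n_samples)) {
    stop("annotation exceeds recording length in ", rec$recording_id)
  }
  lapply(seq_len(nrow(ann)), function(i) {
    idx <- (ann$start_sample[i] + 1L):ann$end_sample[i]
    sites <- lapply(rec$sites, function(blk) {
      out <- channel_block(blk$acc[idx, , drop = FALSE],
                           blk$gyro[idx, , drop = FALSE],
                           blk$mag[idx, , drop = FALSE],
                           normalized = blk$normalized)
      out
    })
    list(sites = sites, label = ann$label[i], trial_id = ann$trial_id[i],
         n_samples = length(idx))
  })
}

## linear interpolation of an n x 3 matrix onto n_out evenly spaced points,
## endpoints preserved exactly
resample_matrix <- function(m, n_out) {
  n <- nrow(m)
  if (n == n_out) return(m)
  xout <- seq(0, n - 1, length.out = n_out)
  apply(m, 2, function(col) stats::approx(x = 0:(n - 1), y = col,
                                          xout = xout)$y)
}

#' Resample a segment to an integer multiple of the window width
#'
#' Linear interpolation onto `L' = max(Wl, Wl * round(L / Wl))` evenly
#' spaced points, so the subsequent windowing covers the whole signal; first
#' and last samples are preserved exactly. A segment already a multiple of
#' `Wl` is returned unchanged.
#'
#' @param segment a segment from [extract_segments()] (or a single
#'   [channel_block()]).
#' @param Wl window width in samples (128).
#' @return The resampled segment (same structure as the input).
#' @export
resample_to_window_multiple <- function(segment, Wl = 128L) {
  resample_block <- function(blk, n_out) {
    channel_block(resample_matrix(blk$acc, n_out),
                  resample_matrix(blk$gyro, n_out),
                  resample_matrix(blk$mag, n_out),
                  normalized = blk$normalized)
  }
  if (inherits(segment, "channel_block")) {
    L <- nrow(segment$acc)
    if (L < 1L) stop("empty segment")
    return(resample_block(segment, max(Wl, Wl * round(L / Wl))))
  }
  L <- segment$n_samples
  if (L < 1L) stop("empty segment")
  n_out <- max(Wl, Wl * round(L / Wl))
  segment$sites <- lapply(segment$sites, resample_block, n_out = n_out)
  segment$n_samples <- n_out
  segment
}

#' Window tensor
#'
#' The network input container: per-modality arrays of shape
#' `(Nw, Wl, Nc)` where `Nw` is the number of sub-windows, `Wl = 128` the
#' window width and `Nc = 3 * n_sites` the channel count (site-major, axes
#' x/y/z within each site), plus per-window labels and trial identities.
#'
#' @param acc,gyro,mag arrays `(Nw, Wl, Nc)`.
#' @param labels per-window activity labels.
#' @param trial_ids per-window trial identity strings.
#' @param sites site codes the channels belong to, canonical order.
#' @return An object of class `window_tensor`.
#' @export
window_tensor <- function(acc, gyro, mag, labels, trial_ids, sites) {
  d <- dim(acc)
  if (length(d) != 3L) stop("modality arrays must be 3-dimensional")
  if (!identical(dim(gyro), d) || !identical(dim(mag), d)) {
    stop("acc, gyro and mag must share the same (Nw, Wl, Nc) shape")
  }
  if (d[2] != 128L) stop("window width must be 128 samples")
  if (d[3] != 3L * length(sites)) stop("Nc must equal 3 * n_sites")
  labels <- activity_factor(labels)
  if (length(labels) != d[1] || length(trial_ids) != d[1]) {
    stop("labels and trial_ids must have one entry per window")
  }
  structure(list(acc = acc, gyro = gyro, mag = mag,
                 labels = labels, trial_ids = as.character(trial_ids),
                 Wl = 128L, Nc = d[3], sites = sites),
            class = "window_tensor")
}

#' @export
print.window_tensor <- function(x, ...) {
  cat(sprintf("<window_tensor> Nw=%d, Wl=%d, Nc=%d (%s)\n",
              n_windows(x), x$Wl, x$Nc, paste(x$sites, collapse = "+")))
  print(table(x$labels))
  invisible(x)
}

#' @rdname window_tensor
#' @param x a `window_tensor`.
#' @return `n_windows()`: the number of sub-windows `Nw`.
#' @export
n_windows <- function(x) dim(x$acc)[1]

#' @rdname window_tensor
#' @param idx integer vector of window indices to keep.
#' @return `tensor_subset()`: the tensor restricted to `idx`.
#' @export
tensor_subset <- function(x, idx) {
  window_tensor(x$acc[idx, , , drop = FALSE], x$gyro[idx, , , drop = FALSE],
                x$mag[idx, , , drop = FALSE], x$labels[idx], x$trial_ids[idx],
                x$sites)
}

#' @rdname window_tensor
#' @param tensors list of `window_tensor`s over the same sites.
#' @return `tensor_rbind()`: their concatenation along the window axis.
#' @export
tensor_rbind <- function(tensors) {
  tensors <- tensors[vapply(tensors, n_windows, integer(1)) > 0L]
  if (length(tensors) == 0L) stop("nothing to combine")
  sites <- tensors[[1]]$sites
  for (tt in tensors) stopifnot(identical(tt$sites, sites))
  bindarr <- function(m) {
    arrs <- lapply(tensors, `[[`, m)
    d <- dim(arrs[[1]])
    out <- array(0, c(sum(vapply(arrs, function(a) dim(a)[1], integer(1))),
                      d[2], d[3]))
    at <- 0L
    for (a in arrs) {
      out[at + seq_len(dim(a)[1]), , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  window_tensor(bindarr("acc"), bindarr("gyro"), bindarr("mag"),
                unlist(lapply(tensors, function(tt) as.character(tt$labels))),
                unlist(lapply(tensors, `[[`, "trial_ids")),
                sites)
}

#' Cut a resampled segment into overlapping sub-windows
#'
#' With window width `Wl = 128` and hop 64 (50% overlap), a segment of
#' length `L` (a multiple of 128) yields `Nw = (L - Wl)/hop + 1 =
#' 2 L / 128 - 1` windows; window `i` (0-based) covers samples
#' `[64 i, 64 i + 128)`. All windows inherit the segment's label and trial
#' identity.
#'
#' @param segment a resampled segment from [resample_to_window_multiple()].
#' @param Wl,hop window width and hop in samples.
#' @return A [window_tensor()].
#' @export
make_windows <- function(segment, Wl = 128L, hop = 64L) {
  L <- segment$n_samples
  if (L < Wl) stop("segment shorter than one window (", L, " samples)")
  if (L %% Wl != 0L) stop("segment length must be a multiple of ", Wl,
                          " (resample first)")
  nw <- as.integer((L - Wl) / hop + 1L)
  sites <- names(segment$sites)
  nc <- 3L * length(sites)
  arr <- function(m) {
    chans <- do.call(cbind, lapply(segment$sites, `[[`, m)) # L x Nc
    out <- array(0, c(nw, Wl, nc))
    for (i in seq_len(nw)) {
      out[i, , ] <- chans[((i - 1L) * hop + 1L):((i - 1L) * hop + Wl), ]
    }
    out
  }
  window_tensor(arr("acc"), arr("gyro"), arr("mag"),
                rep(segment$label, nw), rep(segment$trial_id, nw), sites)
}

#' Magnetometer flip rules
#'
#' Which magnetometer axes invert between the separate-execution and
#' continuous protocols: the turning action flips x and z, the sit-to-stand
#' flips x and y; walking and lying-down are unaffected.
#'
#' @return Named list mapping labels to axis subsets.
#' @export
default_flip_rules <- function() list(TN = c("x", "z"), S2S = c("x", "y"))

#' Flip augmentation
#'
#' For every window whose label has a rule, sign-inverts the listed
#' magnetometer axis channels (for every site), emulating the opposite
#' execution direction of the test protocol. Accelerometer and gyroscope
#' are untouched: linear acceleration and angular velocity do not depend on
#' the orientation with respect to magnetic north. `mode = "append"`
#' concatenates the flipped copies (trial ids suffixed `#flip`);
#' `mode = "replace"` substitutes in place (an involution).
#'
#' @param tensor a [window_tensor()].
#' @param rules as [default_flip_rules()].
#' @param mode `"append"` or `"replace"`.
#' @return The augmented `window_tensor`.
#' @export
augment_flip <- function(tensor, rules = default_flip_rules(),
                         mode = c("append", "replace")) {
  mode <- match.arg(mode)
  bad <- setdiff(unlist(rules), imu_axes())
  if (length(bad) > 0L) stop("flip rule names unknown axis: ",
                             paste(bad, collapse = ", "))
  activity_encoding(names(rules))
  hit <- which(as.character(tensor$labels) %in% names(rules))
  if (length(hit) == 0L) return(tensor)
  flipped <- tensor$mag
  for (lab in names(rules)) {
    rows <- which(as.character(tensor$labels) == lab)
    if (length(rows) == 0L) next
    ax <- match(rules[[lab]], imu_axes())
    cols <- as.vector(outer(ax, (seq_along(tensor$sites) - 1L) * 3L, `+`))
    flipped[rows, , cols] <- -flipped[rows, , cols]
  }
  if (mode == "replace") {
    tensor$mag <- flipped
    return(tensor)
  }
  extra <- window_tensor(tensor$acc[hit, , , drop = FALSE],
                         tensor$gyro[hit, , , drop = FALSE],
                         flipped[hit, , , drop = FALSE],
                         tensor$labels[hit],
                         paste0(tensor$trial_ids[hit], "#flip"),
                         tensor$sites)
  tensor_rbind(list(tensor, extra))
}

#' Magnitude-scaling class balancing
#'
#' Duplicates minority-class windows, each duplicate multiplied (all
#' channels) by a factor drawn uniformly from `factor_range`, until every
#' class count equals the majority class count. One factor is drawn per
#' duplicated trial copy (windows of a trial stay mutually consistent);
#' duplicate trial ids are suffixed `#sK`. The majority class is untouched.
#'
#' @param tensor a [window_tensor()] with at least one window per class
#'   present.
#' @param factor_range scaling interval, default `[0.8, 1.2]`, emulating
#'   slight magnitude differences among repetitions.
#' @param seed integer seed.
#' @return The balanced `window_tensor`.
#' @export
augment_scale_balance <- function(tensor, factor_range = c(0.8, 1.2), seed = 1) {
  if (n_windows(tensor) == 0L) stop("empty tensor")
  counts <- table(factor(as.character(tensor$labels),
                         levels = unique(as.character(tensor$labels))))
  target <- max(counts)
  set.seed(as.integer(seed %% 2147483647))
  pieces <- list(tensor)
  for (lab in names(counts)) {
    deficit <- target - counts[[lab]]
    if (deficit == 0L) next
    rows <- which(as.character(tensor$labels) == lab)
    trials <- unique(tensor$trial_ids[rows])
    round_k <- 0L
    while (deficit > 0L) {
      round_k <- round_k + 1L
      for (tr in sample(trials)) {
        if (deficit <= 0L) break
        tr_rows <- rows[tensor$trial_ids[rows] == tr]
        take <- utils::head(tr_rows, deficit)
        f <- stats::runif(1, factor_range[1], factor_range[2])
        dup <- tensor_subset(tensor, take)
        dup$acc <- dup$acc * f
        dup$gyro <- dup$gyro * f
        dup$mag <- dup$mag * f
        dup$trial_ids <- paste0(dup$trial_ids, "#s", round_k)
        pieces[[length(pieces) + 1L]] <- dup
        deficit <- deficit - length(take)
      }
    }
  }
  if (length(pieces) == 1L) return(tensor)
  tensor_rbind(pieces)
}

#' Assemble a windowed dataset for a sensor combination
#'
#' Runs the full preprocessing chain: restrict each recording to the sensor
#' combination, min-max normalize, extract annotated segments, resample each
#' to a multiple of 128 samples, cut into overlapping sub-windows, and
#' concatenate; with `augment = TRUE` (training data) magnetometer flip
#' augmentation and magnitude-scaling class balancing are applied.
#'
#' @param dataset list with `recordings` and `annotations`, e.g. from
#'   [generate_separate_dataset()].
#' @param combo a [sensor_combination()] (or site vector / name).
#' @param augment logical; apply the two augmentation techniques.
#' @param seed integer seed for the balancing draws.
#' @param flip_mode passed to [augment_flip()].
#' @param factor_range passed to [augment_scale_balance()].
#' @param rules passed to [augment_flip()].
#' @param normalization scope of the min-max statistics: `"dataset"`
#'   (default) pools per-channel min/max over all recordings of the dataset
#'   — one shared affine map, so baselines keep the same meaning across
#'   recordings and protocols; `"recording"` uses each recording's own
#'   ranges.
#' @param stats optional externally computed ranges (see
#'   [normalization_stats()]); typically the training dataset's statistics
#'   applied to the test set. Overrides `normalization`.
#' @return A [window_tensor()].
#' @export
assemble <- function(dataset, combo, augment = FALSE, seed = 1,
                     flip_mode = "append", factor_range = c(0.8, 1.2),
                     rules = default_flip_rules(),
                     normalization = c("dataset", "recording"), stats = NULL) {
  normalization <- match.arg(normalization)
  if (!inherits(combo, "sensor_combination")) combo <- sensor_combination(combo)
  if (is.null(stats) && normalization == "dataset") {
    stats <- normalization_stats(dataset$recordings)
  }
  tensors <- list()
  for (rec in dataset$recordings) {
    segs <- extract_segments(normalize(select_sensors(rec, combo), stats = stats),
                             dataset$annotations)
    for (sg in segs) {
      tensors[[length(tensors) + 1L]] <-
        make_windows(resample_to_window_multiple(sg))
    }
  }
  if (length(tensors) == 0L) stop("no annotated segments in dataset")
  out <- tensor_rbind(tensors)
  if (augment) {
    out <- augment_flip(out, rules = rules, mode = flip_mode)
    out <- augment_scale_balance(out, factor_range = factor_range, seed = seed)
  }
  out
}
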