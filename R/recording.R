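# Core containers: a channel block (one site's nine channels), a multi-site
# recording, and a sensor combination. Modality matrices are stored with time
# in rows and axes x, y, z in columns.

#' Build a channel block
#'
#' One sensor site's data: three `n_samples x 3` matrices (accelerometer,
#' gyroscope, magnetometer; columns x, y, z).
#'
#' @param acc,gyro,mag numeric matrices with 3 columns and a common number of
#'   rows.
#' @param normalized logical; `TRUE` once the block has been min-max mapped
#'   to `[-1, 1]`.
#' @return An object of class `channel_block`.
#' @export
channel_block <- function(acc, gyro, mag, normalized = FALSE) {
  blk <- list(acc = as_axis_matrix(acc), gyro = as_axis_matrix(gyro),
              mag = as_axis_matrix(mag), normalized = isTRUE(normalized))
  n <- vapply(blk[imu_modalities()], nrow, integer(1))
  if (length(unique(n)) != 1L) {
    stop("acc, gyro and mag must share the same number of samples")
  }
  structure(blk, class = "channel_block")
}

as_axis_matrix <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("each modality needs exactly 3 axis columns")
  if (!is.numeric(m)) stop("channel data must be numeric")
  colnames(m) <- imu_axes()
  storage.mode(m) <- "double"
  m
}

#' Build an IMU recording
#'
#' A multi-site recording sampled at 128 Hz. Sites are stored in canonical
#' order (RW, RP, LP, S) restricted to the sites present; each site holds
#' nine channels of equal length.
#'
#' @param recording_id,subject_id identifier strings.
#' @param protocol `"separate"` (one activity per acquisition) or
#'   `"continuous"` (circuit execution).
#' @param sites named list of [channel_block()] objects; names are site codes.
#' @param sample_rate_hz sampling rate; must be 128.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(recording_id, subject_id, protocol, sites,
                          sample_rate_hz = char_sample_rate()) {
  protocol <- match.arg(protocol, c("separate", "continuous"))
  if (!identical(as.numeric(sample_rate_hz), 128)) {
    stop("sample_rate_hz must be 128")
  }
  if (length(sites) == 0L) stop("a recording needs at least one site")
  bad <- setdiff(names(sites), sensor_sites())
  if (length(bad) > 0L) stop("unknown sensor site(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(sites))) stop("duplicated sensor site")
  sites <- sites[intersect(sensor_sites(), names(sites))] # canonical order
  for (s in names(sites)) {
    if (!inherits(sites[[s]], "channel_block")) {
      stop("site ", s, " is not a channel_block")
    }
  }
  n <- vapply(sites, function(b) nrow(b$acc), integer(1))
  if (length(unique(n)) != 1L) stop("all sites must share n_samples")
  structure(list(recording_id = as.character(recording_id),
                 subject_id = as.character(subject_id),
                 protocol = protocol,
                 sample_rate_hz = 128,
                 sites = sites,
                 n_samples = unname(n[1])),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s  subject=%s  protocol=%s\n",
              x$recording_id, x$subject_id, x$protocol))
  cat(sprintf("  %d samples @ %g Hz (%.2f s), sites: %s\n",
              x$n_samples, x$sample_rate_hz, x$n_samples / x$sample_rate_hz,
              paste(names(x$sites), collapse = "+")))
  invisible(x)
}

#' Sensor combinations
#'
#' A sensor combination is a non-empty subset of the four sites, kept in
#' canonical order. `sensor_combination()` accepts either a character vector
#' of site codes or a single `"RW+RP"`-style name. `studied_combinations()`
#' returns the eleven combinations of at least two sensors evaluated in the
#' framework: the six pairs, four triples and the full quadruple.
#'
#' @param sites character vector of site codes, or one `+`-separated name.
#' @return `sensor_combination()`: an object of class `sensor_combination`
#'   with fields `sites` and `name`; the per-branch channel count is
#'   `3 * length(sites)`.
#' @export
sensor_combination <- function(sites) {
  if (length(sites) == 1L && grepl("+", sites, fixed = TRUE)) {
    sites <- strsplit(sites, "+", fixed = TRUE)[[1]]
  }
  sites <- as.character(sites)
  bad <- setdiff(sites, sensor_sites())
  if (length(bad) > 0L) stop("unknown sensor site(s): ", paste(bad, collapse = ", "))
  if (length(sites) == 0L) stop("a sensor combination cannot be empty")
  if (anyDuplicated(sites)) stop("duplicated site in combination")
  sites <- intersect(sensor_sites(), sites)
  structure(list(sites = sites, name = paste(sites, collapse = "+"),
                 n_channels = 3L * length(sites)),
            class = "sensor_combination")
}

#' @rdname sensor_combination
#' @return `studied_combinations()`: named list of the 11 studied
#'   `sensor_combination` objects.
#' @export
studied_combinations <- function() {
  sites <- sensor_sites()
  combos <- list()
  for (k in 2:4) {
    for (idx in utils::combn(4, k, simplify = FALSE)) {
      cmb <- sensor_combination(sites[idx])
      combos[[cmb$name]] <- cmb
    }
  }
  combos
}

#' @export
print.sensor_combination <- function(x, ...) {
  cat(sprintf("<sensor_combination> %s (Nc = %d per branch)\n",
              x$name, x$n_channels))
  invisible(x)
}

#' Restrict a recording to a sensor combination
#'
#' Returns a recording containing exactly the combination's sites, in
#' canonical order, with the data untouched.
#'
#' @param rec an [imu_recording()].
#' @param combo a [sensor_combination()] (or anything it accepts).
#' @return An `imu_recording` with only the requested sites.
#' @export
select_sensors <- function(rec, combo) {
  stopifnot(inherits(rec, "imu_recording"))
  if (!inherits(combo, "sensor_combination")) combo <- sensor_combination(combo)
  missing <- setdiff(combo$sites, names(rec$sites))
  if (length(missing) > 0L) {
    stop("site(s) not present in recording ", rec$recording_id, ": ",
         paste(missing, collapse = ", "))
  }
  out <- rec
  out$sites <- rec$sites[combo$sites]
  out
}
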