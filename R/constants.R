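# Fixed vocabulary of the framework: sensor sites, modalities, axes and
# activity classes. Orders here are canonical and used everywhere so that the
# channel layout fed to the network is deterministic across runs.

#' Canonical sensor sites
#'
#' The four body-worn IMU sites in canonical order: right wrist (RW), right
#' pelvis (RP), left pelvis (LP) and sternum (S). Every multi-site container
#' in the package keeps its sites in this order.
#'
#' @return Character vector of the four site codes.
#' @export
sensor_sites <- function() c("RW", "RP", "LP", "S")

#' Sensing modalities and axes
#'
#' Each site carries nine channels: a 3-axis accelerometer, gyroscope and
#' magnetometer, with axes x, y, z.
#'
#' @return Character vector of the three modality codes.
#' @export
imu_modalities <- function() c("acc", "gyro", "mag")

#' @rdname imu_modalities
#' @export
imu_axes <- function() c("x", "y", "z")

#' Activity classes
#'
#' The four activities of daily living, in the fixed (alphabetical) order
#' that defines their integer encoding and the meaning of the softmax
#' columns: Lying-down (LD = 0), Sit-to-stand (S2S = 1), Turning (TN = 2),
#' Walking (W = 3).
#'
#' @return Character vector of the four class codes, in encoding order.
#' @export
activity_labels <- function() c("LD", "S2S", "TN", "W")

#' @rdname activity_labels
#' @param label character vector of class codes.
#' @return `activity_encoding()`: integer codes (0-based) for `label`.
#' @export
activity_encoding <- function(label) {
  label <- as.character(label)
  bad <- setdiff(unique(label), activity_labels())
  if (length(bad) > 0L) {
    stop("unknown activity label(s): ", paste(bad, collapse = ", "))
  }
  match(label, activity_labels()) - 1L
}

#' @rdname activity_labels
#' @return `activity_factor()`: `label` as a factor with the canonical levels.
#' @export
activity_factor <- function(label) {
  activity_encoding(label) # validates
  factor(as.character(label), levels = activity_labels())
}

## sampling rate (Hz) and window geometry (samples) are protocol constants
CHAR_SAMPLE_RATE <- 128
CHAR_WINDOW <- 128L
CHAR_HOP <- 64L

#' Sampling rate of the acquisition protocol
#'
#' @return The fixed sampling rate, 128 Hz.
#' @export
char_sample_rate <- function() CHAR_SAMPLE_RATE
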