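# Plain-text I/O. Recordings are CSV files with one row per sample and a
# fixed header grammar <site>_<modality>_<axis> (e.g. RW_acc_x); annotations
# are 5-column CSVs of half-open, 0-based labeled sample intervals; a dataset
# is a directory of both plus a manifest.

channel_names_for <- function(sites) {
  unlist(lapply(sites, function(s)
    paste(s, rep(imu_modalities(), each = 3), imu_axes(), sep = "_")),
    use.names = FALSE)
}

#' Write / read a recording CSV
#'
#' `write_recording()` stores one row per sample and one column per channel,
#' header `<site>_<modality>_<axis>`, sites in canonical order.
#' `read_recording()` accepts the columns in any order and restores the
#' canonical layout; every site named in the header must come with all nine
#' channels.
#'
#' @param rec an [imu_recording()].
#' @param path CSV file path.
#' @return `write_recording()`: `path`, invisibly. `read_recording()`: an
#'   `imu_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  cols <- lapply(names(rec$sites), function(s) {
    blk <- rec$sites[[s]]
    do.call(cbind, lapply(imu_modalities(), function(m) blk[[m]]))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- channel_names_for(names(rec$sites))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param recording_id,subject_id,protocol metadata not stored in the CSV
#'   itself; normally supplied by the dataset manifest. `recording_id`
#'   defaults to the file name without extension.
#' @export
read_recording <- function(path, recording_id = NULL, subject_id = NA_character_,
                           protocol = "separate") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(recording_id)) {
    recording_id <- sub("\\.[^.]*$", "", basename(path))
  }
  parts <- strsplit(names(df), "_", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 3L
  if (!all(ok)) stop("malformed channel column name(s): ",
                     paste(names(df)[!ok], collapse = ", "))
  sites_present <- unique(vapply(parts, `[[`, "", 1L))
  bad <- setdiff(sites_present, sensor_sites())
  if (length(bad) > 0L) stop("unknown sensor site(s) in header: ",
                             paste(bad, collapse = ", "))
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (nrow(df) > 0L && !is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad_row <- which(is.na(num) & !is.na(v))[1]
      stop(sprintf("non-numeric value in column %s at data row %d",
                   names(df)[j], if (is.na(bad_row)) NA_integer_ else bad_row))
    }
  }
  sites <- list()
  for (s in intersect(sensor_sites(), sites_present)) {
    want <- channel_names_for(s)
    missing <- setdiff(want, names(df))
    if (length(missing) > 0L) {
      stop("missing channel column(s) for site ", s, ": ",
           paste(missing, collapse = ", "))
    }
    grab <- function(m) {
      x <- as.matrix(df[paste(s, m, imu_axes(), sep = "_")])
      storage.mode(x) <- "double" # header-only files parse as logical
      x
    }
    sites[[s]] <- channel_block(grab("acc"), grab("gyro"), grab("mag"))
  }
  imu_recording(recording_id, subject_id, protocol, sites)
}

#' Read / write segment annotations
#'
#' Annotations are labeled, half-open, 0-based sample intervals
#' `[start_sample, end_sample)` with a trial identity. The reader validates
#' labels, interval sanity and pairwise non-overlap within each recording,
#' and returns the rows sorted by `(recording_id, start_sample)`.
#'
#' @param path CSV path with columns `recording_id`, `start_sample`,
#'   `end_sample`, `label`, `trial_id`.
#' @return A `data.frame` of validated annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = c(
    recording_id = "character", start_sample = "integer",
    end_sample = "integer", label = "character", trial_id = "character"))
  validate_annotations(df)
}

#' @rdname read_annotations
#' @param ann annotation `data.frame` to validate or write.
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
validate_annotations <- function(ann) {
  need <- c("recording_id", "start_sample", "end_sample", "label", "trial_id")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0L) stop("annotation columns missing: ",
                                 paste(missing, collapse = ", "))
  ann <- as.data.frame(ann)[need]
  activity_encoding(ann$label) # validates labels
  if (any(ann$start_sample < 0L)) stop("negative start_sample")
  if (any(ann$end_sample <= ann$start_sample)) {
    stop("empty or inverted annotation interval for trial ",
         ann$trial_id[which(ann$end_sample <= ann$start_sample)[1]])
  }
  ann <- ann[order(ann$recording_id, ann$start_sample), , drop = FALSE]
  rownames(ann) <- NULL
  for (rid in unique(ann$recording_id)) {
    a <- ann[ann$recording_id == rid, , drop = FALSE]
    if (nrow(a) > 1L) {
      ov <- which(a$start_sample[-1] < a$end_sample[-nrow(a)])
      if (length(ov) > 0L) {
        stop(sprintf("overlapping annotations in recording %s: trials %s and %s",
                     rid, a$trial_id[ov[1]], a$trial_id[ov[1] + 1L]))
      }
    }
  }
  ann
}

#' Write / read a dataset directory
#'
#' A dataset is a directory holding one CSV per recording, one annotation
#' CSV, and a `manifest.csv` naming each recording's file, subject, protocol
#' and annotation file.
#'
#' @param dataset list with elements `recordings` (list of
#'   [imu_recording()]) and `annotations` (annotation `data.frame`).
#' @param dir directory to create/read.
#' @return `write_dataset()`: `dir`, invisibly; `read_dataset()`: a dataset
#'   list as above.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset$recordings, function(r) {
    f <- paste0(r$recording_id, ".csv")
    write_recording(r, file.path(dir, f))
    data.frame(recording_id = r$recording_id, path = f,
               subject_id = r$subject_id, protocol = r$protocol,
               annotations_path = "annotations.csv")
  })
  write_annotations(dataset$annotations, file.path(dir, "annotations.csv"))
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         colClasses = "character")
  recs <- lapply(seq_len(nrow(man)), function(i) {
    read_recording(file.path(dir, man$path[i]),
                   recording_id = man$recording_id[i],
                   subject_id = man$subject_id[i],
                   protocol = man$protocol[i])
  })
  names(recs) <- man$recording_id
  ann <- read_annotations(file.path(dir, unique(man$annotations_path)[1]))
  list(recordings = recs, annotations = ann)
}
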