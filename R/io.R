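#' Construct a triaxial acceleration recording
#'
#' @param x A `3 x T` numeric matrix of accelerations in g (axes in rows).
#' @param fs Sampling frequency, Hz.
#' @param subject_id Subject identifier.
#' @param label Class label: `"control"`, `"PD"` or `"unknown"`.
#' @param t0 Recording start as an ISO-8601 timestamp string; sample times
#'   are seconds from `t0`.
#' @param sex Optional sex marker (`"M"`, `"F"` or `NA`), carried through to
#'   cohort manifests for stratified reporting.
#' @param validate Check samples for non-finite values. Internal callers
#'   that construct provably finite signals may skip the scan.
#' @return An `accel_recording` object.
#' @export
accel_recording <- function(x, fs, subject_id, label = "unknown",
                            t0 = "2000-01-01T00:00:00Z", sex = NA_character_,
                            validate = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("format error: 'x' must be a numeric matrix")
  if (nrow(x) != 3L)
    stop("format error: expected 3 acceleration channels, got ", nrow(x))
  if (ncol(x) < 1L) stop("invalid recording: T must be >= 1")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("invalid recording: fs must be positive")
  if (validate) {
    if (anyNA(x)) {
      idx <- which(is.na(x))[1L]
      stop("data error: non-finite sample at index ", idx)
    }
    rng <- range(x)
    if (!all(is.finite(rng))) {
      idx <- which(!is.finite(x))[1L]
      stop("data error: non-finite sample at index ", idx)
    }
  }
  if (!label %in% c("control", "PD", "unknown"))
    stop("invalid recording: label must be control, PD or unknown")
  structure(list(subject_id = as.character(subject_id), fs = fs, x = x,
                 t0 = as.character(t0), label = label,
                 sex = as.character(sex)),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject=%s label=%s fs=%g Hz T=%d (%.2f h) t0=%s\n",
              x$subject_id, x$label, x$fs, ncol(x$x),
              ncol(x$x) / x$fs / 3600, x$t0))
  invisible(x)
}

#' Recording duration in days
#' @param rec An [accel_recording()].
#' @return Recorded span in days (length / 86400 s).
#' @export
recording_days <- function(rec) ncol(rec$x) / rec$fs / 86400

#' Write a recording to a Parquet container
#'
#' Samples are stored losslessly as three float64 columns `x`, `y`, `z`;
#' `fs`, `subject_id`, `label`, `sex` and `t0` travel in the file's
#' key-value metadata.
#'
#' @param rec An [accel_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  tb <- arrow::arrow_table(x = rec$x[1L, ], y = rec$x[2L, ], z = rec$x[3L, ])
  tb$metadata$wpd_fs <- format(rec$fs, digits = 17)
  tb$metadata$wpd_subject_id <- rec$subject_id
  tb$metadata$wpd_label <- rec$label
  tb$metadata$wpd_sex <- rec$sex
  tb$metadata$wpd_t0 <- rec$t0
  arrow::write_parquet(tb, path)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to a Parquet recording.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  tb <- tryCatch(arrow::read_parquet(path, as_data_frame = FALSE),
                 error = function(e) stop("format error reading ", path, ": ",
                                          conditionMessage(e)))
  cols <- names(tb)
  if (!all(c("x", "y", "z") %in% cols))
    stop("format error: expected 3 channels (columns x,y,z), found: ",
         paste(cols, collapse = ","))
  md <- tb$metadata
  df <- as.data.frame(tb)
  accel_recording(rbind(df$x, df$y, df$z),
                  fs = as.numeric(md$wpd_fs),
                  subject_id = md$wpd_subject_id,
                  label = md$wpd_label,
                  t0 = md$wpd_t0,
                  sex = if (is.null(md$wpd_sex)) NA_character_ else md$wpd_sex)
}

#' Import a recording from CSV
#'
#' Interoperability path for externally converted data. The file must have
#' a header `time,x,y,z` with time in seconds (uniformly spaced) and
#' accelerations in g; the sampling frequency is inferred from the time
#' column.
#'
#' @param path Path to a CSV file.
#' @inheritParams accel_recording
#' @return An [accel_recording()].
#' @export
read_recording_csv <- function(path, subject_id = basename(path),
                               label = "unknown",
                               t0 = "2000-01-01T00:00:00Z") {
  df <- read.csv(path)
  if (!identical(names(df), c("time", "x", "y", "z")))
    stop("format error: expected CSV header time,x,y,z, found: ",
         paste(names(df), collapse = ","))
  if (nrow(df) < 2L) stop("format error: need at least 2 samples")
  dt <- diff(df$time)
  if (any(abs(dt - dt[1L]) > 1e-6))
    stop("data error: time column is not uniformly spaced")
  accel_recording(rbind(df$x, df$y, df$z), fs = 1 / dt[1L],
                  subject_id = subject_id, label = label, t0 = t0)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id,path,label` and optionally
#' `sex`. Paths are resolved relative to the manifest's directory. Subject
#' order is preserved exactly as listed.
#'
#' @param path Path to a manifest CSV.
#' @param check_paths Verify that every recording path resolves.
#' @return A data.frame with class `wpd_manifest`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  df <- read.csv(path, colClasses = "character")
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(df)))
    stop("format error: manifest must have columns subject_id,path,label")
  if (anyDuplicated(df$subject_id))
    stop("invalid manifest: duplicated subject_id")
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(root, df$path))
  if (check_paths && !all(file.exists(abs)))
    stop("invalid manifest: unresolvable path(s): ",
         paste(df$path[!file.exists(abs)], collapse = ", "))
  df$path <- abs
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  class(df) <- c("wpd_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest A data.frame with columns `subject_id,path,label` (and
#'   optionally `sex`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest)[, intersect(
    c("subject_id", "path", "label", "sex"), names(manifest))],
    path, row.names = FALSE)
  invisible(path)
}
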