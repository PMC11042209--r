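#' Read a per-view keypoint track table
#'
#' Reads tracker output for one view. The CSV layout flattens the usual
#' two-row (keypoint / coordinate) header into single columns named
#' `<keypoint>_u`, `<keypoint>_v`, `<keypoint>_likelihood`, preceded by a
#' 0-based `frame` column. Low-likelihood rows are preserved as-is;
#' filtering happens later in [preprocess()].
#'
#' @param path file path.
#' @param dialect `"csv"`. (`"hdf5"` is recognised but not available in this
#'   build; requesting it raises an informative error.)
#' @param view_id view the table belongs to; defaults to `"front"`.
#' @param fs sampling rate in frames/s.
#' @param keypoints optional character vector of keypoints that must be
#'   present; a missing keypoint column raises an error naming it.
#' @return A [keypoint_track()].
#' @export
read_track_table <- function(path, dialect = c("csv", "hdf5"),
                             view_id = "front", fs = 100, keypoints = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    stop("the 'hdf5' track dialect is not supported by this build; ",
         "use 'csv'", call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"frame" %in% names(df)) {
    stop("track table lacks a 'frame' column", call. = FALSE)
  }
  frames <- as.integer(df$frame)
  if (length(frames) > 1L && any(diff(frames) != 1L)) {
    stop("track table frames are not contiguous", call. = FALSE)
  }
  suf <- c("_u", "_v", "_likelihood")
  found <- unique(sub("_(u|v|likelihood)$", "",
                      grep("_(u|v|likelihood)$", names(df), value = TRUE)))
  if (is.null(keypoints)) keypoints <- found
  kps <- list()
  for (kp in keypoints) {
    cols <- paste0(kp, suf)
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("missing keypoint column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    kps[[kp]] <- data.frame(u = df[[cols[1]]], v = df[[cols[2]]],
                            likelihood = df[[cols[3]]])
  }
  keypoint_track(view_id, kps, fs = fs, frames = frames)
}

#' Write a keypoint track table
#'
#' @param track a [keypoint_track()].
#' @param path output file.
#' @param dialect `"csv"` (see [read_track_table()] for the layout).
#' @return `path`, invisibly.
#' @export
write_track_table <- function(track, path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf5") {
    stop("the 'hdf5' track dialect is not supported by this build; ",
         "use 'csv'", call. = FALSE)
  }
  out <- data.frame(frame = track$frames)
  for (kp in names(track$keypoints)) {
    df <- track$keypoints[[kp]]
    out[[paste0(kp, "_u")]] <- df$u
    out[[paste0(kp, "_v")]] <- df$v
    out[[paste0(kp, "_likelihood")]] <- df$likelihood
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Parse an acquisition sensor log
#'
#' The behavioral controller streams one row per logged tick: the camera
#' frame number first, then one column per data stream (front-bar touch,
#' floor touch, beam break, ...). Channels are kept as untyped integers;
#' boolean semantics are applied only by edge queries such as
#' [rising_edges()].
#'
#' @param path CSV file whose first column is the camera frame number and
#'   whose header names the channels.
#' @return A data.frame of class `sensor_log`.
#' @export
parse_sensor_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (ncol(df) < 1L) stop("sensor log has no columns", call. = FALSE)
  names(df)[1] <- "frame"
  if (nrow(df) > 1L && any(diff(df$frame) < 0)) {
    stop("sensor log frame numbers decrease: corrupt log", call. = FALSE)
  }
  class(df) <- c("sensor_log", "data.frame")
  df
}

#' Rising edges of a sensor channel
#'
#' Frames at which a channel transitions from 0 to a positive value. Rising
#' edges of the front-bar touch channel are the candidate trial starts.
#'
#' @param log a `sensor_log` (or any data.frame with a `frame` column).
#' @param channel channel (column) name.
#' @return Integer vector of frame numbers (possibly empty).
#' @export
rising_edges <- function(log, channel) {
  if (!channel %in% names(log)) {
    stop(sprintf("no such channel: %s", channel), call. = FALSE)
  }
  if (nrow(log) < 2L) return(integer(0))
  on <- log[[channel]] > 0
  log$frame[which(diff(on) == 1L) + 1L]
}

#' Write a sensor log
#' @param log a `sensor_log` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' Write a per-reach scalar table
#'
#' One row per scored reach with the fixed column set documented in
#' [scalar_table()]. CSV, full double precision.
#'
#' @param table a scalar table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scalar_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write a calibration correspondence table
#'
#' Flat table of 3D checkerboard corners and their image points, one row per
#' corner per view: `view, point_id, X, Y, Z, u, v`.
#'
#' @param corr correspondence data.frame (e.g. from
#'   [calibration_fixture()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correspondences <- function(corr, path) {
  need <- c("view", "point_id", "X", "Y", "Z", "u", "v")
  miss <- setdiff(need, names(corr))
  if (length(miss)) {
    stop(sprintf("correspondence table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  utils::write.csv(corr[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration correspondence table
#' @param path CSV written by [write_correspondences()].
#' @return Correspondence data.frame.
#' @export
read_correspondences <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("view", "point_id", "X", "Y", "Z", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("correspondence table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a per-reach scalar table
#' @param path CSV written by [write_scalar_table()].
#' @return A data.frame with one row per reach.
#' @export
read_scalar_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- scalar_table_columns()
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("scalar table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}
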