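#' 2D keypoint track for one camera view
#'
#' Container for markerless-tracker output in one view: per frame and per
#' keypoint an image position `(u, v)` in pixels and a tracking `likelihood`
#' in `[0, 1]`. Frames are 0-based and contiguous; time is `frame / fs`
#' seconds. All keypoints share the frame index.
#'
#' @param view_id one of `"front"`, `"left_mirror"`, `"right_mirror"`.
#' @param keypoints named list; each element a data.frame with columns
#'   `u`, `v`, `likelihood` and one row per frame.
#' @param fs sampling rate in frames/s (default 100, the acquisition rate
#'   used throughout).
#' @param frames integer vector of 0-based frame indices; defaults to
#'   `0:(n-1)`. Must be contiguous with step 1.
#' @return An object of class `keypoint_track`.
#' @export
keypoint_track <- function(view_id, keypoints, fs = 100,
                           frames = NULL) {
  view_id <- match.arg(view_id, c("front", "left_mirror", "right_mirror"))
  stopifnot(is.list(keypoints), length(keypoints) >= 1L,
            !is.null(names(keypoints)))
  n <- nrow(keypoints[[1]])
  for (kp in names(keypoints)) {
    df <- keypoints[[kp]]
    if (!all(c("u", "v", "likelihood") %in% names(df))) {
      stop(sprintf("keypoint '%s' lacks u/v/likelihood columns", kp),
           call. = FALSE)
    }
    if (nrow(df) != n) {
      stop("all keypoints must share the frame index", call. = FALSE)
    }
    lk <- df$likelihood
    if (any(is.finite(lk) & (lk < 0 | lk > 1))) {
      stop(sprintf("likelihood outside [0, 1] for keypoint '%s'", kp),
           call. = FALSE)
    }
  }
  if (is.null(frames)) frames <- seq_len(n) - 1L
  frames <- as.integer(frames)
  if (n > 1L && any(diff(frames) != 1L)) {
    stop("frame index must be contiguous with step 1", call. = FALSE)
  }
  structure(list(view_id = view_id, fs = fs, frames = frames,
                 keypoints = keypoints),
            class = "keypoint_track")
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("<keypoint_track> view %s, %d frames @ %g Hz, keypoints: %s\n",
              x$view_id, length(x$frames), x$fs,
              paste(names(x$keypoints), collapse = ", ")))
  invisible(x)
}

#' 3D trajectory of one keypoint
#'
#' Per-frame 3D position in millimetres in the behavioral frame: origin at
#' the pellet rest position, +x forward (slit toward pellet), +y sideward,
#' +z upward. `NA` rows mark missing frames.
#'
#' @param xyz n x 3 numeric matrix (columns x, y, z) in mm.
#' @param fs frames per second.
#' @param keypoint keypoint name (e.g. `"palm"`, `"pellet"`).
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(xyz, fs = 100, keypoint = "palm") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(xyz = xyz, fs = fs, keypoint = keypoint),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  fin <- sum(stats::complete.cases(x$xyz))
  cat(sprintf("<trajectory3d> '%s', %d frames @ %g Hz (%d finite)\n",
              x$keypoint, nrow(x$xyz), x$fs, fin))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)
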