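#' Numerical time derivatives of a trajectory
#'
#' Finite-difference derivatives per axis: central differences on interior
#' frames, one-sided differences at the edges of each finite run, applied
#' `order` times with `dt = 1/fs`. Runs shorter than `order + 1` frames
#' yield `NA` with a warning; `NA` propagates with the stencil.
#'
#' @param traj a [trajectory3d()] (derivatives are meaningful only after
#'   [preprocess()] smoothing; third differences of raw 100 Hz tracking are
#'   noise-dominated).
#' @param order 1 (velocity, mm/s), 2 (acceleration, mm/s^2) or
#'   3 (jerk, mm/s^3).
#' @return n x 3 matrix of the derivative time series.
#' @export
differentiate <- function(traj, order = 1L) {
  stopifnot(order %in% 1:3)
  dt <- 1 / traj$fs
  out <- traj$xyz
  for (j in 1:3) out[, j] <- diff_series(traj$xyz[, j], dt, order)
  out
}

diff_series <- function(v, dt, order) {
  out <- rep(NA_real_, length(v))
  short <- FALSE
  for (r in finite_runs(v)) {
    len <- r[2] - r[1] + 1L
    if (len < order + 1L) { short <- TRUE; next }
    s <- v[r[1]:r[2]]
    for (k in seq_len(order)) s <- gradient1(s, dt)
    out[r[1]:r[2]] <- s
  }
  if (short) warning("run too short to differentiate: returned NA")
  out
}

# central differences, one-sided at the two ends (exact for linear series)
gradient1 <- function(s, dt) {
  n <- length(s)
  g <- numeric(n)
  if (n == 1L) return(0)
  g[1] <- (s[2] - s[1]) / dt
  g[n] <- (s[n] - s[n - 1]) / dt
  if (n > 2L) g[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  g
}

#' Kinematic scalars of one reach
#'
#' Computes the per-reach feature vector: duration, endpoint (3D position at
#' the apex, i.e. maximal forward extension, expressed as distance to the
#' pellet per axis since the origin is the pellet rest position), path
#' length, mean and maximum speed, relative timing of the speed peak,
#' maximum acceleration and jerk magnitudes, and the apex position. The
#' endpoint is taken at the apex rather than the segment end because the
#' segment includes the retraction.
#'
#' With missing frames inside the window the scalars are computed on the
#' finite sub-runs and `complete_frac` records the finite fraction; below
#' 50% the reach is flagged (`ok = FALSE`, scalars `NA`) and will classify
#' as an artifact.
#'
#' @param seg one row of a [reach_segments()] table (or a list with
#'   `start`, `end`, `apex`).
#' @param traj aligned palm [trajectory3d()].
#' @return One-row data.frame with the scalar columns of [scalar_table()]
#'   plus `complete_frac` and `ok`.
#' @export
compute_scalars <- function(seg, traj) {
  n <- n_frames(traj)
  s <- as.integer(seg$start); e <- as.integer(seg$end)
  a <- as.integer(seg$apex)
  stopifnot(s >= 0, s < e, e <= n, a >= s, a < e)
  rows <- (s + 1):e
  w <- trajectory3d(traj$xyz[rows, , drop = FALSE], fs = traj$fs,
                    keypoint = traj$keypoint)
  fin <- stats::complete.cases(w$xyz)
  complete_frac <- mean(fin)
  duration <- (e - s) / traj$fs
  na_row <- data.frame(
    start_frame = s, end_frame = e, duration_s = duration,
    end_x_mm = NA_real_, end_y_mm = NA_real_, end_z_mm = NA_real_,
    path_mm = NA_real_, vmean_mm_s = NA_real_, vmax_mm_s = NA_real_,
    tvmax_frac = NA_real_, amax_mm_s2 = NA_real_, jmax_mm_s3 = NA_real_,
    apex_x_mm = NA_real_, apex_y_mm = NA_real_, apex_z_mm = NA_real_,
    complete_frac = complete_frac, ok = FALSE)
  if (complete_frac < 0.5) return(na_row)
  xyz <- w$xyz
  steps <- diff(xyz)
  step_ok <- stats::complete.cases(steps)
  path <- sum(sqrt(rowSums(steps[step_ok, , drop = FALSE]^2)))
  vel <- differentiate(w, 1L)
  speed <- sqrt(rowSums(vel^2))
  acc <- differentiate(w, 2L)
  jrk <- differentiate(w, 3L)
  apex_xyz <- traj$xyz[a + 1L, ]
  imax <- which.max(speed)
  out <- na_row
  out$end_x_mm <- apex_xyz[1]; out$end_y_mm <- apex_xyz[2]
  out$end_z_mm <- apex_xyz[3]
  out$path_mm <- path
  out$vmean_mm_s <- mean(speed, na.rm = TRUE)
  out$vmax_mm_s <- max(speed, na.rm = TRUE)
  out$tvmax_frac <- (imax - 1) / (e - s)
  out$amax_mm_s2 <- max(sqrt(rowSums(acc^2)), na.rm = TRUE)
  out$jmax_mm_s3 <- max(sqrt(rowSums(jrk^2)), na.rm = TRUE)
  out$apex_x_mm <- apex_xyz[1]; out$apex_y_mm <- apex_xyz[2]
  out$apex_z_mm <- apex_xyz[3]
  out$ok <- TRUE
  out
}

#' Column set of the per-reach scalar table
#' @return Character vector of the fixed column names.
#' @export
scalar_table_columns <- function() {
  c("start_frame", "end_frame", "duration_s",
    "end_x_mm", "end_y_mm", "end_z_mm", "path_mm",
    "vmean_mm_s", "vmax_mm_s", "tvmax_frac",
    "amax_mm_s2", "jmax_mm_s3",
    "apex_x_mm", "apex_y_mm", "apex_z_mm", "label", "cluster")
}

#' Per-reach scalar table
#'
#' One row per scored reach: segment bounds, the kinematic scalars of
#' [compute_scalars()], the outcome label and (optionally) a cluster label.
#'
#' @param segs a [reach_segments()] table.
#' @param traj aligned palm [trajectory3d()].
#' @param labels optional character vector of outcome labels (recycled empty
#'   string when absent).
#' @return A data.frame with the columns of [scalar_table_columns()] plus
#'   `complete_frac` and `ok`.
#' @export
scalar_table <- function(segs, traj, labels = NULL) {
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    compute_scalars(segs[i, ], traj)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- stats::setNames(
      data.frame(matrix(numeric(0), 0, length(scalar_table_columns()))),
      scalar_table_columns())
    out$label <- character(0); out$cluster <- integer(0)
    out$complete_frac <- numeric(0); out$ok <- logical(0)
    return(out[, c(scalar_table_columns(), "complete_frac", "ok")])
  }
  out$label <- if (is.null(labels)) "" else as.character(labels)
  out$cluster <- NA_integer_
  out[, c(scalar_table_columns(), "complete_frac", "ok")]
}

#' Time-normalized average reach trajectory
#'
#' Resamples each reach onto `n_samples` equally spaced points of normalized
#' time (linear interpolation per axis), then averages pointwise. This is
#' the mean +/- SD band underlying directional reach profiles: forward,
#' sideward and upward components expressed as distance to the pellet.
#'
#' @param segs a non-empty [reach_segments()] table.
#' @param traj aligned palm [trajectory3d()].
#' @param n_samples number of resampled time points (default 100).
#' @return List with `tau` (normalized time), `mean` and `sd`
#'   (`n_samples` x 3 matrices) and `n` (number of reaches averaged).
#' @export
average_trajectory <- function(segs, traj, n_samples = 100L) {
  if (nrow(segs) == 0L) stop("no segments to average", call. = FALSE)
  tau <- seq(0, 1, length.out = n_samples)
  arr <- array(NA_real_, c(n_samples, 3, nrow(segs)))
  for (i in seq_len(nrow(segs))) {
    rows <- (segs$start[i] + 1):segs$end[i]
    tt <- seq(0, 1, length.out = length(rows))
    for (j in 1:3) {
      v <- traj$xyz[rows, j]
      fin <- is.finite(v)
      if (sum(fin) >= 2L) {
        arr[, j, i] <- stats::approx(tt[fin], v[fin], xout = tau)$y
      }
    }
  }
  mean_m <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  sd_m <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  sd_m[is.na(sd_m)] <- 0
  dimnames(mean_m) <- dimnames(sd_m) <- list(NULL, c("x", "y", "z"))
  list(tau = tau, mean = mean_m, sd = sd_m, n = nrow(segs))
}
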