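#' Clean a track or trajectory
#'
#' Standard cleaning applied before any kinematic computation:
#' \enumerate{
#'   \item (2D tracks only) samples with `likelihood < likelihood_min` are
#'     set missing;
#'   \item interior gaps of at most `max_gap` frames are filled by linear
#'     interpolation, longer gaps stay missing;
#'   \item each contiguous finite run is smoothed with a Savitzky-Golay
#'     (local polynomial least-squares) filter of window `smooth_window`
#'     and order `smooth_order`. Runs shorter than the window are left
#'     unsmoothed with a warning.
#' }
#' Defaults are scaled to 100 Hz sampling and millimetre geometry.
#'
#' @param x a [keypoint_track()] or [trajectory3d()].
#' @param likelihood_min tracking-confidence threshold (2D stage only).
#' @param max_gap longest gap (frames) bridged by interpolation.
#' @param smooth_window odd filter window length, frames.
#' @param smooth_order polynomial order, `< smooth_window`.
#' @param ... passed between methods.
#' @return An object of the same class as `x`.
#' @export
preprocess <- function(x, ...) UseMethod("preprocess")

#' @rdname preprocess
#' @export
preprocess.keypoint_track <- function(x, likelihood_min = 0.6, max_gap = 5,
                                      smooth_window = 7, smooth_order = 3,
                                      ...) {
  check_smooth_params(smooth_window, smooth_order)
  for (kp in names(x$keypoints)) {
    df <- x$keypoints[[kp]]
    low <- !is.finite(df$likelihood) | df$likelihood < likelihood_min
    df$u[low] <- NA_real_
    df$v[low] <- NA_real_
    df$u <- clean_series(df$u, max_gap, smooth_window, smooth_order)
    df$v <- clean_series(df$v, max_gap, smooth_window, smooth_order)
    x$keypoints[[kp]] <- df
  }
  x
}

#' @rdname preprocess
#' @export
preprocess.trajectory3d <- function(x, max_gap = 5, smooth_window = 7,
                                    smooth_order = 3, ...) {
  check_smooth_params(smooth_window, smooth_order)
  for (j in 1:3) {
    x$xyz[, j] <- clean_series(x$xyz[, j], max_gap, smooth_window,
                               smooth_order)
  }
  x
}

check_smooth_params <- function(smooth_window, smooth_order) {
  if (smooth_window %% 2 != 1 || smooth_window <= smooth_order) {
    stop("smooth_window must be odd and greater than smooth_order",
         call. = FALSE)
  }
}

# gap-fill then per-run Savitzky-Golay smoothing of one coordinate series
clean_series <- function(v, max_gap, smooth_window, smooth_order) {
  v <- fill_gaps(v, max_gap)
  runs <- finite_runs(v)
  warned <- FALSE
  for (r in runs) {
    len <- r[2] - r[1] + 1L
    if (len >= smooth_window) {
      v[r[1]:r[2]] <- signal::sgolayfilt(v[r[1]:r[2]], p = smooth_order,
                                         n = smooth_window)
    } else if (!warned && len > 1L) {
      warning("run shorter than smoothing window left unsmoothed")
      warned <- TRUE
    }
  }
  v
}

# linear interpolation of interior NA gaps of length <= max_gap
fill_gaps <- function(v, max_gap) {
  if (max_gap < 1L) return(v)
  na <- !is.finite(v)
  if (!any(na) || all(na)) return(v)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == length(v)) next  # edge gaps stay missing
    x0 <- v[s - 1L]; x1 <- v[e + 1L]
    if (!is.finite(x0) || !is.finite(x1)) next
    w <- seq_len(r$lengths[k]) / (r$lengths[k] + 1)
    v[s:e] <- x0 + w * (x1 - x0)
  }
  v
}

# 1-based (start, end) index pairs of maximal finite runs
finite_runs <- function(v) {
  fin <- is.finite(v)
  if (!any(fin)) return(list())
  r <- rle(fin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(c, starts[r$values], ends[r$values])
}

#' Reach segment set
#'
#' Builds a validated set of reach segments: half-open 0-based frame windows
#' `[start, end)` with the apex (frame of maximal forward extension) inside,
#' sorted and non-overlapping.
#'
#' @param start,end integer vectors, 0-based, half-open.
#' @param apex integer vector, `start <= apex < end`.
#' @param source `"auto"` or `"manual"`, recycled.
#' @param n_frames trajectory length the segments must fit in.
#' @return A data.frame of class `reach_segments` with columns
#'   `start`, `end`, `apex`, `source`.
#' @export
reach_segments <- function(start, end, apex, source = "auto", n_frames) {
  start <- as.integer(start); end <- as.integer(end); apex <- as.integer(apex)
  stopifnot(length(start) == length(end), length(apex) == length(start))
  bad <- which(start < 0L | start >= end | end > n_frames)
  if (length(bad)) {
    stop(sprintf("invalid segment bounds at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(apex < start | apex >= end)) {
    stop("apex frame outside its segment", call. = FALSE)
  }
  o <- order(start)
  start <- start[o]; end <- end[o]; apex <- apex[o]
  if (length(start) > 1L && any(start[-1] < end[-length(end)])) {
    ov <- which(start[-1] < end[-length(end)])
    stop(sprintf("overlapping segments at row(s): %s",
                 paste(ov, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(start = start, end = end, apex = apex,
                    source = rep_len(source, length(start)))
  class(out) <- c("reach_segments", "data.frame")
  out
}

#' Detect reach events in an aligned palm trajectory
#'
#' Automatic replacement for manual span selection. The forward coordinate
#' `x(t)` (origin at the pellet, resting paw behind the slit) is scanned for
#' local maxima whose topographic prominence is at least `min_prominence`
#' and whose height clears `baseline + forward_threshold`. Each retained
#' peak is grown to the surrounding crossings of the hysteresis level
#' `baseline + 0.25 * prominence`; windows violating the duration bounds
#' are dropped; overlapping windows are merged keeping the higher apex
#' (earlier apex on ties).
#'
#' @param traj aligned palm [trajectory3d()].
#' @param forward_threshold minimum apex height above baseline, mm.
#' @param min_prominence minimum peak prominence, mm.
#' @param min_duration,max_duration admissible segment length, frames
#'   (defaults 10 and 200, i.e. 0.1-2 s at 100 Hz).
#' @param baseline resting forward position, mm; default the median of the
#'   finite forward coordinate (the paw rests near the slit most of the
#'   session).
#' @return A [reach_segments()] table (possibly empty).
#' @export
segment_reaches <- function(traj, forward_threshold = 2, min_prominence = 3,
                            min_duration = 10, max_duration = 200,
                            baseline = NULL) {
  stopifnot(forward_threshold > 0, min_prominence > 0)
  x <- traj$xyz[, "x"]
  n <- length(x)
  empty <- reach_segments(integer(0), integer(0), integer(0), "auto", n)
  if (!any(is.finite(x))) return(empty)
  if (is.null(baseline)) baseline <- stats::median(x, na.rm = TRUE)
  cand <- list()
  for (r in finite_runs(x)) {
    seg <- x[r[1]:r[2]]
    pks <- local_maxima(seg)
    for (p in pks) {
      prom <- peak_prominence(seg, p)
      if (prom < min_prominence) next
      if (seg[p] < baseline + forward_threshold) next
      lev <- baseline + 0.25 * prom
      a <- p
      while (a > 1L && seg[a - 1L] >= lev) a <- a - 1L
      b <- p
      while (b < length(seg) && seg[b + 1L] >= lev) b <- b + 1L
      cand[[length(cand) + 1L]] <- c(start = r[1] + a - 1L,
                                     end = r[1] + b,  # exclusive, 1-based+1
                                     apex = r[1] + p - 1L,
                                     height = seg[p])
    }
  }
  if (!length(cand)) return(empty)
  m <- do.call(rbind, cand)
  m <- m[order(m[, "start"], m[, "apex"]), , drop = FALSE]
  merged <- list()
  cur <- m[1, ]
  for (i in seq_len(nrow(m))[-1]) {
    nx <- m[i, ]
    if (nx["start"] <= cur["end"]) {
      cur["end"] <- max(cur["end"], nx["end"])
      if (nx["height"] > cur["height"]) {
        cur["apex"] <- nx["apex"]; cur["height"] <- nx["height"]
      }
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- nx
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)
  dur <- m[, "end"] - m[, "start"]
  m <- m[dur >= min_duration & dur <= max_duration, , drop = FALSE]
  if (!nrow(m)) return(empty)
  # convert 1-based rows to 0-based frames ([start, end) stays half-open)
  reach_segments(m[, "start"] - 1L, m[, "end"] - 1L, m[, "apex"] - 1L,
                 "auto", n)
}

# interior local maxima of a finite vector; a plateau of equal values
# reports its first index, matching which.max() on the same window
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# topographic prominence of peak p within run v
peak_prominence <- function(v, p) {
  h <- v[p]
  left <- v[seq_len(p - 1)]
  right <- if (p < length(v)) v[(p + 1):length(v)] else numeric(0)
  lmin <- run_base(rev(left), h)
  rmin <- run_base(right, h)
  h - max(lmin, rmin)
}

# lowest value between the peak and the first higher ground (or run edge)
run_base <- function(side, h) {
  if (!length(side)) return(h)  # peak at run edge: zero contribution
  higher <- which(side > h)
  if (length(higher)) side <- side[seq_len(higher[1] - 1L)]
  if (!length(side)) return(h)
  min(side)
}

#' Load manually selected reach spans
#'
#' Ingests a CSV of `(start_frame, end_frame)` pairs (0-based, half-open)
#' produced by manual trajectory review, validates them against the
#' trajectory, and computes each span's apex as the frame of maximal forward
#' extension.
#'
#' @param path CSV with columns `start_frame`, `end_frame`.
#' @param traj the palm [trajectory3d()] the spans refer to.
#' @return A [reach_segments()] table with `source = "manual"`.
#' @export
load_manual_segments <- function(path, traj) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("start_frame", "end_frame") %in% names(df))) {
    stop("manual segment file needs start_frame,end_frame columns",
         call. = FALSE)
  }
  n <- n_frames(traj)
  x <- traj$xyz[, "x"]
  apex <- mapply(function(s, e) {
    if (s < 0 || e > n || s >= e) return(NA_integer_)
    w <- x[(s + 1):e]
    if (!any(is.finite(w))) return(s)
    s + which.max(w) - 1L
  }, df$start_frame, df$end_frame)
  reach_segments(df$start_frame, df$end_frame, apex, "manual", n)
}
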