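#' The six reach outcome categories
#'
#' Trial outcomes of a single-pellet reach: `grasped` (pellet retrieved and
#' brought to the mouth), `missed` (pellet never touched), `flicked` (pellet
#' knocked off the feeder disk), `lost` (picked up but dropped on the way to
#' the mouth), `in_vain` (reach with no pellet present) and `artifact` (the
#' recorded trajectory is not an acceptable reach).
#'
#' @return Character vector of the six labels, in canonical order.
#' @export
outcome_levels <- function() {
  c("grasped", "missed", "flicked", "lost", "in_vain", "artifact")
}

#' Rule-based outcome classification of one reach
#'
#' Deterministic operationalization of the outcome categories from the paw
#' and pellet trajectories within the segment window, evaluated as a
#' cascade:
#' \enumerate{
#'   \item fewer than 50% finite paw frames, or a duration outside
#'     `duration_bounds` -> `artifact`;
#'   \item pellet missing for the whole window -> `in_vain`;
#'   \item minimum paw-pellet distance above `contact_radius` -> `missed`;
#'   \item contact without *co-movement* but with pellet net displacement of
#'     at least `displacement_min` -> `flicked` (knocked off the disk);
#'     contact with neither -> `missed`;
#'   \item co-movement whose terminal pellet position lies outside the mouth
#'     zone -> `lost`; inside -> `grasped`.
#' }
#' Co-movement means a run of at least `min_comove` consecutive frames with
#' paw-pellet distance below `contact_radius` during which the pellet itself
#' is displaced by at least `displacement_min`: distance alone is not
#' enough, because the decelerating paw hovers within `contact_radius` of a
#' static pellet on every touching reach.
#'
#' @param seg one row of a [reach_segments()] table.
#' @param paw,pellet aligned [trajectory3d()]s sharing the frame index.
#' @param contact_radius contact distance in mm (default 2, the pellet
#'   diameter).
#' @param displacement_min minimal pellet displacement counting as moved, mm.
#' @param mouth_point 3D position of the mouth at the slit, mm.
#' @param mouth_radius radius of the mouth zone sphere, mm.
#' @param min_comove minimal co-movement run length, frames.
#' @param duration_bounds admissible reach duration `c(min, max)` in frames.
#' @return One of [outcome_levels()].
#' @export
classify_reach <- function(seg, paw, pellet,
                           contact_radius = 2, displacement_min = 1,
                           mouth_point = c(-7, 0, 3), mouth_radius = 5,
                           min_comove = 3L, duration_bounds = c(10L, 200L)) {
  if (n_frames(paw) != n_frames(pellet)) {
    stop("paw and pellet trajectories must share the frame index",
         call. = FALSE)
  }
  s <- as.integer(seg$start); e <- as.integer(seg$end)
  stopifnot(s >= 0, s < e, e <= n_frames(paw))
  rows <- (s + 1):e
  pw <- paw$xyz[rows, , drop = FALSE]
  pl <- pellet$xyz[rows, , drop = FALSE]
  dur <- e - s
  if (mean(stats::complete.cases(pw)) < 0.5 ||
      dur < duration_bounds[1] || dur > duration_bounds[2]) {
    return("artifact")
  }
  pl_fin <- stats::complete.cases(pl)
  if (!any(pl_fin)) return("in_vain")
  d <- sqrt(rowSums((pw - pl)^2))
  if (all(!is.finite(d)) || min(d, na.rm = TRUE) > contact_radius) {
    return("missed")
  }
  # maximal contact runs, tested for genuine pellet transport
  contact <- is.finite(d) & d < contact_radius
  comove_end <- NA_integer_
  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] < min_comove) next
    disp <- sqrt(sum((pl[ends[k], ] - pl[starts[k], ])^2))
    if (is.finite(disp) && disp >= displacement_min) comove_end <- ends[k]
  }
  if (is.na(comove_end)) {
    last <- max(which(pl_fin)); first <- min(which(pl_fin))
    net <- sqrt(sum((pl[last, ] - pl[first, ])^2))
    return(if (is.finite(net) && net >= displacement_min) "flicked" else "missed")
  }
  terminal <- pl[max(which(pl_fin)), ]
  inside <- sqrt(sum((terminal - mouth_point)^2)) <= mouth_radius
  if (inside) "grasped" else "lost"
}

#' Classify every segment of a session
#'
#' @param segs a [reach_segments()] table.
#' @param paw,pellet aligned [trajectory3d()]s.
#' @param ... parameters forwarded to [classify_reach()].
#' @return Character vector of outcome labels, one per segment.
#' @export
classify_session <- function(segs, paw, pellet, ...) {
  vapply(seq_len(nrow(segs)), function(i) {
    classify_reach(segs[i, ], paw, pellet, ...)
  }, character(1))
}

#' Read manual outcome labels
#'
#' Manual labels override the rule cascade when provided. The file maps a
#' 0-based segment index to one of the six outcome categories.
#'
#' @param path CSV with columns `segment_index`, `label`.
#' @param n_segments number of segments the labels apply to.
#' @return Character vector of length `n_segments` (`NA` where unlabeled).
#' @export
read_manual_labels <- function(path, n_segments) {
  df <- utils::read.csv(path)
  if (!all(c("segment_index", "label") %in% names(df))) {
    stop("manual label file needs segment_index,label columns", call. = FALSE)
  }
  bad <- setdiff(unique(df$label), outcome_levels())
  if (length(bad)) {
    stop(sprintf("unknown outcome label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$segment_index < 0 | df$segment_index >= n_segments)) {
    stop("segment_index out of range", call. = FALSE)
  }
  out <- rep(NA_character_, n_segments)
  out[df$segment_index + 1L] <- df$label
  out
}

#' Cluster reaches on their kinematic scalars
#'
#' Unsupervised grouping of reaches from the scalar feature vector
#' (duration, endpoint, path length, speeds, timing, acceleration, jerk).
#' Features are standardized to zero mean and unit variance internally, so
#' the result is invariant to feature scaling. Rows with missing scalars
#' (artifacts) receive `NA` cluster labels.
#'
#' @param table a [scalar_table()] data.frame.
#' @param method `"kmeans"`, `"agglomerative"` (Ward linkage) or `"gmm"`
#'   (Gaussian mixture via mclust).
#' @param k number of clusters; `NULL` picks the silhouette-maximizing
#'   k in 2..6 (bounded by the number of complete rows).
#' @param seed integer seed making the result deterministic.
#' @return List with `labels` (0-based integer cluster ids, `NA` for
#'   incomplete rows), `k`, `method` and `silhouette` (mean silhouette
#'   width; `NA` for k = 1).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_reaches <- function(table, method = c("kmeans", "agglomerative", "gmm"),
                            k = NULL, seed = 1L) {
  method <- match.arg(method)
  feat_cols <- c("duration_s", "end_x_mm", "end_y_mm", "end_z_mm", "path_mm",
                 "vmean_mm_s", "vmax_mm_s", "tvmax_frac", "amax_mm_s2",
                 "jmax_mm_s3")
  X <- as.matrix(table[, feat_cols])
  ok <- stats::complete.cases(X)
  n <- sum(ok)
  if (!is.null(k) && k > n) {
    stop(sprintf("k = %d exceeds the %d complete rows", k, n), call. = FALSE)
  }
  labels <- rep(NA_integer_, nrow(X))
  if (n == 0L) return(list(labels = labels, k = 0L, method = method,
                           silhouette = NA_real_))
  Xs <- scale(X[ok, , drop = FALSE])
  Xs[, !is.finite(colSums(Xs))] <- 0  # constant features carry no signal
  fit_k <- function(kk) {
    set.seed(seed)
    cl <- switch(method,
      kmeans = stats::kmeans(Xs, centers = kk, nstart = 10L)$cluster,
      agglomerative = stats::cutree(
        stats::hclust(stats::dist(Xs), method = "ward.D2"), k = kk),
      gmm = Mclust(Xs, G = kk, verbose = FALSE)$classification)
    as.integer(cl)
  }
  sil <- function(cl) {
    if (length(unique(cl)) < 2L) return(NA_real_)
    mean(cluster::silhouette(cl, stats::dist(Xs))[, "sil_width"])
  }
  if (is.null(k)) {
    ks <- 2:min(6L, n - 1L)
    if (length(ks) == 0L || n < 3L) {
      k <- 1L
    } else {
      fits <- lapply(ks, fit_k)
      sw <- vapply(fits, sil, numeric(1))
      best <- which.max(sw)
      k <- ks[best]
      cl <- fits[[best]]
      labels[ok] <- cl - 1L
      return(list(labels = labels, k = k, method = method,
                  silhouette = sw[best]))
    }
  }
  if (k == 1L) {
    labels[ok] <- 0L
    return(list(labels = labels, k = 1L, method = method,
                silhouette = NA_real_))
  }
  cl <- fit_k(k)
  labels[ok] <- cl - 1L
  list(labels = labels, k = as.integer(k), method = method,
       silhouette = sil(cl))
}

#' Count reaches per outcome category
#'
#' @param table a [scalar_table()] with its `label` column populated.
#' @return Named integer vector over exactly the six categories (zeros
#'   included); errors on labels outside the vocabulary.
#' @export
count_categories <- function(table) {
  lab <- table$label
  lab <- lab[!is.na(lab) & nzchar(lab)]
  bad <- setdiff(unique(lab), outcome_levels())
  if (length(bad)) {
    stop(sprintf("unknown outcome label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  tab <- table(factor(lab, levels = outcome_levels()))
  stats::setNames(as.integer(tab), outcome_levels())
}
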