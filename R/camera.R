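#' Pinhole camera model
#'
#' A camera is stored as its 3x4 homogeneous projection matrix `P` mapping
#' world millimetres to image pixels, together with a `mirrored` flag and the
#' image size. A mirror view of the scene is modeled as a *reflected virtual
#' camera*: the projection matrix of the real camera composed with a 4x4
#' reflection about the mirror plane. Such a camera decomposes as `K [R | t]`
#' with `det(R) = -1`, which is exactly what the `mirrored` flag records.
#' Triangulation treats mirrored and ordinary cameras identically because the
#' reflection lives inside `P`.
#'
#' @param P 3x4 numeric projection matrix (pixels on the left, mm on the
#'   right). The left 3x3 block must have full rank.
#' @param mirrored logical; if `NULL` (default) it is inferred from the sign
#'   of `det(R)` after RQ decomposition of `P[, 1:3]`.
#' @param image_size integer vector `c(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @seealso [calibrate_dlt()], [mirror_camera()], [triangulate()]
#' @export
camera_model <- function(P, mirrored = NULL, image_size = c(1440L, 1080L)) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 4L))) {
    stop("P must be a 3x4 projection matrix", call. = FALSE)
  }
  M <- P[, 1:3]
  if (qr(M)$rank < 3L) {
    stop("left 3x3 block of P is rank-deficient", call. = FALSE)
  }
  dec <- decompose_camera_matrix(P)
  if (is.null(mirrored)) mirrored <- dec$mirrored
  structure(
    list(P = P, mirrored = isTRUE(mirrored),
         image_size = as.numeric(image_size)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %s, image %d x %d px\n",
              if (x$mirrored) "mirrored (virtual)" else "direct",
              as.integer(x$image_size[1]), as.integer(x$image_size[2])))
  invisible(x)
}

# RQ decomposition of a 3x3 matrix, M = R %*% Q with R upper triangular and
# Q orthogonal; signs fixed so diag(R) > 0.
rq3 <- function(M) {
  J <- matrix(0, 3, 3)
  J[1, 3] <- J[2, 2] <- J[3, 1] <- 1
  qrd <- qr(t(J %*% M))
  Qm <- qr.Q(qrd)
  Rm <- qr.R(qrd)
  R <- J %*% t(Rm) %*% J
  Q <- J %*% t(Qm)
  D <- diag(sign(diag(R) + (diag(R) == 0)))
  list(R = R %*% D, Q = D %*% Q)
}

# Split P into intrinsics K, rotation-or-reflection R, translation t.
# det(R) = -1 marks a mirrored (virtual) camera.
decompose_camera_matrix <- function(P) {
  M <- P[, 1:3]
  dec <- rq3(M)
  K <- dec$R
  R <- dec$Q
  K <- K / K[3, 3]
  t <- solve(dec$R, P[, 4])
  list(K = K, R = R, t = t, mirrored = det(R) < 0)
}

#' Project 3D points through a camera
#'
#' @param cam a [camera_model()].
#' @param X numeric matrix n x 3 of world points in mm (rows with any `NA`
#'   project to `NA`).
#' @return n x 2 matrix of pixel coordinates `(u, v)`; points at or behind
#'   the camera plane are returned as `NA` with a warning.
#' @export
project_points <- function(cam, X) {
  X <- rbind(t(as.matrix(X)), 1)
  xh <- cam$P %*% X
  w <- xh[3, ]
  bad <- is.finite(w) & w <= 0
  if (any(bad)) {
    warning(sprintf("%d point(s) behind the camera marked missing", sum(bad)))
    w[bad] <- NA_real_
  }
  cbind(u = xh[1, ] / w, v = xh[2, ] / w)
}

#' Build a camera looking at a target point
#'
#' Convenience constructor used by the synthetic scene: a pinhole camera with
#' focal length `f` (pixels), principal point at the image center, positioned
#' at `center` and oriented toward `target` with `up` defining the vertical.
#'
#' @param center,target 3D points in mm.
#' @param up approximate up direction (default +z).
#' @param f focal length in pixels.
#' @param image_size `c(width, height)` pixels.
#' @return A `camera_model`.
#' @export
look_at_camera <- function(center, target, up = c(0, 0, 1), f = 2000,
                           image_size = c(1440L, 1080L)) {
  zc <- target - center
  zc <- zc / sqrt(sum(zc^2))
  xc <- cross3(up, zc)
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-12) stop("up direction parallel to viewing axis", call. = FALSE)
  xc <- xc / nx
  yc <- cross3(zc, xc)
  R <- rbind(xc, yc, zc)
  t <- -R %*% center
  K <- matrix(c(f, 0, image_size[1] / 2,
                0, f, image_size[2] / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  camera_model(K %*% cbind(R, t), mirrored = FALSE, image_size = image_size)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Calibrate a camera by the direct linear transform
#'
#' Estimates the 3x4 projection matrix from 3D-2D correspondences by
#' homogeneous least squares (SVD of the stacked DLT system) with Hartley
#' normalization of both point sets for conditioning. The sign of `P` is
#' fixed so that the calibration points have positive depth, after which the
#' `mirrored` flag is read off the determinant of the rotation factor.
#'
#' @param X n x 3 matrix of 3D points in mm. The set must span 3 dimensions:
#'   a single checkerboard pose (coplanar points) is degenerate for the DLT,
#'   so calibration fixtures use several board orientations.
#' @param x n x 2 matrix of the corresponding image points in pixels.
#' @param image_size passed through to the resulting [camera_model()].
#' @return A `camera_model` with attribute `reprojection_error`, the mean
#'   Euclidean reprojection residual in pixels.
#' @examples
#' sc <- scene_config()
#' fix <- calibration_fixture(sc)
#' cam <- calibrate_dlt(fix$points3d, fix$pixels[["front"]])
#' attr(cam, "reprojection_error") # ~0 for noiseless correspondences
#' @export
calibrate_dlt <- function(X, x, image_size = c(1440L, 1080L)) {
  X <- as.matrix(X)
  x <- as.matrix(x)
  ok <- stats::complete.cases(X) & stats::complete.cases(x)
  X <- X[ok, , drop = FALSE]
  x <- x[ok, , drop = FALSE]
  n <- nrow(X)
  if (n < 6L) {
    stop(sprintf("DLT calibration needs at least 6 correspondences, got %d", n),
         call. = FALSE)
  }
  sv <- svd(scale(X, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1]) {
    stop("3D calibration points are (near-)coplanar: degenerate configuration",
         call. = FALSE)
  }
  T2 <- hartley_transform(x)
  T3 <- hartley_transform(X)
  xn <- t(T2 %*% rbind(t(x), 1))
  Xn <- t(T3 %*% rbind(t(X), 1))
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    Xi <- Xn[i, ]
    A[2 * i - 1, ] <- c(Xi, rep(0, 4), -xn[i, 1] * Xi)
    A[2 * i, ] <- c(rep(0, 4), Xi, -xn[i, 2] * Xi)
  }
  p <- svd(A, nu = 0)$v[, 12]
  Pn <- matrix(p, 3, 4, byrow = TRUE)
  P <- solve(T2) %*% Pn %*% T3
  # cheirality: calibration points must sit in front of the camera
  w <- as.numeric(P[3, ] %*% rbind(t(X), 1))
  if (stats::median(w) < 0) P <- -P
  P <- P / sqrt(sum(P[3, 1:3]^2))
  cam <- camera_model(P, image_size = image_size)
  proj <- project_points(cam, X)
  err <- mean(sqrt(rowSums((proj - x)^2)))
  attr(cam, "reprojection_error") <- err
  cam
}

# Hartley normalization: centroid to origin, mean distance sqrt(dim).
hartley_transform <- function(pts) {
  pts <- as.matrix(pts)
  d <- ncol(pts)
  ctr <- colMeans(pts)
  dist <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- sqrt(d) / mean(dist)
  T <- diag(c(rep(s, d), 1))
  T[seq_len(d), d + 1] <- -s * ctr
  T
}

#' Reflect a camera about a mirror plane
#'
#' Returns the virtual camera seen in a planar mirror: `P %*% H`, where `H`
#' is the 4x4 reflection about the plane through `point` with unit `normal`.
#' The `mirrored` flag is toggled. Reflecting twice about the same plane
#' recovers the original camera.
#'
#' @param cam a [camera_model()].
#' @param point any point on the mirror plane (mm).
#' @param normal plane normal (need not be unit length, but not zero).
#' @return The reflected `camera_model`.
#' @export
mirror_camera <- function(cam, point, normal) {
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("mirror plane normal must be non-zero", call. = FALSE)
  n <- normal / nn
  H <- diag(4)
  H[1:3, 1:3] <- diag(3) - 2 * tcrossprod(n)
  H[1:3, 4] <- 2 * sum(point * n) * n
  camera_model(cam$P %*% H, mirrored = !cam$mirrored,
               image_size = cam$image_size)
}

#' Linear two-view (or multi-view) triangulation
#'
#' Per-frame direct linear triangulation: for every frame, the rows
#' `u * P[3,] - P[1,]` and `v * P[3,] - P[2,]` of each view with finite
#' coordinates are stacked and the homogeneous least-squares solution taken
#' from the SVD. Frames observed by fewer than two views yield `NA` points.
#' Mirrored cameras need no special casing.
#'
#' @param pts list of n x 2 pixel matrices, one per view (equal row counts).
#' @param cams list of [camera_model()]s, same length and order as `pts`.
#' @return n x 3 matrix of world points in mm, `NA` rows where triangulation
#'   was impossible; if every frame is invalid a warning is emitted.
#' @export
triangulate <- function(pts, cams) {
  stopifnot(length(pts) == length(cams), length(cams) >= 2L)
  pts <- lapply(pts, as.matrix)
  n <- nrow(pts[[1]])
  stopifnot(all(vapply(pts, nrow, 0L) == n))
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_len(n)) {
    rows <- list()
    for (v in seq_along(cams)) {
      uv <- pts[[v]][i, ]
      if (all(is.finite(uv))) {
        P <- cams[[v]]$P
        rows[[length(rows) + 1L]] <- rbind(uv[1] * P[3, ] - P[1, ],
                                           uv[2] * P[3, ] - P[2, ])
      }
    }
    if (length(rows) >= 2L) {
      A <- do.call(rbind, rows)
      h <- svd(A, nu = 0)$v[, 4]
      out[i, ] <- h[1:3] / h[4]
    }
  }
  if (all(!is.finite(out))) warning("no frame could be triangulated")
  out
}

#' Nonlinear triangulation by direct reprojection-error minimization
#'
#' Refines (or checks) linear triangulation by minimizing the sum of squared
#' pixel reprojection residuals per point with a quasi-Newton search. Used as
#' an independent accuracy reference for [triangulate()] under pixel noise.
#'
#' @inheritParams triangulate
#' @param init optional n x 3 matrix of starting points; defaults to the
#'   linear solution.
#' @return n x 3 matrix of refined world points.
#' @export
triangulate_refine <- function(pts, cams, init = NULL) {
  pts <- lapply(pts, as.matrix)
  if (is.null(init)) init <- suppressWarnings(triangulate(pts, cams))
  out <- init
  obj <- function(X, obs) {
    s <- 0
    for (v in seq_along(obs)) {
      xh <- cams[[v]]$P %*% c(X, 1)
      s <- s + sum((xh[1:2] / xh[3] - obs[[v]])^2)
    }
    s
  }
  for (i in seq_len(nrow(init))) {
    if (!all(is.finite(init[i, ]))) next
    obs <- Filter(Negate(is.null), lapply(seq_along(cams), function(v) {
      uv <- pts[[v]][i, ]
      if (all(is.finite(uv))) uv else NULL
    }))
    fit <- stats::optim(init[i, ], obj, obs = obs, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    out[i, ] <- fit$par
  }
  out
}

#' Similarity alignment of a trajectory to named reference points
#'
#' Estimates the least-squares similarity transform (isotropic scale,
#' rotation, translation) that maps *measured* static reference points (as
#' triangulated, in the arbitrary calibration frame) onto their *nominal*
#' coordinates in the behavioral frame -- origin at the pellet rest position,
#' +x forward (slit to pellet), +y sideward, +z upward -- and applies it to
#' every frame of the trajectory. The residual isotropic scale absorbs the
#' gauge freedom of the calibration.
#'
#' @param traj a [trajectory3d()] in the calibration frame.
#' @param measured k x 3 matrix of triangulated reference points (k >= 3,
#'   non-collinear), rows matching `nominal`.
#' @param nominal k x 3 matrix of the same points in the behavioral frame.
#' @return The transformed `trajectory3d`, with attribute `transform`, a list
#'   `(s, R, t)` such that `x_nominal = s * R x_measured + t`.
#' @export
align_to_reference <- function(traj, measured, nominal) {
  measured <- as.matrix(measured)
  nominal <- as.matrix(nominal)
  stopifnot(nrow(measured) == nrow(nominal), nrow(measured) >= 3L)
  sv <- svd(scale(nominal, scale = FALSE))$d
  if (sv[2] < 1e-9 * sv[1]) {
    stop("reference points are collinear: alignment is degenerate",
         call. = FALSE)
  }
  tr <- similarity_transform(measured, nominal)
  xyz <- apply_similarity(tr, traj$xyz)
  out <- trajectory3d(xyz, fs = traj$fs, keypoint = traj$keypoint)
  attr(out, "transform") <- tr
  out
}

# Umeyama closed-form similarity fit: maps x onto y.
similarity_transform <- function(x, y) {
  mx <- colMeans(x)
  my <- colMeans(y)
  xc <- sweep(x, 2, mx)
  yc <- sweep(y, 2, my)
  S <- crossprod(yc, xc) / nrow(x)
  sv <- svd(S)
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- mean(rowSums(xc^2))
  s <- sum(sv$d * diag(D)) / varx
  t <- my - s * as.numeric(R %*% mx)
  list(s = s, R = R, t = t)
}

apply_similarity <- function(tr, xyz) {
  out <- tr$s * t(tr$R %*% t(xyz)) + matrix(tr$t, nrow(xyz), 3, byrow = TRUE)
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}
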