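#' Synthetic scene configuration
#'
#' Fixes the geometry and sampling of the simulated reach-to-grasp scene.
#' The defaults encode the physical task: camera sampling at 100 Hz, the
#' pellet rest position 7 mm in front of the slit (the origin of the
#' behavioral frame is the pellet, +x points forward from slit to pellet,
#' +y sideward, +z upward), a ~2 mm sugar pellet, and a 4x4-square
#' checkerboard with 1 x 1 mm squares for calibration. Two vertical mirrors
#' flanking the box at 45 degrees provide the side views; they are modeled
#' as reflection planes generating virtual cameras.
#'
#' The world (calibration) frame is deliberately offset from the behavioral
#' frame by a rigid transform so that every simulated pipeline run has to
#' perform the reference-point alignment, exactly as a real calibration
#' does.
#'
#' @param fs sampling rate, frames/s.
#' @param slit_pellet_distance slit-to-pellet distance, mm.
#' @param pellet_diameter pellet diameter, mm.
#' @param board checkerboard layout: squares per side and square size in mm.
#' @param noise_px image-noise SD in pixels used by [project_scene()].
#' @param noise_mm trajectory-noise SD in mm used by [generate_session()].
#' @param dropout per-frame tracking dropout probability.
#' @param seed integer; fixes all randomness of the generators.
#' @param world_rotation_deg,world_translation rigid offset of the world
#'   frame relative to the behavioral frame (rotation about +z, degrees).
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(fs = 100, slit_pellet_distance = 7,
                         pellet_diameter = 2,
                         board = list(rows = 4, cols = 4, square = 1),
                         noise_px = 0, noise_mm = 0, dropout = 0,
                         seed = 1L,
                         world_rotation_deg = 15,
                         world_translation = c(10, -5, 3)) {
  stopifnot(fs > 0, slit_pellet_distance > 0, pellet_diameter > 0,
            board$square > 0)
  sx <- -slit_pellet_distance
  th <- world_rotation_deg * pi / 180
  R0 <- matrix(c(cos(th), -sin(th), 0,
                 sin(th), cos(th), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  cfg <- list(
    fs = fs,
    slit_pellet_distance = slit_pellet_distance,
    pellet_diameter = pellet_diameter,
    board = board,
    noise_px = noise_px, noise_mm = noise_mm, dropout = dropout,
    seed = as.integer(seed),
    pellet_rest = c(0, 0, 0),
    slit_center = c(sx, 0, 0),
    paw_rest = c(sx - 1, 0, 0),
    mouth_point = c(sx, 0, 3),
    mouth_radius = 5,
    contact_radius = pellet_diameter,
    reference_nominal = rbind(
      pellet = c(0, 0, 0),
      slit_left = c(sx, -2.5, 0),
      slit_right = c(sx, 2.5, 0),
      slit_top = c(sx, 0, 10)),
    camera = list(center = c(200, 0, 30), target = c(0, 0, 5),
                  f = 2000, image_size = c(1440L, 1080L)),
    mirrors = list(
      left_mirror = list(point = c(0, 40, 0),
                         normal = c(1, -1, 0) / sqrt(2)),
      right_mirror = list(point = c(0, -40, 0),
                          normal = c(1, 1, 0) / sqrt(2))),
    world = list(R = R0, t = world_translation))
  class(cfg) <- "scene_config"
  cfg
}

#' Map behavioral-frame points to the world (calibration) frame
#'
#' @param config a [scene_config()].
#' @param X n x 3 matrix (or length-3 vector) in the behavioral frame.
#' @return Matrix of the same shape in the world frame.
#' @export
to_world_frame <- function(config, X) {
  one <- is.null(dim(X))
  X <- rbind(X)
  out <- t(config$world$R %*% t(X)) +
    matrix(config$world$t, nrow(X), 3, byrow = TRUE)
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  if (one) out[1, ] else out
}

#' True cameras of the synthetic scene
#'
#' The front camera plus the two mirror-generated virtual cameras, all
#' expressed in the world frame (so that calibrating from world-frame
#' checkerboard correspondences recovers exactly these matrices).
#'
#' @param config a [scene_config()].
#' @return Named list of [camera_model()]s
#'   (`front`, `left_mirror`, `right_mirror`).
#' @export
scene_cameras <- function(config) {
  cm <- config$camera
  front <- look_at_camera(cm$center, cm$target, f = cm$f,
                          image_size = cm$image_size)
  cams <- list(front = front)
  for (v in names(config$mirrors)) {
    m <- config$mirrors[[v]]
    cams[[v]] <- mirror_camera(front, m$point, m$normal)
  }
  # conjugate with the inverse world transform: P_world = P_behav o T^-1
  R0 <- config$world$R; t0 <- config$world$t
  Tinv <- rbind(cbind(t(R0), -t(R0) %*% t0), c(0, 0, 0, 1))
  lapply(cams, function(cam) {
    camera_model(cam$P %*% Tinv, mirrored = cam$mirrored,
                 image_size = cam$image_size)
  })
}

#' Checkerboard corner grid for one pose
#'
#' Corners of a `rows x cols`-square board (hence `(rows+1) x (cols+1)`
#' corners) with exact `square` mm pitch, ordered left to right, top to
#' bottom, placed by a rotation + translation.
#'
#' @param board list with `rows`, `cols`, `square`.
#' @param rotation 3x3 rotation matrix (board local to scene).
#' @param translation board center position, mm.
#' @return Matrix `(rows+1)*(cols+1) x 3` with attributes `grid_row`,
#'   `grid_col`.
#' @export
checkerboard_corners <- function(board, rotation = diag(3),
                                 translation = c(0, 0, 5)) {
  nr <- board$rows + 1L
  nc <- board$cols + 1L
  sq <- board$square
  grid_row <- rep(seq_len(nr) - 1L, each = nc)
  grid_col <- rep(seq_len(nc) - 1L, times = nr)
  local <- cbind(0,
                 (grid_col - (nc - 1) / 2) * sq,
                 ((nr - 1) / 2 - grid_row) * sq)
  X <- t(rotation %*% t(local)) +
    matrix(translation, nrow(local), 3, byrow = TRUE)
  dimnames(X) <- list(NULL, c("x", "y", "z"))
  attr(X, "grid_row") <- grid_row
  attr(X, "grid_col") <- grid_col
  X
}

rot_xyz <- function(ax = 0, ay = 0, az = 0) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Checkerboard calibration fixture
#'
#' Places the calibration checkerboard in several orientations (a single
#' planar pose is degenerate for the DLT), projects all corners into the
#' requested views with optional pixel noise, and returns the 3D-2D
#' correspondences together with the true cameras.
#'
#' @param config a [scene_config()].
#' @param views which views to project into.
#' @param noise_px Gaussian pixel noise SD (default `config$noise_px`).
#' @param seed randomness seed (default `config$seed`).
#' @return List with `points3d` (world frame), `pixels` (named list of
#'   n x 2 matrices), `cams` (true cameras), `pose_id`, `grid_row`,
#'   `grid_col`, and `corr`, the flat correspondence table
#'   `(view, point_id, X, Y, Z, u, v)`.
#' @export
calibration_fixture <- function(config,
                                views = c("front", "left_mirror"),
                                noise_px = config$noise_px,
                                seed = config$seed) {
  poses <- list(
    list(R = rot_xyz(0, 0, 0), t = c(0, 0, 5)),
    list(R = rot_xyz(15 * pi / 180, 20 * pi / 180, 30 * pi / 180),
         t = c(1.5, 1, 6.5)),
    list(R = rot_xyz(-20 * pi / 180, -25 * pi / 180, 10 * pi / 180),
         t = c(-1.5, -1, 3.5)))
  pts <- list(); pose_id <- integer(0)
  grid_row <- integer(0); grid_col <- integer(0)
  for (k in seq_along(poses)) {
    Xk <- checkerboard_corners(config$board, poses[[k]]$R, poses[[k]]$t)
    pts[[k]] <- Xk
    pose_id <- c(pose_id, rep(k, nrow(Xk)))
    grid_row <- c(grid_row, attr(Xk, "grid_row"))
    grid_col <- c(grid_col, attr(Xk, "grid_col"))
  }
  X <- to_world_frame(config, do.call(rbind, pts))
  cams <- scene_cameras(config)[views]
  set.seed(seed)
  pixels <- lapply(cams, function(cam) {
    px <- project_points(cam, X)
    if (noise_px > 0) px <- px + matrix(stats::rnorm(length(px), 0, noise_px),
                                        nrow(px), 2)
    px
  })
  corr <- do.call(rbind, lapply(views, function(v) {
    data.frame(view = v, point_id = seq_len(nrow(X)) - 1L,
               X = X[, 1], Y = X[, 2], Z = X[, 3],
               u = pixels[[v]][, 1], v = pixels[[v]][, 2])
  }))
  rownames(corr) <- NULL
  list(points3d = X, pixels = pixels, cams = cams, pose_id = pose_id,
       grid_row = grid_row, grid_col = grid_col, corr = corr)
}

#' Mean adjacent-corner spacing of triangulated checkerboard corners
#'
#' Averages the Euclidean distance over all pairs of corners that are grid
#' neighbors (sharing a row or column edge) within the same board pose.
#' For an ideal board this equals the square size.
#'
#' @param points3d n x 3 matrix of corner positions.
#' @param pose_id,grid_row,grid_col corner bookkeeping from
#'   [calibration_fixture()].
#' @return Mean spacing in mm.
#' @export
mean_corner_spacing <- function(points3d, pose_id, grid_row, grid_col) {
  d <- numeric(0)
  for (p in unique(pose_id)) {
    idx <- which(pose_id == p)
    for (i in idx) {
      right <- idx[grid_row[idx] == grid_row[i] &
                   grid_col[idx] == grid_col[i] + 1L]
      below <- idx[grid_col[idx] == grid_col[i] &
                   grid_row[idx] == grid_row[i] + 1L]
      for (j in c(right, below)) {
        d <- c(d, sqrt(sum((points3d[i, ] - points3d[j, ])^2)))
      }
    }
  }
  mean(d)
}

#' Minimum-jerk point-to-point reach
#'
#' The quintic minimum-jerk profile `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`
#' along the straight line from `start` to `target`: zero velocity and
#' acceleration at both ends, peak speed `1.875 * D / T` at mid-movement.
#' This is the standard smooth-limb-movement fixture used in place of
#' recorded reaches.
#'
#' @param D movement amplitude in mm (used to place `start` when it is not
#'   given).
#' @param T movement duration in seconds.
#' @param fs sampling rate, frames/s; `T * fs` must be at least 4.
#' @param target end position, mm.
#' @param start start position; default `target - c(D, 0, 0)` (a purely
#'   forward reach).
#' @param keypoint keypoint name for the resulting trajectory.
#' @return A [trajectory3d()] with `round(T * fs) + 1` frames.
#' @export
min_jerk_reach <- function(D = 7, T = 0.3, fs = 100, target = c(0, 0, 0),
                           start = NULL, keypoint = "palm") {
  stopifnot(D > 0, T > 0)
  if (T * fs < 4) stop("T * fs < 4: too few samples for a reach", call. = FALSE)
  if (is.null(start)) start <- target - c(D, 0, 0)
  N <- round(T * fs)
  tau <- seq(0, 1, length.out = N + 1)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  xyz <- matrix(start, N + 1, 3, byrow = TRUE) +
    outer(s, target - start)
  trajectory3d(xyz, fs = fs, keypoint = keypoint)
}

default_outcome_mix <- function() {
  c(grasped = 0.35, missed = 0.25, flicked = 0.15, lost = 0.15,
    in_vain = 0.10, artifact = 0)
}

#' Simulate a training session with ground truth
#'
#' Concatenates idle epochs (paw resting behind the slit) with minimum-jerk
#' reaches whose outcome is drawn from `outcome_mix`, and generates the
#' matching pellet trajectory, sensor log and ground-truth labels:
#' \itemize{
#'   \item `grasped`: the pellet co-moves with the paw from the apex back to
#'     the mouth zone at the slit;
#'   \item `lost`: co-movement that drops the pellet mid-retraction, far
#'     from the mouth;
#'   \item `flicked`: a brief touch knocks the pellet off the disk in a
#'     couple of frames, no transport;
#'   \item `missed`: the reach apex is offset sideways beyond the contact
#'     radius, pellet untouched;
#'   \item `in_vain`: no pellet present during the reach;
#'   \item `artifact`: a reach whose paw track is mostly missing (emulating
#'     tracking dropout).
#' }
#' The sensor log's front-bar channel rises exactly at each reach onset.
#' All randomness derives from `config$seed`.
#'
#' @param config a [scene_config()].
#' @param n_reaches number of reaches (0 gives an idle-only session).
#' @param outcome_mix named probability vector over [outcome_levels()];
#'   must sum to 1.
#' @param paw_bias probability that a reach uses the right paw.
#' @return List with `paw` and `pellet` ([trajectory3d()]s in the
#'   behavioral frame, with `config$noise_mm` measurement noise), `truth`
#'   (clean trajectories, window/label/parameter table), `sensor`
#'   (a `sensor_log`) and `config`.
#' @export
generate_session <- function(config = scene_config(), n_reaches = 20,
                             outcome_mix = default_outcome_mix(),
                             paw_bias = 0.5) {
  stopifnot(n_reaches >= 0)
  if (is.null(names(outcome_mix)) ||
      !all(names(outcome_mix) %in% outcome_levels()) ||
      any(outcome_mix < 0) || abs(sum(outcome_mix) - 1) > 1e-8) {
    stop("outcome_mix must be a probability vector over the outcome labels",
         call. = FALSE)
  }
  set.seed(config$seed)
  fs <- config$fs
  rest0 <- config$paw_rest
  side_of <- function(paw) if (paw == "right") -0.5 else 0.5
  labels <- if (n_reaches > 0) {
    sample(names(outcome_mix), n_reaches, replace = TRUE, prob = outcome_mix)
  } else character(0)
  paws <- if (n_reaches > 0) {
    ifelse(stats::runif(n_reaches) < paw_bias, "right", "left")
  } else character(0)

  paw_blocks <- list(); pel_blocks <- list()
  cursor <- 0L                          # frames emitted so far
  windows <- list()
  idle_block <- function(len, rest) {
    jit <- matrix(stats::rnorm(len * 3, 0, 0.02), len, 3)
    matrix(rest, len, 3, byrow = TRUE) + jit
  }
  # opening idle epoch
  len0 <- sample(50:120, 1)
  paw_blocks[[1]] <- idle_block(len0, rest0)
  pel_blocks[[1]] <- matrix(config$pellet_rest, len0, 3, byrow = TRUE)
  cursor <- len0

  for (i in seq_len(n_reaches)) {
    lab <- labels[i]
    rest <- rest0 + c(0, side_of(paws[i]), 0)
    target <- switch(lab,
      missed = config$pellet_rest + c(0, 3 * sign(side_of(paws[i])), 0),
      config$pellet_rest)
    T_out <- stats::runif(1, 0.25, 0.35)
    T_back <- stats::runif(1, 0.25, 0.35)
    out_tr <- min_jerk_reach(T = T_out, fs = fs, target = target,
                             start = rest)$xyz
    back_tr <- min_jerk_reach(T = T_back, fs = fs, target = rest,
                              start = target)$xyz
    dwell <- matrix(target, 2, 3, byrow = TRUE)
    reach <- rbind(out_tr[-1, ], dwell, back_tr[-1, ])
    n_reach <- nrow(reach)
    onset <- cursor                     # 0-based frame of first reach sample
    apex <- onset + nrow(out_tr) - 2L   # first sample at the target (0-based)

    pel <- matrix(config$pellet_rest, n_reach, 3, byrow = TRUE)
    rel_apex <- apex - onset + 1L       # row of apex within `reach`
    if (lab == "in_vain") {
      pel[] <- NA_real_
    } else if (lab == "flicked") {
      pel[(rel_apex + 1L):n_reach, ] <-
        matrix(config$pellet_rest + c(2, 4, -1), n_reach - rel_apex, 3,
               byrow = TRUE)
    } else if (lab %in% c("grasped", "lost")) {
      pel[rel_apex:n_reach, ] <- reach[rel_apex:n_reach, ]
      if (lab == "lost") {
        after <- which(reach[, 1] < -2 & seq_len(n_reach) > rel_apex)
        drop_at <- if (length(after)) after[1] else n_reach
        drop_pos <- c(reach[drop_at, 1:2], 0)
        pel[drop_at:n_reach, ] <- matrix(drop_pos, n_reach - drop_at + 1L,
                                         3, byrow = TRUE)
      }
    }
    if (lab == "artifact") {
      blk <- floor(0.6 * n_reach)
      from <- floor(0.15 * n_reach) + 1L
      reach[from:(from + blk - 1L), ] <- NA_real_
    }
    paw_blocks[[length(paw_blocks) + 1L]] <- reach
    pel_blocks[[length(pel_blocks) + 1L]] <- pel
    cursor <- cursor + n_reach
    windows[[i]] <- data.frame(
      start = onset, end = onset + n_reach, apex = apex,
      label = lab, paw = paws[i],
      target_x = target[1], target_y = target[2], target_z = target[3],
      D = sqrt(sum((target - rest)^2)), T_out = (nrow(out_tr) - 1) / fs,
      T_back = (nrow(back_tr) - 1) / fs,
      # the session-wide speed peak is in the faster of the two phases
      vmax_true = 1.875 * sqrt(sum((target - rest)^2)) /
        (min(nrow(out_tr), nrow(back_tr)) - 1) * fs)
    # inter-reach idle: new pellet on the disk
    leni <- sample(50:120, 1)
    paw_blocks[[length(paw_blocks) + 1L]] <- idle_block(leni, rest)
    pel_blocks[[length(pel_blocks) + 1L]] <- matrix(config$pellet_rest,
                                                    leni, 3, byrow = TRUE)
    cursor <- cursor + leni
  }
  paw_xyz <- do.call(rbind, paw_blocks)
  pel_xyz <- do.call(rbind, pel_blocks)
  n_total <- nrow(paw_xyz)
  truth_windows <- if (length(windows)) {
    do.call(rbind, windows)
  } else {
    data.frame(start = integer(0), end = integer(0), apex = integer(0),
               label = character(0), paw = character(0),
               target_x = numeric(0), target_y = numeric(0),
               target_z = numeric(0), D = numeric(0), T_out = numeric(0),
               T_back = numeric(0), vmax_true = numeric(0))
  }
  paw_clean <- trajectory3d(paw_xyz, fs = fs, keypoint = "palm")
  pel_clean <- trajectory3d(pel_xyz, fs = fs, keypoint = "pellet")
  add_noise <- function(xyz, sd) {
    if (sd > 0) {
      noise <- matrix(stats::rnorm(length(xyz), 0, sd), nrow(xyz), 3)
      xyz <- xyz + noise  # NA entries stay NA
    }
    xyz
  }
  paw <- trajectory3d(add_noise(paw_xyz, config$noise_mm), fs = fs,
                      keypoint = "palm")
  pellet <- trajectory3d(add_noise(pel_xyz, config$noise_mm), fs = fs,
                         keypoint = "pellet")
  bar <- integer(n_total)
  for (i in seq_len(nrow(truth_windows))) {
    bar[(truth_windows$start[i] + 1):truth_windows$end[i]] <- 1L
  }
  beam <- as.integer(is.finite(paw_xyz[, 1]) &
                     paw_xyz[, 1] > config$slit_center[1])
  sensor <- data.frame(frame = seq_len(n_total) - 1L, bar = bar,
                       floor = 1L - bar, beam = beam)
  class(sensor) <- c("sensor_log", "data.frame")
  list(paw = paw, pellet = pellet,
       truth = list(windows = truth_windows, paw = paw_clean,
                    pellet = pel_clean),
       sensor = sensor, config = config)
}

#' Project 3D trajectories into camera views as 2D keypoint tracks
#'
#' Pinhole projection of a set of keypoint trajectories through each
#' camera, with additive Gaussian pixel noise and simulated tracking
#' dropout: dropped frames get a low likelihood (uniform below 0.5), all
#' others a high one (uniform above 0.9). Missing 3D frames project to
#' missing 2D samples with low likelihood. Deterministic under `seed`.
#'
#' @param trajs named list of [trajectory3d()]s, all of equal length, in
#'   the same frame as the cameras (use [to_world_frame()] for scene
#'   trajectories and [scene_cameras()]).
#' @param cams named list of [camera_model()]s; names become view ids and
#'   must be valid `keypoint_track` views.
#' @param noise_px Gaussian pixel noise SD.
#' @param dropout per-frame dropout probability.
#' @param seed integer seed.
#' @param fs frames/s recorded in the output tracks.
#' @return Named list of [keypoint_track()]s, one per camera.
#' @export
project_scene <- function(trajs, cams, noise_px = 0, dropout = 0, seed = 1L,
                          fs = trajs[[1]]$fs) {
  stopifnot(noise_px >= 0, dropout >= 0, dropout <= 1)
  n <- n_frames(trajs[[1]])
  stopifnot(all(vapply(trajs, n_frames, 0L) == n))
  set.seed(seed)
  out <- list()
  for (v in names(cams)) {
    kps <- list()
    for (kp in names(trajs)) {
      px <- project_points(cams[[v]], trajs[[kp]]$xyz)
      if (noise_px > 0) {
        px <- px + matrix(stats::rnorm(2 * n, 0, noise_px), n, 2)
      }
      drop <- stats::runif(n) < dropout
      miss <- !stats::complete.cases(px)
      lik <- stats::runif(n, 0.9, 1)
      lik[drop | miss] <- stats::runif(sum(drop | miss), 0, 0.5)
      kps[[kp]] <- data.frame(u = px[, 1], v = px[, 2], likelihood = lik)
    }
    out[[v]] <- keypoint_track(v, kps, fs = fs)
  }
  out
}
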