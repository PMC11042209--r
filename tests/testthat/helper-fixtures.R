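# shared fixtures and independent oracles for the test suite

# normalize a projection matrix to compare cameras up to projective scale
norm_P <- function(P) {
  P <- P / sqrt(sum(P^2))
  if (P[which.max(abs(P))] < 0) P <- -P
  P
}

expect_camera_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(norm_P(a$P) - norm_P(b$P))), tol)
  expect_identical(a$mirrored, b$mirrored)
}

# closed-form minimum-jerk speed profile; its dense numeric maximization is
# the oracle for peak-speed assertions
min_jerk_speed <- function(tau, D, T) {
  (D / T) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}
min_jerk_vmax_oracle <- function(D, T) {
  max(min_jerk_speed(seq(0, 1, length.out = 200001), D, T))
}

# independent oracle for session metrics: direct transcription of the
# counting rules -- total = sum of the four counts; right% = right/total *
# 100; the dominant paw is the paw used for more than 70% of all reaches;
# success = successful/total; shaping needs >= 20 reaches and a dominant
# paw; learner at >= 30%.
oracle_metrics <- function(fr, fl, sr, sl) {
  total <- fr + fl + sr + sl
  if (total == 0) {
    return(list(total = 0, pct_right = NA_real_, dom = "none",
                success = NA_real_, shaping = FALSE, learner = FALSE))
  }
  pr <- 100 * (fr + sr) / total
  pl <- 100 * (fl + sl) / total
  dom <- if (pr > 70) "right" else if (pl > 70) "left" else "none"
  succ <- (sr + sl) / total
  list(total = total, pct_right = pr, dom = dom, success = succ,
       shaping = total >= 20 && dom != "none", learner = succ >= 0.30)
}

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# write a small well-formed track CSV; returns the path
write_demo_track_csv <- function(path, frames = 0:2,
                                 kps = c("palm", "pellet"),
                                 likelihood = 0.95) {
  df <- data.frame(frame = frames)
  for (kp in kps) {
    df[[paste0(kp, "_u")]] <- 100 + seq_along(frames)
    df[[paste0(kp, "_v")]] <- 200 + seq_along(frames)
    df[[paste0(kp, "_likelihood")]] <- likelihood
  }
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# project scene trajectories (behavioral frame) into views and triangulate
# one keypoint back, returning world-frame points
pipeline_triangulate <- function(sc, trajs, views = c("front", "left_mirror"),
                                 noise_px = 0, dropout = 0, seed = 1) {
  cams <- scene_cameras(sc)[views]
  world <- lapply(trajs, function(tr) {
    trajectory3d(to_world_frame(sc, tr$xyz), fs = tr$fs,
                 keypoint = tr$keypoint)
  })
  tracks <- project_scene(world, cams, noise_px = noise_px,
                          dropout = dropout, seed = seed)
  list(tracks = tracks, cams = cams,
       tri = function(kp) {
         triangulate(lapply(tracks, function(t) {
           as.matrix(t$keypoints[[kp]][, c("u", "v")])
         }), cams)
       })
}

# measured (triangulated, world-frame) reference points of a scene
measure_references <- function(sc, views = c("front", "left_mirror"),
                               noise_px = 0, seed = 99) {
  refs <- lapply(seq_len(nrow(sc$reference_nominal)), function(i) {
    trajectory3d(matrix(sc$reference_nominal[i, ], 2, 3, byrow = TRUE),
                 fs = sc$fs)
  })
  names(refs) <- rownames(sc$reference_nominal)
  pp <- pipeline_triangulate(sc, refs, views, noise_px = noise_px,
                             seed = seed)
  do.call(rbind, lapply(names(refs), function(k) colMeans(pp$tri(k))))
}

# run the whole simulated pipeline: session -> projection -> triangulation
# -> alignment; returns aligned palm/pellet trajectories and the session
run_simulated_pipeline <- function(sc, n_reaches = 5,
                                   outcome_mix = NULL,
                                   views = c("front", "left_mirror"),
                                   noise_px = 0, dropout = 0) {
  ss <- if (is.null(outcome_mix)) {
    generate_session(sc, n_reaches = n_reaches)
  } else {
    generate_session(sc, n_reaches = n_reaches, outcome_mix = outcome_mix)
  }
  pp <- pipeline_triangulate(sc, list(palm = ss$truth$paw,
                                      pellet = ss$truth$pellet),
                             views, noise_px = noise_px, dropout = dropout,
                             seed = sc$seed + 1000L)
  meas <- measure_references(sc, views, seed = sc$seed + 2000L)
  tr <- NULL
  align <- function(kp, name) {
    a <- align_to_reference(trajectory3d(pp$tri(kp), fs = sc$fs,
                                         keypoint = name),
                            meas, sc$reference_nominal)
    a
  }
  list(session = ss,
       palm = align("palm", "palm"),
       pellet = align("pellet", "pellet"))
}
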