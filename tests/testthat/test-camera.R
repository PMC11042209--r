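test_that("DLT recovers a known camera from noiseless correspondences", {
  sc <- scene_config(seed = 2)
  fix <- calibration_fixture(sc)
  for (v in names(fix$cams)) {
    est <- calibrate_dlt(fix$points3d, fix$pixels[[v]])
    expect_camera_equal(est, fix$cams[[v]], tol = 1e-7)
    expect_lt(attr(est, "reprojection_error"), 1e-6)
  }
})

test_that("DLT reprojection error stays at the pixel-noise scale", {
  sc <- scene_config()
  errs <- vapply(1:100, function(s) {
    fix <- calibration_fixture(sc, views = "front", noise_px = 0.5, seed = s)
    attr(calibrate_dlt(fix$points3d, fix$pixels$front),
         "reprojection_error")
  }, numeric(1))
  expect_lte(stats::quantile(errs, 0.95), 1)
})

test_that("DLT rejects degenerate configurations", {
  sc <- scene_config()
  fix <- calibration_fixture(sc, views = "front")
  expect_error(calibrate_dlt(fix$points3d[1:5, ], fix$pixels$front[1:5, ]),
               "at least 6")
  # one board pose only: coplanar points
  flat <- checkerboard_corners(sc$board)
  px <- project_points(scene_cameras(sc)$front,
                       to_world_frame(sc, flat))
  expect_error(calibrate_dlt(to_world_frame(sc, flat), px), "coplanar")
})

test_that("mirror cameras behave like reflections", {
  sc <- scene_config()
  front <- scene_cameras(sc)$front
  pl <- sc$mirrors$left_mirror
  virt <- mirror_camera(front, pl$point, pl$normal)
  expect_true(virt$mirrored)

  # involution: reflecting twice restores the camera up to scale
  back <- mirror_camera(virt, pl$point, pl$normal)
  expect_camera_equal(back, front)

  # points on the mirror plane project identically in both cameras
  tang <- cross3_test(pl$normal, c(0, 0, 1))
  on_plane <- rbind(pl$point, pl$point + 5 * tang, pl$point + c(0, 0, 7))
  expect_equal(project_points(virt, on_plane),
               project_points(front, on_plane), tolerance = 1e-9)

  expect_error(mirror_camera(front, pl$point, c(0, 0, 0)), "non-zero")
})

test_that("virtual-camera projection equals projecting the reflected point", {
  # independent reflection oracle: reflect the 3D point by hand, project it
  # through the real camera, compare with the virtual camera's projection
  sc <- scene_config()
  front <- scene_cameras(sc)$front
  pl <- sc$mirrors$right_mirror
  virt <- mirror_camera(front, pl$point, pl$normal)
  set.seed(42)
  X <- matrix(stats::rnorm(30, 0, 5), 10, 3)
  reflect <- function(x) {
    x - 2 * sum((x - pl$point) * pl$normal) * pl$normal
  }
  Xr <- t(apply(X, 1, reflect))
  expect_equal(project_points(virt, X), project_points(front, Xr),
               tolerance = 1e-9)
})

test_that("triangulation inverts projection exactly without noise", {
  sc <- scene_config()
  cams <- scene_cameras(sc)[c("front", "left_mirror")]
  t <- seq(0, 4 * pi, length.out = 120)
  helix <- cbind(3 * cos(t) - 4, 3 * sin(t), t / 2)
  px <- lapply(cams, function(cam) {
    project_points(cam, to_world_frame(sc, helix))
  })
  X <- triangulate(px, cams)
  rmse <- sqrt(mean(rowSums((X - to_world_frame(sc, helix))^2)))
  expect_lt(rmse, 1e-9)
})

test_that("a frame missing in one view is NaN without touching neighbors", {
  sc <- scene_config()
  cams <- scene_cameras(sc)[c("front", "right_mirror")]
  X0 <- to_world_frame(sc, cbind(seq(-6, 0, length.out = 7), 0, 1))
  px <- lapply(cams, function(cam) project_points(cam, X0))
  px[[1]][4, ] <- NA
  X <- triangulate(px, cams)
  expect_true(all(is.na(X[4, ])))
  expect_lt(max(abs(X[-4, ] - X0[-4, ])), 1e-9)
})

test_that("linear triangulation under pixel noise matches the nonlinear oracle", {
  sc <- scene_config(seed = 8)
  cams <- scene_cameras(sc)[c("front", "left_mirror")]
  set.seed(8)
  X0 <- to_world_frame(sc, cbind(stats::runif(40, -8, 0),
                                 stats::runif(40, -3, 3),
                                 stats::runif(40, 0, 6)))
  px <- lapply(cams, function(cam) {
    project_points(cam, X0) + matrix(stats::rnorm(80, 0, 0.5), 40, 2)
  })
  lin <- triangulate(px, cams)
  ref <- triangulate_refine(px, cams)
  rmse_lin <- sqrt(mean(rowSums((lin - X0)^2)))
  rmse_ref <- sqrt(mean(rowSums((ref - X0)^2)))
  expect_gt(rmse_lin, 0)
  expect_lt(abs(rmse_lin - rmse_ref) / rmse_ref, 0.10)
})

test_that("alignment recovers the world offset and the 7 mm slit distance", {
  sc <- scene_config(seed = 4)
  meas <- measure_references(sc)
  traj <- trajectory3d(meas, fs = sc$fs)
  aligned <- align_to_reference(traj, meas, sc$reference_nominal)
  tr <- attr(aligned, "transform")
  # recovered transform is the inverse of the generator's world offset
  expect_equal(tr$s, 1, tolerance = 1e-6)
  expect_lt(max(abs(tr$R - t(sc$world$R))), 1e-6)
  expect_lt(max(abs(tr$t + as.numeric(t(sc$world$R) %*% sc$world$t))), 1e-6)
  # identity when references are already nominal
  tr0 <- attr(align_to_reference(traj, sc$reference_nominal,
                                 sc$reference_nominal), "transform")
  expect_equal(tr0$s, 1, tolerance = 1e-9)
  expect_lt(max(abs(tr0$R - diag(3))), 1e-9)
  expect_lt(max(abs(tr0$t)), 1e-9)
  # slit center to pellet distance equals the configured 7 mm
  slit <- (aligned$xyz[2, ] + aligned$xyz[3, ]) / 2
  pellet <- aligned$xyz[1, ]
  expect_equal(sqrt(sum((slit - pellet)^2)), 7, tolerance = 1e-6)

  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(align_to_reference(traj, meas[1:3, ], line), "collinear")
})

test_that("aligned trajectories are invariant to the calibration gauge", {
  base <- list(world_rotation_deg = c(15, -40),
               world_translation = list(c(10, -5, 3), c(-25, 12, 40)))
  out <- lapply(1:2, function(i) {
    sc <- scene_config(seed = 21,
                       world_rotation_deg = base$world_rotation_deg[i],
                       world_translation = base$world_translation[[i]])
    run_simulated_pipeline(sc, n_reaches = 2)$palm$xyz
  })
  expect_lt(max(abs(out[[1]] - out[[2]]), na.rm = TRUE), 1e-6)
})
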