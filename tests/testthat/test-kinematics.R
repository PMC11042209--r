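test_that("finite differences are exact for constant and linear motion", {
  const <- trajectory3d(matrix(c(1, 2, 3), 30, 3, byrow = TRUE), fs = 100)
  expect_equal(max(abs(differentiate(const, 1))), 0)

  lin <- trajectory3d(cbind(50 * (0:49) / 100, 0, 0), fs = 100)
  v <- differentiate(lin, 1)
  expect_equal(v[, 1], rep(50, 50), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(max(abs(differentiate(lin, 2))), 0, tolerance = 1e-9)
})

test_that("sampled minimum-jerk peak speed matches the closed-form oracle", {
  D <- 10; T <- 0.3
  tr <- min_jerk_reach(D = D, T = T, fs = 100)
  v <- differentiate(tr, 1)
  vmax <- max(sqrt(rowSums(v^2)))
  expect_equal(vmax, min_jerk_vmax_oracle(D, T), tolerance = 0.01)
  expect_equal(min_jerk_vmax_oracle(D, T), 1.875 * D / T, tolerance = 1e-6)
})

test_that("integrating velocity recovers net displacement", {
  tr <- min_jerk_reach(D = 8, T = 0.35, fs = 100,
                       target = c(0, 1, 2), start = c(-8, 0, 0))
  v <- differentiate(tr, 1)
  # trapezoidal integral per axis
  dt <- 1 / tr$fs
  disp <- colSums((v[-1, ] + v[-nrow(v), ]) / 2) * dt
  net <- tr$xyz[nrow(tr$xyz), ] - tr$xyz[1, ]
  expect_equal(as.numeric(disp), as.numeric(net), tolerance = 0.01 * 8)
})

test_that("reach scalars have their defining properties", {
  tr <- min_jerk_reach(D = 8, T = 0.29, fs = 100, target = c(0, 1, 2),
                       start = c(-8, 0, 0))
  n <- nrow(tr$xyz)
  seg <- reach_segments(0L, n, n - 1L, "manual", n)
  sc <- compute_scalars(seg[1, ], tr)
  expect_equal(sc$duration_s, n / 100)
  # straight-line reach: path length equals start-to-apex distance
  expect_equal(sc$path_mm,
               sqrt(sum((tr$xyz[n, ] - tr$xyz[1, ])^2)), tolerance = 1e-9)
  expect_equal(c(sc$end_x_mm, sc$end_y_mm, sc$end_z_mm), c(0, 1, 2),
               tolerance = 1e-9)
  expect_identical(c(sc$end_x_mm, sc$end_y_mm, sc$end_z_mm),
                   c(sc$apex_x_mm, sc$apex_y_mm, sc$apex_z_mm))
  expect_lte(sc$vmean_mm_s, sc$vmax_mm_s)
  expect_equal(sc$tvmax_frac, 0.5, tolerance = 0.1)
})

test_that("speed scalars are invariant to rigid rotation and time shift", {
  tr <- min_jerk_reach(D = 7, T = 0.3, fs = 100)
  n <- nrow(tr$xyz)
  seg <- reach_segments(0L, n, n - 1L, "manual", n)
  base <- compute_scalars(seg[1, ], tr)

  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- trajectory3d(t(R %*% t(tr$xyz)), fs = tr$fs)
  rsc <- compute_scalars(seg[1, ], rot)
  for (col in c("vmean_mm_s", "vmax_mm_s", "amax_mm_s2", "jmax_mm_s3",
                "path_mm", "duration_s", "tvmax_frac")) {
    expect_equal(rsc[[col]], base[[col]], tolerance = 1e-9)
  }
  # endpoint transforms covariantly
  expect_equal(as.numeric(R %*% c(base$end_x_mm, base$end_y_mm,
                                  base$end_z_mm)),
               c(rsc$end_x_mm, rsc$end_y_mm, rsc$end_z_mm),
               tolerance = 1e-9)

  pad <- trajectory3d(rbind(matrix(tr$xyz[1, ], 25, 3, byrow = TRUE),
                            tr$xyz), fs = tr$fs)
  shift <- reach_segments(25L, n + 25L, n + 24L, "manual", n + 25L)
  ssc <- compute_scalars(shift[1, ], pad)
  expect_equal(ssc$vmax_mm_s, base$vmax_mm_s, tolerance = 1e-9)
  expect_equal(ssc$path_mm, base$path_mm, tolerance = 1e-9)
})

test_that("axis-wise velocity components sum in quadrature to 3D speed", {
  ss <- generate_session(scene_config(seed = 17), n_reaches = 2)
  v <- differentiate(ss$truth$paw, 1)
  speed <- sqrt(rowSums(v^2))
  recomposed <- sqrt(v[, "x"]^2 + v[, "y"]^2 + v[, "z"]^2)
  expect_lt(max(abs(speed - recomposed), na.rm = TRUE), 1e-9)
})

test_that("mostly-missing segments are flagged instead of scored", {
  tr <- min_jerk_reach(D = 8, T = 0.3, fs = 100)
  n <- nrow(tr$xyz)
  tr$xyz[5:(5 + ceiling(0.6 * n)), ] <- NA
  seg <- reach_segments(0L, n, 2L, "manual", n)
  sc <- compute_scalars(seg[1, ], tr)
  expect_false(sc$ok)
  expect_lt(sc$complete_frac, 0.5)
  expect_true(is.na(sc$vmax_mm_s))
})

test_that("average trajectory reduces to the reach for degenerate ensembles", {
  tr <- min_jerk_reach(D = 7, T = 0.3, fs = 100)
  n <- nrow(tr$xyz)
  one <- reach_segments(0L, n, n - 1L, "manual", n)
  avg1 <- average_trajectory(one, tr, n_samples = 50)
  resampled <- apply(tr$xyz, 2, function(col) {
    stats::approx(seq(0, 1, length.out = n), col,
                  seq(0, 1, length.out = 50))$y
  })
  expect_equal(avg1$mean, resampled, tolerance = 1e-9, ignore_attr = TRUE)

  two_xyz <- rbind(tr$xyz, matrix(tr$xyz[n, ], 20, 3, byrow = TRUE), tr$xyz)
  two_traj <- trajectory3d(two_xyz, fs = 100)
  two <- reach_segments(c(0L, n + 20L), c(n, 2L * n + 20L),
                        c(n - 1L, 2L * n + 19L), "manual", nrow(two_xyz))
  avg2 <- average_trajectory(two, two_traj, n_samples = 50)
  expect_lt(max(avg2$sd), 1e-9)
  expect_equal(avg2$mean, avg1$mean, tolerance = 1e-9)
  expect_error(average_trajectory(one[0, ], tr), "no segments")
})

test_that("averaging noisy copies converges at the Monte-Carlo rate", {
  truth <- min_jerk_reach(D = 7, T = 0.3, fs = 100)
  n <- nrow(truth$xyz)
  m <- 20
  sigma <- 0.05
  set.seed(5)
  blocks <- lapply(1:m, function(i) {
    truth$xyz + matrix(rnorm(n * 3, 0, sigma), n, 3)
  })
  xyz <- do.call(rbind, blocks)
  traj <- trajectory3d(xyz, fs = 100)
  segs <- reach_segments(seq(0, by = n, length.out = m),
                         seq(n, by = n, length.out = m),
                         seq(n - 1, by = n, length.out = m),
                         "manual", nrow(xyz))
  avg <- average_trajectory(segs, traj, n_samples = n)
  err <- abs(avg$mean - truth$xyz)
  # 5-sigma envelope of the mean of m draws
  expect_lt(max(err), 5 * sigma / sqrt(m))
})
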