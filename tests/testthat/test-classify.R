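make_seg <- function(start, end, apex, n) {
  reach_segments(start, end, apex, "manual", n)[1, ]
}

test_that("explicit cascade rules fire on constructed scenes", {
  n <- 60L
  paw <- min_jerk_reach(D = 8, T = 0.3, fs = 100)
  paw$xyz <- rbind(paw$xyz, paw$xyz[nrow(paw$xyz):1, ][-1, ])
  paw <- trajectory3d(paw$xyz, fs = 100)
  nf <- nrow(paw$xyz)
  seg <- make_seg(0L, nf, 30L, nf)

  # pellet absent for the whole window -> in vain
  ghost <- trajectory3d(matrix(NA_real_, nf, 3), fs = 100)
  expect_identical(classify_reach(seg, paw, ghost), "in_vain")

  # static pellet 5 mm away with 2 mm contact radius -> missed
  far <- trajectory3d(matrix(c(0, 5, 0), nf, 3, byrow = TRUE), fs = 100)
  expect_identical(classify_reach(seg, paw, far, contact_radius = 2),
                   "missed")

  # mismatched frame ranges -> error
  short <- trajectory3d(matrix(0, nf - 1, 3), fs = 100)
  expect_error(classify_reach(seg, paw, short), "share the frame index")
})

test_that("rule-based labels reproduce generator intent per category", {
  mixes <- list(grasped = c(grasped = 1), missed = c(missed = 1),
                flicked = c(flicked = 1), lost = c(lost = 1),
                in_vain = c(in_vain = 1), artifact = c(artifact = 1))
  for (lab in names(mixes)) {
    sc <- scene_config(seed = 50 + match(lab, names(mixes)))
    ss <- generate_session(sc, n_reaches = 3, outcome_mix = mixes[[lab]])
    got <- classify_session(ss$truth$windows, ss$truth$paw, ss$truth$pellet,
                            mouth_point = sc$mouth_point,
                            mouth_radius = sc$mouth_radius,
                            contact_radius = sc$contact_radius)
    expect_identical(got, rep(lab, 3))
  }
})

test_that("every scored segment receives exactly one of the six labels", {
  sc <- scene_config(seed = 77, noise_mm = 0.05)
  ss <- generate_session(sc, n_reaches = 12)
  labs <- classify_session(ss$truth$windows, ss$paw, ss$pellet,
                           mouth_point = sc$mouth_point,
                           mouth_radius = sc$mouth_radius,
                           contact_radius = sc$contact_radius)
  expect_length(labs, 12L)
  expect_true(all(labs %in% outcome_levels()))
})

test_that("clustering separates two kinematically distinct reach types", {
  # short slow reaches vs long fast reaches
  aris <- vapply(1:10, function(s) {
    set.seed(s)
    mk <- function(D, T, m) {
      t(vapply(seq_len(m), function(i) {
        tr <- min_jerk_reach(D = D + rnorm(1, 0, 0.1),
                             T = T + runif(1, -0.01, 0.01), fs = 100)
        n <- nrow(tr$xyz)
        seg <- make_seg(0L, n, n - 1L, n)
        unlist(compute_scalars(seg, tr)[1, ])
      }, numeric(17)))
    }
    rows <- rbind(mk(4, 0.45, 12), mk(10, 0.22, 12))
    tab <- as.data.frame(rows)
    truth <- rep(0:1, each = 12)
    cl <- cluster_reaches(tab, method = "kmeans", k = 2, seed = s)
    mclust::adjustedRandIndex(cl$labels, truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("clustering edge cases behave as documented", {
  ss <- generate_session(scene_config(seed = 14), n_reaches = 6)
  tab <- scalar_table(segment_reaches(ss$truth$paw), ss$truth$paw)
  one <- cluster_reaches(tab, k = 1, seed = 1)
  expect_true(all(one$labels == 0L))
  expect_true(is.na(one$silhouette))
  expect_error(cluster_reaches(tab, k = 50, seed = 1), "exceeds")

  # duplicated rows always co-cluster
  dup <- rbind(tab, tab[1, ])
  cl <- cluster_reaches(dup, method = "agglomerative", k = 2, seed = 1)
  expect_identical(cl$labels[1], cl$labels[nrow(dup)])

  # standardization makes the result invariant to feature scaling
  scaled <- tab
  scaled$vmax_mm_s <- scaled$vmax_mm_s * 1000
  scaled$duration_s <- scaled$duration_s / 50
  a <- cluster_reaches(tab, method = "kmeans", k = 2, seed = 3)
  b <- cluster_reaches(scaled, method = "kmeans", k = 2, seed = 3)
  expect_gte(mclust::adjustedRandIndex(a$labels, b$labels), 0.999)

  # deterministic under a fixed seed, across methods
  for (m in c("kmeans", "agglomerative", "gmm")) {
    c1 <- cluster_reaches(tab, method = m, k = 2, seed = 7)
    c2 <- cluster_reaches(tab, method = m, k = 2, seed = 7)
    expect_identical(c1$labels, c2$labels)
  }
})

test_that("category counting covers all six labels and rejects unknowns", {
  tab <- data.frame(label = c("grasped", "grasped", "grasped",
                              "missed", "missed"))
  counts <- count_categories(tab)
  expect_identical(counts[["grasped"]], 3L)
  expect_identical(counts[["missed"]], 2L)
  expect_identical(sum(counts), 5L)
  expect_setequal(names(counts), outcome_levels())

  expect_identical(sum(count_categories(data.frame(label = character(0)))),
                   0L)
  expect_error(count_categories(data.frame(label = "dropped")), "unknown")

  ss <- generate_session(scene_config(seed = 23), n_reaches = 10)
  tab2 <- data.frame(label = ss$truth$windows$label)
  counts2 <- count_categories(tab2)
  expect_identical(sum(counts2), 10L)
  expect_identical(as.integer(counts2["grasped"]),
                   sum(ss$truth$windows$label == "grasped"))
})

test_that("manual labels override and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(segment_index = c(0, 2),
                              label = c("grasped", "lost")),
                   path, row.names = FALSE)
  labs <- read_manual_labels(path, 4)
  expect_identical(labs, c("grasped", NA, "lost", NA))
  utils::write.csv(data.frame(segment_index = 0, label = "oops"),
                   path, row.names = FALSE)
  expect_error(read_manual_labels(path, 4), "unknown")
})
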