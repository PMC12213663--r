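test_that("noiseless correspondences recover every model exactly", {
  set.seed(201)
  for (model in c("translation", "rigid", "similarity", "affine")) {
    for (i in 1:25) {
      t_true <- random_transform(model)
      src <- matrix(stats::runif(20, -100, 100), 10, 2)
      r <- estimate_transform(correspondences(src, apply_transform(t_true, src)),
                              model = model)
      expect_lt(r$fre_rms_px, 1e-9)
      expect_lt(max(abs(r$transform$matrix - t_true$matrix)), 1e-9)
      expect_lt(max(abs(r$transform$offset - t_true$offset)), 1e-9)
    }
  }
})

test_that("a mirrored similarity is recovered when reflections are allowed", {
  set.seed(202)
  t_true <- random_similarity(reflect = TRUE)
  src <- matrix(stats::runif(16, -50, 50), 8, 2)
  r <- estimate_transform(correspondences(src, apply_transform(t_true, src)),
                          "similarity")
  expect_lt(r$fre_rms_px, 1e-9)
  expect_true(transform_is_reflected(r$transform))
})

test_that("identity correspondences give identity with zero FRE", {
  pts <- matrix(stats::runif(12, 0, 10), 6, 2)
  r <- estimate_transform(correspondences(pts, pts), "similarity")
  expect_equal(r$transform$matrix, diag(2), tolerance = 1e-12)
  expect_equal(r$fre_rms_px, 0, tolerance = 1e-12)
  expect_equal(r$fre_rms_px, sqrt(mean(rowSums(r$residuals_px^2))), tolerance = 1e-9)
})

test_that("insufficient or degenerate configurations raise informative errors", {
  one <- correspondences(cbind(1, 2), cbind(3, 4))
  expect_error(estimate_transform(one, "similarity"), "at least 2")
  coll <- correspondences(cbind(1:3, 2 * (1:3)), cbind(1:3, 2 * (1:3)) + 1)
  expect_error(estimate_transform(coll, "affine"), "collinear")
  same <- correspondences(matrix(1, 4, 2), matrix(2, 4, 2))
  expect_error(estimate_transform(same, "similarity"), "degenerate|coincident")
})

test_that("channel shift from paired beads recovers a field-wide affine", {
  set.seed(203)
  beads <- matrix(stats::runif(40, 0, 512), 20, 2)
  truth <- transform2d(1.01 * diag(2), c(1.7, -2.3), "affine",
                       "fm_beads", "fm")
  moved <- apply_transform(truth, beads)
  r <- estimate_channel_shift(point_set(beads, "fm"),
                              point_set(moved, "fm_beads"))
  corrected <- apply_transform(r$transform, moved)
  expect_lt(max(sqrt(rowSums((corrected - beads)^2))), 0.02)
  expect_error(estimate_channel_shift(beads, moved[1:10, ]), "paired in order")
  coll <- cbind(1:3, 1:3)
  expect_error(estimate_channel_shift(coll, coll + 1), "collinear")
})

test_that("matching pairs markers with and without an initial transform", {
  set.seed(204)
  pts <- matrix(stats::runif(24, 10, 90), 12, 2)
  m_id <- match_correspondences(pts, pts, initial = transform_identity(),
                                max_dist_px = 1)
  expect_identical(m_id$pairs[, 1], m_id$pairs[, 2])
  # 12 true markers + 4 spurious per side under a known similarity
  t_true <- random_similarity(c(1.5, 3))
  src <- rbind(pts, matrix(stats::runif(8, 10, 90), 4, 2))
  tgt <- rbind(apply_transform(t_true, pts),
               matrix(stats::runif(8, -100, 400), 4, 2))
  perm_s <- sample(16); perm_t <- sample(16)
  mm <- match_correspondences(src[perm_s, ], tgt[perm_t, ], max_dist_px = 2)
  expect_identical(nrow(mm$pairs), 12L)
  # matched pairs are exactly the true ones: map and compare
  fit <- estimate_transform(mm$correspondences, "similarity")
  expect_lt(fit$fre_rms_px, 1e-9)
  expect_lt(max(abs(fit$transform$matrix - t_true$matrix)), 1e-8)
})

test_that("matching 8 vs 15 markers yields at most 8 pairs", {
  set.seed(205)
  t_true <- random_similarity()
  small <- matrix(stats::runif(16, 0, 100), 8, 2)
  big <- rbind(apply_transform(t_true, small), matrix(stats::runif(14, -200, 300), 7, 2))
  mm <- match_correspondences(small, big[sample(15), ], max_dist_px = 2)
  expect_lte(nrow(mm$pairs), 8L)
  expect_gte(nrow(mm$pairs), 3L)
})

test_that("matching refuses empty input and impossible gates", {
  expect_error(match_correspondences(matrix(numeric(0), 0, 2), cbind(1, 2),
                                     max_dist_px = 1), "empty")
  far_a <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  expect_error(match_correspondences(far_a, far_a + 1000,
                                     initial = transform_identity(),
                                     max_dist_px = 1), "no matching")
})

test_that("FRE at N=6 follows the residual-dof noise law", {
  set.seed(206)
  N <- 6; t_true <- random_similarity()
  for (s in c(0.5, 1.0)) {
    fres <- replicate(500, {
      src <- matrix(stats::runif(2 * N, 0, 100), N, 2)
      tgt <- apply_transform(t_true, src) + matrix(stats::rnorm(2 * N, 0, s), N, 2)
      estimate_transform(correspondences(src, tgt), "similarity")$fre_rms_px
    })
    expect_lt(abs(mean(fres) / (s * sqrt(2 * (1 - 2 / N))) - 1), 0.1)
  }
})

test_that("leave-one-out TRE is a conservative error proxy (>= FRE)", {
  set.seed(207)
  stats_mc <- replicate(300, {
    src <- matrix(stats::runif(16, 0, 100), 8, 2)
    tgt <- apply_transform(random_similarity(), src) +
      matrix(stats::rnorm(16, 0, 0.7), 8, 2)
    r <- estimate_transform(correspondences(src, tgt), "similarity")
    c(mean(r$loo_tre_px), r$fre_rms_px)
  })
  # one-sided: mean LOO TRE above mean FRE
  expect_lt(t.test(stats_mc[1, ] - stats_mc[2, ], alternative = "greater")$p.value,
            0.01)
})

test_that("FRE is invariant under a rigid change of the target frame", {
  set.seed(208)
  src <- matrix(stats::runif(20, 0, 100), 10, 2)
  tgt <- apply_transform(random_similarity(), src) + matrix(stats::rnorm(20, 0, 1), 10, 2)
  r1 <- estimate_transform(correspondences(src, tgt), "similarity")
  rot <- transform_similarity(0.9, 1, 12, -7)
  r2 <- estimate_transform(correspondences(src, apply_transform(rot, tgt)), "similarity")
  expect_equal(r1$fre_rms_px, r2$fre_rms_px, tolerance = 1e-9)
})

test_that("robust estimation survives gross outliers and is seeded", {
  set.seed(209)
  t_true <- random_similarity()
  src <- matrix(stats::runif(24, 0, 100), 12, 2)
  tgt <- apply_transform(t_true, src)
  out_idx <- c(2, 5, 9)
  tgt[out_idx, ] <- tgt[out_idx, ] + matrix(stats::runif(6, 30, 60), 3, 2)
  corr <- correspondences(src, tgt)
  r <- estimate_transform_robust(corr, "similarity", inlier_threshold_px = 2, seed = 42)
  ref <- estimate_transform(correspondences(src[-out_idx, ], tgt[-out_idx, ]),
                            "similarity")
  expect_lt(max(abs(r$transform$matrix - ref$transform$matrix)), 1e-6)
  expect_identical(which(!r$inlier_mask), as.integer(out_idx))
  r2 <- estimate_transform_robust(corr, "similarity", inlier_threshold_px = 2, seed = 42)
  expect_identical(r$transform$matrix, r2$transform$matrix)
  # all-inlier input reproduces the plain fit
  clean <- correspondences(src, apply_transform(t_true, src))
  ra <- estimate_transform_robust(clean, "similarity", inlier_threshold_px = 2, seed = 1)
  rp <- estimate_transform(clean, "similarity")
  expect_lt(max(abs(ra$transform$matrix - rp$transform$matrix)), 1e-9)
})

test_that("robust estimation errors when consensus is impossible", {
  set.seed(210)
  src <- matrix(stats::runif(8, 0, 100), 4, 2)
  tgt <- apply_transform(random_similarity(), src)
  tgt[1:3, ] <- tgt[1:3, ] + matrix(stats::runif(6, 40, 80), 3, 2)
  expect_error(estimate_transform_robust(correspondences(src, tgt), "similarity",
                                         inlier_threshold_px = 2, seed = 5),
               "consensus")
  expect_error(estimate_transform_robust(correspondences(src, tgt), "similarity",
                                         inlier_threshold_px = 2),
               "seed is required")
})

test_that("build_chain composes stages and checks frames", {
  pts <- matrix(stats::runif(16, 0, 50), 8, 2)
  id_coarse <- estimate_transform(correspondences(pts, pts), "similarity",
                                  source_frame = "fm", target_frame = "montage")
  id_fine <- estimate_transform(correspondences(pts, pts), "similarity",
                                source_frame = "montage", target_frame = "tomogram")
  ch <- build_chain(NULL, id_coarse, id_fine)
  expect_equal(ch$fm_to_tomogram$matrix, diag(2), tolerance = 1e-12)
  bad <- estimate_transform(correspondences(pts, pts), "similarity",
                            source_frame = "other", target_frame = "tomogram")
  expect_error(build_chain(NULL, id_coarse, bad), "does not match")
})

test_that("the composed chain equals stagewise application on probe points", {
  m <- generate_scene(scene_spec(17))
  sim <- simulate_registration_chain(m, noise_px = 0, seed = 1)
  probes <- matrix(stats::runif(20, 10, 80), 10, 2)
  ch <- sim$chain
  step <- apply_transform(ch$montage_to_tomogram$transform,
                          apply_transform(ch$fm_to_montage$transform, probes))
  direct <- apply_transform(ch$fm_to_tomogram, probes)
  expect_lt(max(abs(step - direct)), 1e-9)
  expect_lt(sim$error_tomo_px, 1e-6)
})
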