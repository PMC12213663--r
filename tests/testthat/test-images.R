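test_that("z-projection reduces correctly and matches a naive loop", {
  set.seed(301)
  one <- tomogram_stack(array(stats::runif(1 * 12 * 15), c(1, 12, 15)), 1)
  expect_equal(zproject(one, "min")$pixels, one$voxels[1, , ])
  const <- tomogram_stack(array(7, c(5, 8, 8)), 2)
  expect_true(all(zproject(const, "mean")$pixels == 7))
  st <- tomogram_stack(array(stats::runif(6 * 20 * 25), c(6, 20, 25)), 0.5)
  for (m in c("min", "mean", "max")) {
    naive <- apply(st$voxels, c(2, 3), get(ifelse(m == "mean", "mean", m)))
    expect_equal(zproject(st, m)$pixels, naive, tolerance = 1e-12)
  }
  expect_true(all(zproject(st, "min")$pixels <= zproject(st, "mean")$pixels + 1e-12))
  expect_true(all(zproject(st, "mean")$pixels <= zproject(st, "max")$pixels + 1e-12))
})

test_that("min projection shows dark spheres at every depth", {
  m <- generate_scene(scene_spec(4, tomo_size = 320L, tomo_nz = 24L,
                                 n_gold50 = 6, gold50_min_sep_nm = 30,
                                 n_gold10 = 0))
  stack <- render_tomogram(m)
  proj <- zproject(stack, "min")
  bg <- max(proj$pixels)
  for (i in seq_len(nrow(m$gold50))) {
    v <- proj$pixels[round(m$gold50$tomo_y[i]) + 1, round(m$gold50$tomo_x[i]) + 1]
    expect_lt(v, 0.7 * bg)
  }
  # equality with the per-pixel loop oracle on a sub-window
  sub <- stack$voxels[, 1:40, 1:40]
  naive <- apply(sub, c(2, 3), min)
  expect_equal(zproject(stack, "min")$pixels[1:40, 1:40], naive)
})

test_that("warping is exact for identity and integer translations", {
  set.seed(302)
  img <- matrix(stats::runif(30 * 40), 30, 40)
  ip <- image_plane(img, 1)
  w_id <- warp_image(ip, transform_identity(), c(30, 40))
  expect_equal(unclass(w_id$pixels)[, ], img, tolerance = 1e-12, ignore_attr = TRUE)
  w <- warp_image(ip, transform_translation(3, 5), c(30, 40))
  expect_equal(w$pixels[6:30, 4:40], img[1:25, 1:37], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(!attr(w$pixels, "valid")[1:5, ]))
  expect_true(all(w$pixels[1:5, ] == 0))
})

test_that("warp round-trip stays within bilinear tolerance on band-limited images", {
  set.seed(303)
  img <- EBImage::gblur(matrix(stats::runif(96 * 96), 96, 96), sigma = 3)
  t <- transform_similarity(0.35, 1.1, 4, -2)
  fwd <- warp_image(image_plane(img, 1), t, c(96, 96))
  back <- warp_image(fwd, invert_transform(t), c(96, 96))
  ok <- attr(back$pixels, "valid") & attr(fwd$pixels, "valid")
  # interior only: out-of-field pixels were filled
  core <- ok & row(img) %in% 20:76 & col(img) %in% 20:76
  dyn <- diff(range(img))
  expect_lt(max(abs(back$pixels[core] - img[core])), 0.02 * dyn)
})

test_that("warping commutes with composition", {
  set.seed(304)
  img <- EBImage::gblur(matrix(stats::runif(80 * 80), 80, 80), sigma = 3)
  a <- transform_similarity(0.2, 1.05, 2, 1)
  b <- transform_similarity(-0.15, 0.95, -3, 2)
  two <- warp_image(warp_image(image_plane(img, 1), a, c(80, 80)), b, c(80, 80))
  one <- warp_image(image_plane(img, 1), compose_transforms(b, a), c(80, 80))
  ok <- attr(two$pixels, "valid") & attr(one$pixels, "valid") &
    row(img) %in% 15:65 & col(img) %in% 15:65
  expect_lt(max(abs(two$pixels[ok] - one$pixels[ok])), 0.02 * diff(range(img)))
})

test_that("overlay renders the EM base and adds normalized channels", {
  set.seed(305)
  em <- image_plane(matrix(stats::runif(40 * 40, 0, 1000), 40, 40), 4, "montage")
  base_only <- compose_overlay(em)
  g <- (em$pixels - min(em$pixels)) / diff(range(em$pixels))
  expect_equal(base_only[, , 1], g, tolerance = 1e-12)
  expect_equal(base_only[, , 2], base_only[, , 3], tolerance = 1e-12)
  fm <- image_plane(matrix(stats::runif(40 * 40, 0, 500), 40, 40), 4, "montage", "PSD95")
  ov <- compose_overlay(em, list(list(plane = fm,
                                      transform = transform_identity("montage", "montage"),
                                      color = "green")), alpha = 1)
  fmn <- (fm$pixels - min(fm$pixels)) / diff(range(fm$pixels))
  expect_equal(ov[, , 2], pmin(g + fmn, 1), tolerance = 1e-9)
  expect_equal(ov[, , 1], g, tolerance = 1e-12)   # red untouched by a green channel
  # idempotent in the EM base under zero-intensity fluorescence
  zero <- image_plane(matrix(0, 40, 40), 4, "montage")
  ov0 <- compose_overlay(em, list(list(plane = zero,
                                       transform = transform_identity("montage", "montage"),
                                       color = "red")))
  expect_equal(ov0, base_only, tolerance = 1e-12)
})

test_that("overlay rejects transforms into the wrong frame", {
  em <- image_plane(matrix(0, 20, 20), 4, "montage")
  fm <- image_plane(matrix(0, 20, 20), 160, "fm")
  t_wrong <- transform_identity("fm", "tomogram")
  expect_error(compose_overlay(em, list(list(plane = fm, transform = t_wrong,
                                             color = "green"))), "frame")
})

test_that("bead overlay peaks coincide with dark EM discs", {
  m <- generate_scene(scene_spec(21, n_beads = 9))
  em <- render_em(m, "montage")
  fm <- render_fm(m, "beads")
  shift_then_map <- compose_transforms(m$fm_to_montage, m$channel_shift)
  ov <- compose_overlay(em, list(list(plane = fm, transform = shift_then_map,
                                      color = "red")), alpha = 1)
  red_excess <- ov[, , 1] - ov[, , 2]
  for (i in seq_len(nrow(m$beads))) {
    r <- round(m$beads$mont_y[i]) + 1; c <- round(m$beads$mont_x[i]) + 1
    win <- red_excess[(r - 60):(r + 60), (c - 60):(c + 60)]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lt(sqrt(sum((pk - 61)^2)), 61)  # peak lives in the bead's window
    expect_gt(max(win), 0.3)               # and is genuinely red
  }
})

test_that("the 8 dihedral orientations are tagged with exact inverse transforms", {
  asym <- matrix(seq_len(63), 7, 9)
  vars <- enumerate_orientations(asym)
  expect_length(vars, 8)
  sigs <- vapply(vars, function(v) paste(as.vector(v$pixels), collapse = ","), "")
  expect_identical(anyDuplicated(sigs), 0L)
  for (v in vars) {
    back <- warp_image(v$pixels, v$transform, dim(asym))
    expect_equal(unclass(back)[, ], asym, ignore_attr = TRUE, tolerance = 1e-9)
  }
  # constant image: identical pixels, distinct tags
  const <- matrix(1, 6, 6)
  vc <- enumerate_orientations(const)
  expect_true(all(vapply(vc, function(v) all(v$pixels == 1), TRUE)))
  mats <- vapply(vc, function(v) paste(round(c(v$transform$matrix, v$transform$offset), 9),
                                       collapse = ","), "")
  expect_identical(anyDuplicated(mats), 0L)
  # scoring against a reference ranks the true orientation first
  scored <- enumerate_orientations(vars[[4]]$pixels, reference = asym)
  expect_identical(which.max(vapply(scored, `[[`, 1, "score")), 2L)  # rot90 undoes rot270
})
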