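test_that("three exact non-collinear pairs determine the affine exactly;
           fewer pairs are rejected", {
  gt <- make_affine(scale_x = 1.4, rotation = 7, tx = 22, ty = -9)
  src <- matrix(c(10, 10, 80, 20, 30, 70), 3, 2, byrow = TRUE)
  dst <- affine_apply(gt, src)
  est <- estimate_affine_ransac(src, dst, ransac_params(seed = 1))
  expect_equal(est$transform$matrix, gt$matrix, tolerance = 1e-6)
  expect_lt(max(est$errors), 1e-6)
  expect_error(estimate_affine_ransac(src[1:2, ], dst[1:2, ]),
               "at least 3")
  # all-collinear geometry cannot be solved
  col_src <- cbind(1:5, 2 * (1:5))
  expect_error(estimate_affine_ransac(col_src, col_src + 1,
                                      ransac_params(seed = 1)),
               "degenerate")
})

test_that("RANSAC recovers a transform from contaminated correspondences
           and flags the planted inliers", {
  set.seed(77)
  gt <- make_affine(scale_x = 1.5, scale_y = 1.45, rotation = -4,
                    tx = 30, ty = 12)
  src <- cbind(runif(20, 0, 300), runif(20, 0, 400))
  dst <- affine_apply(gt, src)
  out_idx <- 15:20
  dst[out_idx, ] <- dst[out_idx, ] + matrix(runif(12, 40, 120), 6, 2)
  p <- ransac_params(seed = 5)
  est <- estimate_affine_ransac(src, dst, p)
  expect_lt(max(abs(est$transform$matrix - gt$matrix)), 1e-3)
  expect_true(all(1:14 %in% est$inliers))
  expect_true(all(est$errors[est$inliers] <= p$max_distance))
  # determinism given the seed
  est2 <- estimate_affine_ransac(src, dst, p)
  expect_identical(est$transform$matrix, est2$transform$matrix)
})

test_that("raising the trial budget never shrinks the consensus", {
  set.seed(19)
  gt <- make_affine(scale_x = 1.3, rotation = 2, tx = 10, ty = 4)
  src <- cbind(runif(30, 0, 200), runif(30, 0, 200))
  dst <- affine_apply(gt, src)
  dst[25:30, ] <- dst[25:30, ] + 60
  n_prev <- 0L
  for (trials in c(5L, 20L, 100L, 1000L)) {
    est <- estimate_affine_ransac(src, dst,
                                  ransac_params(max_num_trials = trials,
                                                seed = 3))
    expect_gte(length(est$inliers), n_prev)
    n_prev <- length(est$inliers)
  }
})

test_that("affine decomposition round-trips pose parameters", {
  d0 <- decompose_affine(affine_identity())
  expect_equal(unlist(d0), c(scale_x = 1, scale_y = 1, rotation = 0,
                             shear = 0, tx = 0, ty = 0))
  d10 <- decompose_affine(make_affine(rotation = 10))
  expect_equal(d10$rotation, 10, tolerance = 1e-9)
  expect_equal(c(d10$scale_x, d10$scale_y), c(1, 1), tolerance = 1e-9)
  t3 <- make_affine(scale_x = 1.3, scale_y = 1.3, rotation = 5,
                    tx = 40, ty = -12)
  d3 <- decompose_affine(t3)
  expect_equal(c(d3$scale_x, d3$scale_y, d3$rotation, d3$tx, d3$ty),
               c(1.3, 1.3, 5, 40, -12), tolerance = 1e-9)
  # recomposition reproduces the matrix
  t4 <- make_affine(1.2, 0.9, -8, 0.05, 7, 3)
  d4 <- decompose_affine(t4)
  re <- make_affine(d4$scale_x, d4$scale_y, d4$rotation, d4$shear,
                    d4$tx, d4$ty)
  expect_equal(re$matrix, t4$matrix, tolerance = 1e-9)
  expect_error(affine_transform(matrix(c(1, 2, 2, 4, 0, 0), 2, 3)),
               "degenerate")
})

test_that("admissibility bounds are enforced on scale, rotation and
           translation", {
  b <- admissibility_bounds()
  diag_px <- 800
  expect_true(is_admissible(affine_identity(), b, diag_px))
  expect_false(is_admissible(make_affine(scale_x = 3, scale_y = 3), b,
                             diag_px))
  expect_true(is_admissible(make_affine(rotation = 19.9), b, diag_px))
  expect_false(is_admissible(make_affine(rotation = 20.1), b, diag_px))
  expect_false(is_admissible(make_affine(tx = 500), b, diag_px))
  expect_true(is_admissible(make_affine(tx = 300), b, diag_px))
})

test_that("warping: identity, exact integer shifts, inverse round trip", {
  set.seed(5)
  img <- gauss_blur(matrix(runif(80 * 60), 80, 60), 2)
  img <- (img - min(img)) / diff(range(img))
  expect_equal(warp(img, affine_identity(), 60, 80), img,
               tolerance = 1e-12)
  sh <- make_affine(tx = 5, ty = 3)
  shifted <- warp(img, sh, 60, 80)
  expect_equal(shifted[10:70, 10:50], img[7:67, 5:45], tolerance = 1e-12)
  tr <- make_affine(scale_x = 1.15, scale_y = 1.1, rotation = 6,
                    tx = 4, ty = -2)
  there <- warp(img, tr, 90, 100)
  back <- warp(there, affine_invert(tr), 60, 80)
  inner <- abs(back - img)[20:60, 15:45]
  expect_lt(mean(inner), 0.01)
  # mask warping is nearest-neighbour and stays logical
  m <- disc_mask(60, 80, 30, 40, 12)
  wm <- warp_mask(m, sh, 60, 80)
  expect_type(wm, "logical")
  expect_equal(wm[20:70, 20:50], m[17:67, 15:45])
})

test_that("transform JSON serialisation round-trips", {
  tr <- make_affine(1.3, 1.25, 4, 0.01, 17, -6)
  p <- tempfile(fileext = ".json")
  affine_to_json(tr, p)
  expect_equal(affine_from_json(p)$matrix, tr$matrix, tolerance = 1e-12)
})

test_that("register_pair recovers identity-rendered scenes and fails
           gracefully on empty fluorescence", {
  sc <- generate_scene(species_profile("rosette_top"),
                       affine_identity(),
                       synth_noise(n_clutter_range = c(2L, 3L)),
                       seed = 31,
                       vis_size = c(360L, 420L), flu_size = c(360L, 420L))
  res <- register_pair(sc$flu, sc$vis, reg_config())
  expect_true(res$success)
  # mean reprojection over the plant area within 1 px of identity
  pts <- which(sc$flu_mask, arr.ind = TRUE)
  pts <- cbind(pts[, 2] - 1, pts[, 1] - 1)
  proj <- affine_apply(res$transform, pts)
  expect_lt(mean(sqrt(rowSums((proj - pts)^2))), 1)
  # a black FLU frame cannot be registered
  black <- array(0, dim(sc$flu))
  res2 <- register_pair(black, sc$vis, reg_config())
  expect_false(res2$success)
  expect_lte(res2$counts$n_fp_flu, 5L)
  expect_s3_class(res2, "registration_result")
})

test_that("register_pair recovers a known transform on a synthetic pair", {
  gt <- make_affine(scale_x = 1.2, scale_y = 1.2, rotation = 5,
                    tx = 30, ty = -15)
  # anchor the plant inside both frames under this transform
  sc <- generate_scene(species_profile("cereal_side"),
                       gt, seed = 44,
                       vis_size = c(420L, 520L), flu_size = c(340L, 430L))
  res <- register_pair(sc$flu, sc$vis, reg_config())
  expect_true(res$success)
  d <- decompose_affine(res$transform)
  expect_lt(abs(d$scale_x - 1.2), 0.05)
  expect_lt(abs(d$scale_y - 1.2), 0.05)
  expect_lt(abs(d$rotation - 5), 1)
  expect_lt(sqrt((d$tx - 30)^2 + (d$ty + 15)^2), 3)
  expect_true(all(res$counts$n_selected >= 3))
})

test_that("registration is reproducible for a fixed seed", {
  sc <- quick_scene(seed = 6)
  r1 <- register_pair(sc$flu, sc$vis, reg_config())
  r2 <- register_pair(sc$flu, sc$vis, reg_config())
  expect_identical(r1$transform$matrix, r2$transform$matrix)
  expect_identical(r1$counts, r2$counts)
})

test_that("cropped framing maps coordinates back to full frames", {
  sc <- quick_scene(seed = 13)
  cfg <- reg_config(framing = "cropped", crop_margin = 10L)
  res <- register_pair(sc$flu, sc$vis, cfg, vis_mask = sc$vis_mask,
                       flu_mask = sc$flu_mask)
  expect_true(res$success)
  dg <- decompose_affine(sc$gt_transform)
  d <- decompose_affine(res$transform)
  expect_lt(abs(d$scale_x - dg$scale_x), 0.1)
})
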