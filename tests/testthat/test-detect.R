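test_that("all detectors return nothing on constant images", {
  flat <- matrix(0.5, 48, 48)
  p <- detector_params()
  expect_equal(nrow(detect_harris(flat, p)), 0L)
  expect_equal(nrow(detect_min_eigen(flat, p)), 0L)
  expect_equal(nrow(detect_fast(flat, p)), 0L)
  expect_equal(nrow(detect_doh(flat, p)), 0L)
  expect_equal(nrow(detect_mser(flat, p)), 0L)
})

test_that("corner detectors find the four corners of a square", {
  img <- square_image(64L, 17L, 49L)       # corners at (16,16)...(48,48)
  p <- detector_params()
  truth <- expand.grid(x = c(16, 48), y = c(16, 48))
  for (fps in list(detect_harris(img, p), detect_min_eigen(img, p))) {
    expect_gte(nrow(fps), 4L)
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((fps$x - truth$x[i])^2 + (fps$y - truth$y[i])^2)
      expect_lte(min(d), 2)
    }
  }
})

test_that("harris and min-eigen strengths match the brute-force structure
           tensor to 1e-6 relative", {
  set.seed(4)
  img <- gauss_blur(matrix(runif(64 * 64), 64, 64), 1)
  img <- img + square_image(64L, 20L, 44L, fg = 0.4, bg = 0)
  img <- img / max(img)
  p <- detector_params()
  hs <- detect_harris(img, p)
  me <- detect_min_eigen(img, p)
  expect_gt(nrow(hs), 0); expect_gt(nrow(me), 0)
  for (i in seq_len(min(nrow(hs), 10L))) {
    # strengths live on the pixel grid; evaluate the oracle there
    m <- oracle_structure_tensor(img, round(hs$x[i]), round(hs$y[i]),
                                 p$harris_filter_size)
    r_oracle <- det(m) - 0.04 * sum(diag(m))^2
    expect_equal(hs$strength[i], r_oracle, tolerance = 1e-6)
  }
  for (i in seq_len(min(nrow(me), 10L))) {
    m <- oracle_structure_tensor(img, round(me$x[i]), round(me$y[i]),
                                 p$min_eigen_filter_size)
    # closed-form smaller eigenvalue of the 2x2 tensor
    lam <- (m[1, 1] + m[2, 2]) / 2 -
      sqrt(((m[1, 1] - m[2, 2]) / 2)^2 + m[1, 2]^2)
    expect_equal(me$strength[i], lam, tolerance = 1e-6)
  }
})

test_that("corner thresholds are monotone: higher quality, fewer points", {
  set.seed(9)
  img <- gauss_blur(matrix(runif(80 * 80), 80, 80), 1.2)
  img <- (img - min(img)) / diff(range(img))
  n_prev <- Inf
  for (q in c(0.01, 0.03, 0.1, 0.3)) {
    n <- nrow(detect_harris(img, detector_params(harris_min_quality = q)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("FAST detects an isolated bright pixel and passes the exhaustive
           segment test everywhere", {
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  fps <- detect_fast(img, detector_params(fast_min_contrast = 0.9))
  expect_equal(nrow(fps), 1L)
  expect_equal(round(c(fps$x, fps$y)), c(10, 10))
  # every detection on a textured image passes the brute-force test
  set.seed(21)
  tex <- gauss_blur(matrix(runif(60 * 60), 60, 60), 0.8)
  tex <- (tex - min(tex)) / diff(range(tex))
  p <- detector_params()
  fps <- detect_fast(tex, p)
  expect_gt(nrow(fps), 0)
  for (i in seq_len(nrow(fps)))
    expect_true(oracle_fast_test(tex, round(fps$x[i]), round(fps$y[i]),
                                 p$fast_min_contrast, p$fast_arc_length))
  # non-maximum suppression: no two detections in one 3x3 neighbourhood
  if (nrow(fps) > 1L) {
    dmin <- min(dist(cbind(round(fps$x), round(fps$y)), method = "maximum"))
    expect_gt(dmin, 1)
  }
  # lowering the contrast threshold never loses corners
  n_low <- nrow(detect_fast(tex, detector_params(fast_min_contrast = 0.05)))
  expect_gte(n_low, nrow(fps))
})

test_that("determinant-of-Hessian finds blobs at the right scale", {
  img <- gaussian_blob(64L, sigma = 4)
  fps <- detect_doh(img, detector_params())
  expect_equal(nrow(fps), 1L)
  expect_lt(abs(fps$x - 31.5), 1)
  expect_lt(abs(fps$y - 31.5), 1)
  expect_lt(max(fps$scale / 4, 4 / fps$scale), 1.5)
  # two well-separated blobs of different size: ordered scales
  img2 <- pmax(gaussian_blob(128L, cx = 30, cy = 30, sigma = 3),
               gaussian_blob(128L, cx = 90, cy = 90, sigma = 8))
  fps2 <- detect_doh(img2, detector_params())
  expect_equal(nrow(fps2), 2L)
  near_small <- which.min((fps2$x - 30)^2 + (fps2$y - 30)^2)
  expect_lt(fps2$scale[near_small], fps2$scale[-near_small])
})

test_that("MSER reports stable bright and dark regions", {
  # toy frames are small, so lift the relative area cap off the regions
  p <- detector_params(mser_max_area_frac = 0.5)
  # bright disc on black: centroid and equivalent radius recovered
  img <- matrix(0, 64, 64)
  img[disc_mask(64, 64, 30, 25, 10)] <- 1
  fps <- detect_mser(img, p)
  expect_equal(nrow(fps), 1L)
  expect_lt(abs(fps$x - 30), 1)
  expect_lt(abs(fps$y - 25), 1)
  expect_lt(abs(fps$scale - 10) / 10, 0.1)
  # nested bright square inside a brighter rectangle, distinct levels
  img2 <- matrix(0, 80, 80)
  img2[20:60, 15:65] <- 0.5
  img2[35:45, 30:50] <- 1
  fps2 <- detect_mser(img2, p)
  expect_gte(nrow(fps2), 2L)
  # one region near each centroid
  expect_lte(min(sqrt((fps2$x - 40)^2 + (fps2$y - 40)^2)), 2)
})

test_that("combined detection merges lists and respects count bounds", {
  img <- square_image(64L, 17L, 49L)
  p <- detector_params()
  single <- detect_harris(img, p)
  comb1 <- detect_combined(img, "harris", p)
  expect_equal(comb1[order(comb1$x, comb1$y), c("x", "y", "strength")],
               single[order(single$x, single$y), c("x", "y", "strength")],
               ignore_attr = TRUE)
  both <- detect_combined(img, c("harris", "min_eigen"), p)
  nh <- nrow(detect_harris(img, p)); nm <- nrow(detect_min_eigen(img, p))
  expect_gte(nrow(both), max(nh, nm))
  expect_lte(nrow(both), nh + nm)
  expect_error(detect_combined(img, "nope", p), "unknown detector")
  # adapter detectors plug into the combined scheme
  register_adapter("fake", function(img, p)
    data.frame(x = 1, y = 2, scale = 1, strength = 99,
               detector_id = "x", stringsAsFactors = FALSE))
  withr::defer(register_adapter("fake", NULL))
  fps <- detect_combined(img, c("harris", "adapter:fake"), p)
  expect_true("adapter:fake" %in% fps$detector_id)
})

test_that("detections stay inside bounds with strengths above threshold", {
  scene <- quick_scene(seed = 2)
  img <- colour_edge(scene$vis)
  p <- detector_params()
  fps <- detect_combined(img, p = p)
  expect_gt(nrow(fps), 0)
  expect_true(all(fps$x >= 0 & fps$x < ncol(img)))
  expect_true(all(fps$y >= 0 & fps$y < nrow(img)))
  expect_true(all(fps$strength > 0))
})

test_that("strongest keeps the top-n by strength with stable ties", {
  fps <- data.frame(x = c(3, 1, 2, 5, 4), y = c(1, 1, 2, 2, 3),
                    scale = 1, strength = c(1, 5, 3, 4, 2),
                    detector_id = "harris", stringsAsFactors = FALSE)
  expect_equal(nrow(strongest(fps, 0)), 0L)
  expect_equal(nrow(strongest(fps, 99)), 5L)
  top2 <- strongest(fps, 2)
  expect_setequal(top2$strength, c(5, 4))
  # ties broken by (y, x)
  tie <- data.frame(x = c(2, 1), y = c(1, 1), scale = 1,
                    strength = c(7, 7), detector_id = "fast",
                    stringsAsFactors = FALSE)
  expect_equal(strongest(tie, 1)$x, 1)
})
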