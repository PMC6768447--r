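test_that("identity scenes with equal frames have identical masks and
           regeneration is byte-deterministic", {
  sz <- c(320L, 380L)
  sc <- generate_scene(species_profile("rosette_top"), affine_identity(),
                       seed = 9, vis_size = sz, flu_size = sz)
  expect_identical(sc$vis_mask, sc$flu_mask)
  sc2 <- generate_scene(species_profile("rosette_top"), affine_identity(),
                        seed = 9, vis_size = sz, flu_size = sz)
  expect_identical(sc$vis, sc2$vis)
  expect_identical(sc$flu, sc2$flu)
  # different seed, different scene
  sc3 <- generate_scene(species_profile("rosette_top"), affine_identity(),
                        seed = 10, vis_size = sz, flu_size = sz)
  expect_false(identical(sc$vis, sc3$vis))
})

test_that("ground-truth transform maps the FLU mask onto the VIS mask", {
  tr <- make_affine(scale_x = 1.4, scale_y = 1.4, rotation = 3,
                    tx = 25, ty = -10)
  sc <- generate_scene(species_profile("cereal_side"), tr, seed = 12)
  wm <- warp_mask(sc$flu_mask, tr, ncol(sc$vis_mask), nrow(sc$vis_mask))
  iou <- sum(wm & sc$vis_mask) / sum(wm | sc$vis_mask)
  expect_gte(iou, 0.95)
  # centroids agree within a pixel
  cen <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  }
  flu_cen_in_vis <- affine_apply(tr, cen(sc$flu_mask))
  expect_lt(sqrt(sum((flu_cen_in_vis - cen(sc$vis_mask))^2)), 1.5)
})

test_that("modality structure: dark FLU background, monotone VIS
           illumination gradient, clutter stays off the plant", {
  sc <- quick_scene(seed = 19)
  grey_flu <- to_greyscale(sc$flu)
  expect_lt(mean(grey_flu[!sc$flu_mask]), 0.05)
  # background gradient: clutter-free, noise-free scene, column means
  # strictly increase top to bottom
  sc0 <- generate_scene(species_profile("rosette_top"), affine_identity(),
                        synth_noise(vis_sd = 0, flu_sd = 0,
                                    n_clutter_range = c(0L, 0L)),
                        seed = 19)
  g <- to_greyscale(sc0$vis)
  bg_rows <- which(rowSums(sc0$vis_mask) == 0)
  rm <- rowMeans(g[bg_rows, ])
  expect_true(all(diff(rm) > 0))
  # invalid scene: transform pushes the plant far outside the FLU frame
  expect_error(generate_scene(species_profile("rosette_top"),
                              make_affine(tx = 5000), seed = 1),
               "invalid scene")
})

test_that("non-rigid leaf perturbation moves only the FLU rendering", {
  prof <- species_profile("cereal_side", n_leaves = 3L)
  tr <- with_test_seed(33, sample_transform(profile = prof))
  sc <- generate_scene(prof, tr, seed = 33)
  expect_identical(perturb_nonrigid(sc, 0), sc)
  pert <- perturb_nonrigid(sc, 40, seed = 2)
  expect_identical(pert$vis, sc$vis)
  expect_false(identical(pert$flu_mask, sc$flu_mask))
  or0 <- overlap_ratio(sc$flu_mask, tr, sc$vis_mask)
  or1 <- overlap_ratio(pert$flu_mask, tr, sc$vis_mask)
  expect_lt(or1, or0)
  # the mask stays a plant-like union of leaves: component count bounded
  lab <- phytoreg:::cpp_label(pert$flu_mask)
  expect_lte(max(lab), prof$n_leaves + 1L)
})

test_that("sampled transforms honour the admissibility envelope", {
  set.seed(61)
  for (i in 1:25) {
    tr <- sample_transform()
    expect_true(is_admissible(tr, admissibility_bounds(),
                              sqrt(514^2 + 614^2)))
    d <- decompose_affine(tr)
    expect_true(d$scale_x >= 1.2 - 0.05 && d$scale_x <= 1.8 + 0.05)
    expect_lte(abs(d$rotation), 5)
  }
})

test_that("generated datasets are complete, deterministic and admissible", {
  out1 <- file.path(tempdir(), "synthds1")
  out2 <- file.path(tempdir(), "synthds2")
  man1 <- generate_dataset(3, list(species_profile("rosette_top"),
                                   species_profile("cereal_side")),
                           out_dir = out1, seed = 5)
  expect_equal(nrow(man1), 3L)
  expect_true(all(file.exists(man1$flu_path)))
  expect_true(all(file.exists(man1$vis_path)))
  expect_true(all(file.exists(man1$vis_mask_path)))
  expect_true(all(file.exists(man1$flu_mask_path)))
  expect_equal(length(list.files(out1, pattern = "\\.png$")), 12L)
  for (i in 1:3) {
    tr <- affine_from_json(file.path(out1,
                                     sprintf("pair_%03d_transform.json", i)))
    expect_true(is_admissible(tr, admissibility_bounds(),
                              sqrt(514^2 + 614^2)))
  }
  man2 <- generate_dataset(3, list(species_profile("rosette_top"),
                                   species_profile("cereal_side")),
                           out_dir = out2, seed = 5)
  for (i in 1:3)
    expect_identical(readBin(man1$vis_path[i], "raw", 1e6),
                     readBin(man2$vis_path[i], "raw", 1e6))
  unlink(c(out1, out2), recursive = TRUE)
})
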