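# ---------------------------------------------------------------------------
# Synthetic FLU/VIS scene generation. Scenes emulate the structure of real
# phenotyping image pairs: a VIS frame with a vertical illumination
# gradient, rectangular/circular background clutter (pot, carrier
# contours), a soft shadow and a green plant silhouette; and a FLU frame
# showing only the plant, red-dominant on a near-black background, at a
# different resolution and a known affine offset. Ground-truth masks and
# the FLU -> VIS transform are exact, and everything is seed-deterministic.
# ---------------------------------------------------------------------------

#' Species rendering profile
#'
#' Controls the synthetic plant morphology: `rosette_top` mimics a
#' top-view rosette (round leaves radiating from a centre), `cereal_side`
#' a side-view cereal shoot (thin, curved leaves on a vertical stem).
#'
#' @param morphology `"rosette_top"` or `"cereal_side"`.
#' @param n_leaves number of leaves.
#' @param leaf_length_range,leaf_width_range per-leaf size ranges in VIS
#'   pixels.
#' @param curvature_range unitless leaf-bend range (fraction of length).
#' @return list of class `species_profile`.
#' @export
species_profile <- function(morphology = c("rosette_top", "cereal_side"),
                            n_leaves = NULL,
                            leaf_length_range = NULL,
                            leaf_width_range = NULL,
                            curvature_range = NULL) {
  morphology <- match.arg(morphology)
  def <- if (morphology == "rosette_top")
    list(n_leaves = 8L, leaf_length_range = c(70, 115),
         leaf_width_range = c(20, 34), curvature_range = c(0.05, 0.2))
  else
    list(n_leaves = 5L, leaf_length_range = c(130, 230),
         leaf_width_range = c(16, 24), curvature_range = c(0.25, 0.6))
  p <- list(morphology = morphology,
            n_leaves = as.integer(n_leaves %||% def$n_leaves),
            leaf_length_range = leaf_length_range %||% def$leaf_length_range,
            leaf_width_range = leaf_width_range %||% def$leaf_width_range,
            curvature_range = curvature_range %||% def$curvature_range)
  stopifnot(p$n_leaves >= 1L, all(p$leaf_length_range > 0),
            all(p$leaf_width_range > 0))
  structure(p, class = "species_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise parameters of the synthetic renderer
#'
#' @param vis_sd,flu_sd Gaussian pixel-noise standard deviation of the two
#'   modalities (on `[0,1]` intensities).
#' @param n_clutter_range range of the number of background clutter shapes
#'   in the VIS frame.
#' @export
synth_noise <- function(vis_sd = 0.02, flu_sd = 0.01,
                        n_clutter_range = c(2L, 5L)) {
  list(vis_sd = vis_sd, flu_sd = flu_sd,
       n_clutter_range = as.integer(n_clutter_range))
}

# --- stroke geometry --------------------------------------------------------
# A plant is a list of strokes; a stroke is a data.frame of centreline
# samples (x, y) with per-sample radius r, rasterised as a union of discs.

bezier_stroke <- function(p0, p1, p2, width, n = NULL, tip_round = TRUE) {
  if (is.null(n)) {
    # sample densely enough that consecutive discs overlap even at the
    # narrow tip (spacing <= 0.5 px after any downscaling by ~2)
    len <- sqrt(sum((p1 - p0)^2)) + sqrt(sum((p2 - p1)^2))
    n <- max(64L, as.integer(ceiling(len / 0.4)))
  }
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  r <- width / 2 * (0.35 + 0.65 * sin(pi * pmin(t * 1.12, 1))^0.8)
  if (!tip_round) r <- rep(width / 2, n)
  data.frame(x = x, y = y, r = pmax(r, 0.6), t = t)
}

# leaf strokes in local coordinates; uses the current RNG stream
plant_strokes <- function(profile) {
  runifr <- function(rg) stats::runif(1, rg[1], rg[2])
  strokes <- list()
  if (profile$morphology == "rosette_top") {
    ang0 <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(profile$n_leaves)) {
      a <- ang0 + (i - 1) * 2 * pi / profile$n_leaves +
        stats::runif(1, -0.15, 0.15)
      len <- runifr(profile$leaf_length_range)
      wid <- runifr(profile$leaf_width_range)
      cur <- runifr(profile$curvature_range)
      dir <- c(cos(a), sin(a))
      nrm <- c(-sin(a), cos(a))
      p0 <- c(0, 0)
      p2 <- dir * len
      p1 <- dir * len * 0.5 + nrm * cur * len
      strokes[[length(strokes) + 1L]] <- bezier_stroke(p0, p1, p2, wid)
    }
  } else {                                   # cereal_side
    stem_h <- max(profile$leaf_length_range) * 1.05
    strokes[[1]] <- bezier_stroke(c(0, 0), c(stats::runif(1, -6, 6),
                                             -stem_h * 0.5),
                                  c(stats::runif(1, -10, 10), -stem_h),
                                  max(profile$leaf_width_range) * 0.8,
                                  tip_round = FALSE)
    for (i in seq_len(profile$n_leaves)) {
      h <- stats::runif(1, 0.25, 0.95)       # attachment height on stem
      side <- if (i %% 2L == 0L) 1 else -1
      len <- runifr(profile$leaf_length_range)
      wid <- runifr(profile$leaf_width_range)
      cur <- runifr(profile$curvature_range)
      p0 <- c(0, -stem_h * h)
      up <- stats::runif(1, 0.35, 0.8)       # initial upward slant
      p1 <- p0 + c(side * len * 0.45, -len * up)
      p2 <- p0 + c(side * len * 0.85, -len * up + cur * len)
      strokes[[length(strokes) + 1L]] <- bezier_stroke(p0, p1, p2, wid)
    }
  }
  strokes
}

strokes_bbox_center <- function(strokes) {
  xs <- unlist(lapply(strokes, `[[`, "x"))
  ys <- unlist(lapply(strokes, `[[`, "y"))
  c((min(xs) + max(xs)) / 2, (min(ys) + max(ys)) / 2)
}

shift_strokes <- function(strokes, dx, dy) {
  lapply(strokes, function(s) { s$x <- s$x + dx; s$y <- s$y + dy; s })
}

transform_strokes <- function(strokes, t) {
  sc <- sqrt(abs(det(t$matrix[, 1:2])))
  lapply(strokes, function(s) {
    xy <- affine_apply(t, cbind(s$x, s$y))
    data.frame(x = xy[, 1], y = xy[, 2], r = s$r * sc, t = s$t)
  })
}

# rasterise strokes (0-based coordinates) into a w x h logical mask
rasterize_strokes <- function(strokes, width, height) {
  m <- matrix(FALSE, height, width)
  for (s in strokes) {
    for (i in seq_len(nrow(s))) {
      r <- s$r[i]
      c0 <- max(0L, floor(s$x[i] - r)); c1 <- min(width - 1L, ceiling(s$x[i] + r))
      r0 <- max(0L, floor(s$y[i] - r)); r1 <- min(height - 1L, ceiling(s$y[i] + r))
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      dx2 <- (cols - s$x[i])^2
      dy2 <- (rows - s$y[i])^2
      hit <- outer(dy2, dx2, `+`) <= r^2
      m[rows + 1L, cols + 1L] <- m[rows + 1L, cols + 1L] | hit
    }
  }
  m
}

render_flu <- function(strokes, width, height, flu_sd, rng_seed) {
  mask <- rasterize_strokes(strokes, width, height)
  with_seed(rng_seed, {
    img <- array(0, c(height, width, 3L))
    base <- c(0.02, 0.015, 0.01)             # near-black background
    plant <- c(stats::runif(1, 0.78, 0.9),   # chlorophyll fluorescence red
               stats::runif(1, 0.08, 0.15), 0.05)
    soft <- gauss_blur(mask * 1, 0.4)        # soften silhouette edges
    for (k in 1:3) {
      ch <- base[k] + (plant[k] - base[k]) * soft
      if (flu_sd > 0) ch <- ch + stats::rnorm(length(ch), 0, flu_sd)
      img[, , k] <- pmin(pmax(ch, 0), 1)
    }
    list(img = img, mask = mask)
  })
}

render_vis <- function(strokes, width, height, noise) {
  # caller supplies RNG state
  img <- array(0, c(height, width, 3L))
  grad <- seq(0.28, 0.62, length.out = height)   # vertical illumination
  tint <- c(1.0, 0.97, 0.9)
  for (k in 1:3) img[, , k] <- matrix(grad * tint[k], height, width)
  n_cl <- if (noise$n_clutter_range[2] >= noise$n_clutter_range[1] &&
                noise$n_clutter_range[2] > 0)
    sample(noise$n_clutter_range[1]:noise$n_clutter_range[2], 1L) else 0L
  for (j in seq_len(n_cl)) {                     # pot / carrier clutter
    shade <- stats::runif(1, 0.12, 0.75)
    col <- shade * c(1, stats::runif(1, 0.75, 1), stats::runif(1, 0.55, 0.95))
    cx <- stats::runif(1, 0, width - 1); cy <- stats::runif(1, 0, height - 1)
    if (stats::runif(1) < 0.5) {                 # rectangle
      w2 <- stats::runif(1, 12, 70); h2 <- stats::runif(1, 8, 50)
      rows <- max(0, round(cy - h2)):min(height - 1, round(cy + h2)) + 1L
      cols <- max(0, round(cx - w2)):min(width - 1, round(cx + w2)) + 1L
      for (k in 1:3) img[rows, cols, k] <- col[k]
    } else {                                     # disc
      rr <- stats::runif(1, 10, 45)
      r0 <- max(0, floor(cy - rr)):min(height - 1, ceiling(cy + rr))
      c0 <- max(0, floor(cx - rr)):min(width - 1, ceiling(cx + rr))
      hit <- outer((r0 - cy)^2, (c0 - cx)^2, `+`) <= rr^2
      for (k in 1:3) {
        sub <- img[r0 + 1L, c0 + 1L, k]; sub[hit] <- col[k]
        img[r0 + 1L, c0 + 1L, k] <- sub
      }
    }
  }
  mask <- rasterize_strokes(strokes, width, height)
  # soft shadow: blurred, offset, darkened silhouette at 30% opacity
  sh <- gauss_blur(mask * 1, 6)
  sh_off <- matrix(0, height, width)
  oy <- 9L; ox <- 7L
  sh_off[(oy + 1L):height, (ox + 1L):width] <-
    sh[1L:(height - oy), 1L:(width - ox)]
  for (k in 1:3) img[, , k] <- img[, , k] * (1 - 0.3 * sh_off)
  # plant drawn last, over clutter and shadow
  plant_col <- c(stats::runif(1, 0.12, 0.2), stats::runif(1, 0.45, 0.62),
                 stats::runif(1, 0.1, 0.18))
  texture <- gauss_blur(matrix(stats::runif(height * width), height, width), 2)
  texture <- 0.75 + 0.5 * (texture - min(texture)) /
    max(max(texture) - min(texture), 1e-12)
  soft <- gauss_blur(mask * 1, 0.8)
  for (k in 1:3)
    img[, , k] <- img[, , k] * (1 - soft) + plant_col[k] * texture * soft
  if (noise$vis_sd > 0)
    img <- img + stats::rnorm(length(img), 0, noise$vis_sd)
  img <- pmin(pmax(img, 0), 1)
  list(img = img, mask = mask)
}

plant_anchor <- function(profile, width, height) {
  if (profile$morphology == "rosette_top") c(width / 2, height / 2)
  else c(width / 2, height * 0.55)
}

#' Generate a synthetic FLU/VIS scene
#'
#' Draws a plant silhouette (Bezier-curve leaves per the species profile)
#' into a VIS frame with vertical illumination gradient, clutter shapes,
#' a soft shadow and pixel noise, and into a FLU frame (red-dominant plant
#' on near-black background) positioned via the inverse of the
#' ground-truth transform. Masks are exact rasterisations of the same
#' geometry; the whole scene is a deterministic function of `seed`.
#'
#' @param profile [species_profile()].
#' @param transform `affine_transform` mapping FLU to VIS coordinates
#'   (the ground truth); default identity.
#' @param noise [synth_noise()] parameters.
#' @param seed integer seed.
#' @param vis_size,flu_size frame sizes `c(width, height)` in pixels.
#' @return object of class `scene_sample`: `vis`, `flu` (3-channel
#'   rasters), `vis_mask`, `flu_mask`, `gt_transform`, `seed`, plus the
#'   stroke geometry needed by [perturb_nonrigid()].
#' @export
generate_scene <- function(profile = species_profile(),
                           transform = affine_identity(),
                           noise = synth_noise(), seed = 1L,
                           vis_size = c(514L, 614L),
                           flu_size = c(308L, 406L)) {
  stopifnot(inherits(transform, "affine_transform"))
  w_v <- vis_size[1]; h_v <- vis_size[2]
  w_f <- flu_size[1]; h_f <- flu_size[2]
  flu_seed <- (as.integer(seed) * 7L + 13L) %% .Machine$integer.max
  with_seed(seed, {
    strokes <- plant_strokes(profile)
    ctr <- strokes_bbox_center(strokes)
    anchor <- plant_anchor(profile, w_v, h_v)
    strokes <- shift_strokes(strokes, anchor[1] - ctr[1], anchor[2] - ctr[2])
    vis <- render_vis(strokes, w_v, h_v, noise)
    flu_strokes <- transform_strokes(strokes, affine_invert(transform))
    flu <- render_flu(flu_strokes, w_f, h_f, noise$flu_sd, flu_seed)
    if (!any(vis$mask) || !any(flu$mask))
      stop("invalid scene: transform places the plant outside a frame",
           call. = FALSE)
    structure(list(vis = vis$img, flu = flu$img,
                   vis_mask = vis$mask, flu_mask = flu$mask,
                   gt_transform = transform, seed = as.integer(seed),
                   profile = profile, noise = noise,
                   strokes_vis = strokes, strokes_flu = flu_strokes,
                   flu_seed = flu_seed,
                   vis_size = c(w_v, h_v), flu_size = c(w_f, h_f)),
              class = "scene_sample")
  })
}

#' Perturb a scene with non-rigid leaf motion
#'
#' Redraws one randomly chosen leaf in the FLU rendering with its tip
#' displaced by `leaf_displacement` pixels along the leaf normal,
#' emulating inertial leaf movement between the two acquisitions. The
#' ground-truth transform is left unchanged (it remains the best global
#' affine), so the overlap ratio of a perfect registration drops below 1.
#'
#' @param s `scene_sample`.
#' @param leaf_displacement tip displacement in FLU pixels (>= 0).
#' @param seed seed for the leaf choice.
#' @return perturbed `scene_sample` (FLU image and mask updated).
#' @export
perturb_nonrigid <- function(s, leaf_displacement, seed = 1L) {
  stopifnot(inherits(s, "scene_sample"), leaf_displacement >= 0)
  if (leaf_displacement == 0) return(s)
  strokes <- s$strokes_flu
  # leaves only: for cereal morphology stroke 1 is the stem
  first_leaf <- if (s$profile$morphology == "cereal_side") 2L else 1L
  idx <- with_seed(seed,
                   sample(first_leaf:length(strokes), 1L))
  st <- strokes[[idx]]
  n <- nrow(st)
  tang <- c(st$x[n] - st$x[n - 1L], st$y[n] - st$y[n - 1L])
  tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
  nrm <- c(-tang[2], tang[1])
  st$x <- st$x + nrm[1] * leaf_displacement * st$t^2
  st$y <- st$y + nrm[2] * leaf_displacement * st$t^2
  strokes[[idx]] <- st
  flu <- render_flu(strokes, s$flu_size[1], s$flu_size[2],
                    s$noise$flu_sd, s$flu_seed)
  s$flu <- flu$img
  s$flu_mask <- flu$mask
  s$strokes_flu <- strokes
  s
}

#' Sample an admissible ground-truth transform
#'
#' Draws a FLU -> VIS transform from the study's geometry: an overall
#' scale in `scale_range` (the VIS/FLU camera-resolution ratio), up to 2%
#' scale anisotropy, a small rotation, slight shear, and a translation
#' that keeps the plant near the FLU frame centre with up to
#' `jitter` px offset. Uses the current RNG stream.
#'
#' @param vis_size,flu_size frame sizes `c(width, height)`.
#' @param profile [species_profile()] (fixes the plant anchor).
#' @param scale_range,rot_range sampling ranges for scale and rotation
#'   (degrees).
#' @param aniso maximal relative scale anisotropy.
#' @param shear_max maximal absolute shear.
#' @param jitter maximal FLU-centre offset in pixels.
#' @return `affine_transform`.
#' @export
sample_transform <- function(vis_size = c(514L, 614L),
                             flu_size = c(308L, 406L),
                             profile = species_profile(),
                             scale_range = c(1.2, 1.8),
                             rot_range = c(-5, 5),
                             aniso = 0.02, shear_max = 0.02,
                             jitter = 25) {
  s <- stats::runif(1, scale_range[1], scale_range[2])
  sy <- s * stats::runif(1, 1 - aniso, 1 + aniso)
  th <- stats::runif(1, rot_range[1], rot_range[2])
  sh <- stats::runif(1, -shear_max, shear_max)
  lin <- make_affine(scale_x = s, scale_y = sy, rotation = th, shear = sh)
  vis_anchor <- plant_anchor(profile, vis_size[1], vis_size[2])
  flu_anchor <- c(flu_size[1] / 2 + stats::runif(1, -jitter, jitter),
                  flu_size[2] / 2 + stats::runif(1, -jitter, jitter))
  t0 <- affine_apply(lin, flu_anchor)
  make_affine(scale_x = s, scale_y = sy, rotation = th, shear = sh,
              tx = vis_anchor[1] - t0[1], ty = vis_anchor[2] - t0[2])
}

#' Generate a synthetic benchmark dataset on disk
#'
#' Writes `n_pairs` scenes (VIS/FLU images and masks as PNG, ground-truth
#' transforms as JSON) plus a benchmark manifest CSV compatible with
#' [run_benchmark()]. Transforms are sampled with [sample_transform()];
#' every file is a deterministic function of `seed`.
#'
#' @param n_pairs number of scenes (>= 1).
#' @param profiles list of [species_profile()]s cycled over the pairs.
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param noise [synth_noise()].
#' @param vis_size,flu_size frame sizes.
#' @return the manifest data.frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n_pairs, profiles = list(species_profile()),
                             out_dir, seed = 1L, noise = synth_noise(),
                             vis_size = c(514L, 614L),
                             flu_size = c(308L, 406L)) {
  stopifnot(n_pairs >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    prof <- profiles[[(i - 1L) %% length(profiles) + 1L]]
    pair_seed <- (as.integer(seed) + 977L * i) %% .Machine$integer.max
    tr <- with_seed(pair_seed * 2L + 1L,
                    sample_transform(vis_size, flu_size, prof))
    sc <- generate_scene(prof, tr, noise, pair_seed, vis_size, flu_size)
    id <- sprintf("pair_%03d", i)
    paths <- file.path(out_dir, paste0(id, c("_vis.png", "_flu.png",
                                             "_vis_mask.png",
                                             "_flu_mask.png",
                                             "_transform.json")))
    write_image(sc$vis, paths[1])
    write_image(sc$flu, paths[2])
    write_mask(sc$vis_mask, paths[3])
    write_mask(sc$flu_mask, paths[4])
    affine_to_json(tr, paths[5])
    rows[[i]] <- data.frame(pair_id = id, flu_path = paths[2],
                            vis_path = paths[1], vis_mask_path = paths[3],
                            flu_mask_path = paths[4],
                            group = prof$morphology,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
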