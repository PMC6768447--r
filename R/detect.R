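# ---------------------------------------------------------------------------
# Feature-point detectors. All detectors return a data.frame of feature
# points with columns x, y (0-based pixel-centre coordinates), scale
# (pixels; 1 for single-scale corner detectors), strength (detector-specific
# metric, >= the acceptance threshold) and detector_id.
# ---------------------------------------------------------------------------

#' Detector parameters
#'
#' Tuning constants of the five native detectors. The defaults follow the
#' adjusted-parameter set found to work on multimodal plant image pairs:
#' corner filter size 3 with relative quality 0.03, FAST minimum contrast
#' 0.1 (fraction of the intensity range) with 9-of-16 arc length, 4
#' blob-pyramid octaves with a response floor equivalent to 25 on the
#' squared 8-bit intensity scale (stored as `25/255^2`), and an MSER
#' threshold step of 0.8 grey levels on the 0-255 scale.
#'
#' @param harris_filter_size odd Gaussian window (px) for the Harris
#'   structure tensor.
#' @param harris_min_quality acceptance threshold as a fraction of the
#'   maximal corner response, in (0, 1).
#' @param min_eigen_filter_size,min_eigen_min_quality same for the
#'   minimum-eigenvalue (Shi-Tomasi) detector.
#' @param fast_min_contrast FAST segment-test contrast, fraction of the
#'   intensity range.
#' @param fast_arc_length required contiguous circle pixels (of 16).
#' @param doh_num_octaves octaves of the determinant-of-Hessian pyramid.
#' @param doh_metric_threshold response floor of the scale-normalised
#'   determinant of Hessian on `[0,1]` intensities.
#' @param mser_threshold_delta threshold sweep step on the 0-255 scale.
#' @param mser_min_area,mser_max_area_frac region area limits (px and
#'   fraction of the image area).
#' @param mser_max_variation maximal relative area change across one
#'   threshold step for a region to count as stable.
#' @return list of class `detector_params`.
#' @export
detector_params <- function(harris_filter_size = 3L,
                            harris_min_quality = 0.03,
                            min_eigen_filter_size = 3L,
                            min_eigen_min_quality = 0.03,
                            fast_min_contrast = 0.1,
                            fast_arc_length = 9L,
                            doh_num_octaves = 4L,
                            doh_metric_threshold = 25 / 255^2,
                            mser_threshold_delta = 0.8,
                            mser_min_area = 30L,
                            mser_max_area_frac = 0.01,
                            mser_max_variation = 0.25) {
  stopifnot(harris_filter_size >= 3L, harris_filter_size %% 2L == 1L,
            min_eigen_filter_size >= 3L, min_eigen_filter_size %% 2L == 1L,
            harris_min_quality > 0, harris_min_quality < 1,
            min_eigen_min_quality > 0, min_eigen_min_quality < 1,
            fast_min_contrast > 0, fast_arc_length >= 1L,
            fast_arc_length <= 16L,
            doh_num_octaves >= 1L, doh_metric_threshold > 0,
            mser_threshold_delta > 0, mser_min_area >= 1L,
            mser_max_variation > 0)
  structure(list(harris_filter_size = as.integer(harris_filter_size),
                 harris_min_quality = harris_min_quality,
                 min_eigen_filter_size = as.integer(min_eigen_filter_size),
                 min_eigen_min_quality = min_eigen_min_quality,
                 fast_min_contrast = fast_min_contrast,
                 fast_arc_length = as.integer(fast_arc_length),
                 doh_num_octaves = as.integer(doh_num_octaves),
                 doh_metric_threshold = doh_metric_threshold,
                 mser_threshold_delta = mser_threshold_delta,
                 mser_min_area = as.integer(mser_min_area),
                 mser_max_area_frac = mser_max_area_frac,
                 mser_max_variation = mser_max_variation),
            class = "detector_params")
}

fp_df <- function(x = numeric(), y = numeric(), scale = numeric(),
                  strength = numeric(), detector_id = character()) {
  data.frame(x = as.numeric(x), y = as.numeric(y),
             scale = as.numeric(scale), strength = as.numeric(strength),
             detector_id = as.character(detector_id),
             stringsAsFactors = FALSE)
}

gaussian_kernel <- function(sigma, size = NULL) {
  if (is.null(size)) size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  h <- (size - 1L) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  cpp_sepconv2(img, k, k)
}

# Smoothed structure-tensor components: Sobel gradients, Gaussian window of
# length `filter_size` with sigma = filter_size / 3.
structure_tensor <- function(img, filter_size) {
  deriv <- c(-0.5, 0, 0.5)
  smooth <- c(0.25, 0.5, 0.25)
  ix <- cpp_sepconv2(img, deriv, smooth)
  iy <- cpp_sepconv2(img, smooth, deriv)
  w <- gaussian_kernel(filter_size / 3, filter_size)
  list(xx = cpp_sepconv2(ix * ix, w, w),
       yy = cpp_sepconv2(iy * iy, w, w),
       xy = cpp_sepconv2(ix * iy, w, w))
}

# quadratic (parabola) subpixel refinement of response peaks; offsets are
# clamped to half a pixel
subpixel_offset <- function(resp, pts) {
  r <- pts[, 1] + 1L; cc <- pts[, 2] + 1L
  off1d <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    d <- ifelse(abs(den) > 1e-12, 0.5 * (vm - vp) / den, 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  dx <- off1d(resp[cbind(r, cc - 1L)], resp[cbind(r, cc)],
              resp[cbind(r, cc + 1L)])
  dy <- off1d(resp[cbind(r - 1L, cc)], resp[cbind(r, cc)],
              resp[cbind(r + 1L, cc)])
  cbind(dx, dy)
}

corner_points <- function(resp, min_quality, border, id) {
  mx <- max(resp)
  if (!(mx > 0)) return(fp_df())
  pts <- cpp_local_max(resp, 1L, min_quality * mx, border)
  if (nrow(pts) == 0L) return(fp_df())
  off <- subpixel_offset(resp, pts)
  fp_df(x = pts[, 2] + off[, 1], y = pts[, 1] + off[, 2], scale = 1,
        strength = resp[pts + 1L], detector_id = id)
}

#' Harris corner detector
#'
#' Corner response `R = det(M) - k * trace(M)^2` (`k = 0.04`) on a
#' Gaussian-smoothed structure tensor; 3x3 local maxima with
#' `R >= min_quality * max(R)` are returned with `strength = R`.
#'
#' @param img single-channel raster image.
#' @param p [detector_params()].
#' @return feature-point data.frame (empty on constant images or images
#'   smaller than the filter window).
#' @export
detect_harris <- function(img, p = detector_params()) {
  assert_raster(img)
  stopifnot(n_channels(img) == 1L)
  fs <- p$harris_filter_size
  if (nrow(img) < fs || ncol(img) < fs) return(fp_df())
  st <- structure_tensor(img, fs)
  resp <- (st$xx * st$yy - st$xy^2) - 0.04 * (st$xx + st$yy)^2
  corner_points(resp, p$harris_min_quality, fs %/% 2L + 2L, "harris")
}

#' Minimum-eigenvalue (Shi-Tomasi) corner detector
#'
#' Strength is the smaller eigenvalue of the same smoothed structure tensor
#' used by [detect_harris()]; thresholding and non-maximum suppression are
#' identical.
#'
#' @inheritParams detect_harris
#' @return feature-point data.frame.
#' @export
detect_min_eigen <- function(img, p = detector_params()) {
  assert_raster(img)
  stopifnot(n_channels(img) == 1L)
  fs <- p$min_eigen_filter_size
  if (nrow(img) < fs || ncol(img) < fs) return(fp_df())
  st <- structure_tensor(img, fs)
  resp <- (st$xx + st$yy) / 2 - sqrt(((st$xx - st$yy) / 2)^2 + st$xy^2)
  corner_points(resp, p$min_eigen_min_quality, fs %/% 2L + 2L, "min_eigen")
}

#' FAST corner detector
#'
#' Segment test on the 16-pixel Bresenham circle of radius 3: a pixel is a
#' corner when at least `fast_arc_length` contiguous circle pixels are all
#' brighter than centre + t or all darker than centre - t, with
#' `t = fast_min_contrast`. Strength is the maximal contrast preserving
#' cornerness; 3x3 non-maximum suppression is applied.
#'
#' @inheritParams detect_harris
#' @return feature-point data.frame.
#' @export
detect_fast <- function(img, p = detector_params()) {
  assert_raster(img)
  stopifnot(n_channels(img) == 1L)
  if (nrow(img) < 7L || ncol(img) < 7L) return(fp_df())
  score <- cpp_fast_score(img, p$fast_arc_length)
  pts <- cpp_local_max(score, 1L, p$fast_min_contrast, 3L)
  if (nrow(pts) == 0L) return(fp_df())
  off <- subpixel_offset(score, pts)
  fp_df(x = pts[, 2] + off[, 1], y = pts[, 1] + off[, 2], scale = 1,
        strength = score[pts + 1L], detector_id = "fast")
}

#' Determinant-of-Hessian blob detector
#'
#' Scale-normalised determinant of the Gaussian Hessian over a
#' `doh_num_octaves`-octave pyramid (base sigma 1.6, four scale layers per
#' octave, downsampling by two per octave). 3D local maxima in (x, y,
#' scale) above `doh_metric_threshold` are returned; `scale` records the
#' absolute blob sigma in full-resolution pixels.
#'
#' @inheritParams detect_harris
#' @return feature-point data.frame.
#' @export
detect_doh <- function(img, p = detector_params()) {
  assert_raster(img)
  stopifnot(n_channels(img) == 1L)
  if (nrow(img) < 16L || ncol(img) < 16L) return(fp_df())
  sig0 <- 1.6
  # 5 layers per octave at ratio 2^(1/3): the three interior layers of
  # consecutive octaves tile the scale axis without gaps
  nlay <- 5L
  base <- gauss_blur(img, sqrt(sig0^2 - 0.25))   # assume 0.5 px camera blur
  out <- fp_df()
  for (o in seq_len(p$doh_num_octaves)) {
    if (nrow(base) < 16L || ncol(base) < 16L) break
    sig_rel <- sig0 * 2^((0:(nlay - 1L)) / 3)
    layers <- vector("list", nlay)
    resp <- vector("list", nlay)
    for (s in seq_len(nlay)) {
      extra <- sqrt(max(sig_rel[s]^2 - sig0^2, 0))
      L <- gauss_blur(base, extra)
      lxx <- cpp_sepconv2(L, c(1, -2, 1), 1)
      lyy <- cpp_sepconv2(L, 1, c(1, -2, 1))
      lxy <- cpp_sepconv2(L, c(-0.5, 0, 0.5), c(-0.5, 0, 0.5))
      layers[[s]] <- L
      resp[[s]] <- sig_rel[s]^4 * (lxx * lyy - lxy^2)
    }
    for (s in 2:(nlay - 1L)) {
      border <- as.integer(ceiling(2 * sig_rel[s])) + 1L
      pts <- cpp_local_max(resp[[s]], 1L, p$doh_metric_threshold, border)
      if (nrow(pts) == 0L) next
      keep <- logical(nrow(pts))
      for (i in seq_len(nrow(pts))) {
        r <- pts[i, 1] + 1L; cc <- pts[i, 2] + 1L
        v <- resp[[s]][r, cc]
        nb_lo <- resp[[s - 1L]][(r - 1L):(r + 1L), (cc - 1L):(cc + 1L)]
        nb_hi <- resp[[s + 1L]][(r - 1L):(r + 1L), (cc - 1L):(cc + 1L)]
        keep[i] <- v >= max(nb_lo) && v >= max(nb_hi)
      }
      pts <- pts[keep, , drop = FALSE]
      if (nrow(pts) == 0L) next
      stren <- resp[[s]][pts + 1L]
      off <- subpixel_offset(resp[[s]], pts)
      f <- 2^(o - 1L)
      out <- rbind(out, fp_df(x = (pts[, 2] + off[, 1]) * f,
                              y = (pts[, 1] + off[, 2]) * f,
                              scale = sig_rel[s] * f,
                              strength = stren,
                              detector_id = "doh_blob"))
    }
    # next octave: blur to 2*sig0 (in this octave's pixels) and decimate
    nxt <- gauss_blur(base, sqrt((2 * sig0)^2 - sig0^2))
    base <- nxt[seq(1L, nrow(nxt), by = 2L), seq(1L, ncol(nxt), by = 2L)]
  }
  out
}

#' MSER region detector
#'
#' Maximally stable extremal regions found by a quantised threshold sweep
#' with step `mser_threshold_delta` (on the 0-255 scale), run on the image
#' and its inversion so that both bright and dark regions are reported.
#' Stability is the relative area change across one step each way; each
#' stable region is reported as a single feature point at its centroid with
#' `scale = sqrt(area / pi)` and `strength = 1 / stability`.
#'
#' @inheritParams detect_harris
#' @return feature-point data.frame.
#' @export
detect_mser <- function(img, p = detector_params()) {
  assert_raster(img)
  stopifnot(n_channels(img) == 1L)
  nlevels <- as.integer(floor(255 / p$mser_threshold_delta)) + 1L
  max_area <- max(p$mser_min_area,
                  as.integer(p$mser_max_area_frac * length(img)))
  one <- function(m) {
    reg <- cpp_mser(m, nlevels, p$mser_min_area, max_area,
                    p$mser_max_variation, 0.2)
    if (nrow(reg) == 0L) return(fp_df())
    fp_df(x = reg[, 1], y = reg[, 2], scale = sqrt(reg[, 3] / pi),
          strength = 1 / pmax(reg[, 4], 1e-6), detector_id = "mser")
  }
  rbind(one(img), one(1 - img))
}

native_detectors <- c(harris = NA, min_eigen = NA, fast = NA,
                      doh_blob = NA, mser = NA)

# registry for external adapter detectors ("adapter:<name>")
.adapters <- new.env(parent = emptyenv())

#' Register an adapter detector
#'
#' Plugs an external feature detector into the combined scheme under the id
#' `adapter:<name>`. The function must accept `(img, p)` and return a
#' feature-point data.frame like the native detectors; its `detector_id`
#' column is overwritten with the adapter id.
#'
#' @param name adapter name (e.g. `"brisk"`).
#' @param fun detector function, or `NULL` to unregister.
#' @export
register_adapter <- function(name, fun) {
  if (is.null(fun)) {
    if (exists(name, envir = .adapters)) rm(list = name, envir = .adapters)
  } else {
    stopifnot(is.function(fun))
    assign(name, fun, envir = .adapters)
  }
  invisible(name)
}

run_detector <- function(id, img, p) {
  fps <- switch(id,
    harris = detect_harris(img, p),
    min_eigen = detect_min_eigen(img, p),
    fast = detect_fast(img, p),
    doh = ,
    doh_blob = detect_doh(img, p),
    mser = detect_mser(img, p),
    {
      if (!startsWith(id, "adapter:"))
        stop("unknown detector id: ", id, call. = FALSE)
      nm <- sub("^adapter:", "", id)
      if (!exists(nm, envir = .adapters))
        stop("adapter not registered: ", nm, call. = FALSE)
      get(nm, envir = .adapters)(img, p)
    })
  if (nrow(fps)) fps$detector_id <- if (id == "doh") "doh_blob" else id
  fps
}

#' Combined multi-detector feature extraction
#'
#' Runs every detector in `detector_set` and merges their outputs into one
#' feature-point list. Near-duplicate points from different detectors
#' (closer than 1 px with a scale ratio below 1.2) are merged, keeping the
#' point of higher strength; the surviving point keeps its detector_id.
#'
#' @param img single-channel raster image.
#' @param detector_set character vector of detector ids from
#'   `harris, min_eigen, fast, doh, mser, adapter:<name>`.
#' @param p [detector_params()].
#' @return feature-point data.frame.
#' @export
detect_combined <- function(img,
                            detector_set = c("harris", "min_eigen", "fast",
                                             "doh", "mser"),
                            p = detector_params()) {
  stopifnot(length(detector_set) >= 1L)
  fps <- do.call(rbind, lapply(detector_set, run_detector, img = img, p = p))
  if (is.null(fps) || nrow(fps) == 0L) return(fp_df())
  ord <- order(-fps$strength, fps$y, fps$x)
  fps <- fps[ord, , drop = FALSE]
  keep <- cpp_dedupe(fps$x, fps$y, fps$scale, 1.0, 1.2)
  out <- fps[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep the strongest feature points
#'
#' Top-`n` points by strength; ties are broken by (y, x) lexicographic
#' order for determinism. With `n` at or above the list length the full
#' list is returned.
#'
#' @param fps feature-point data.frame.
#' @param n number of points to keep (>= 0).
#' @return feature-point data.frame with at most `n` rows.
#' @export
strongest <- function(fps, n) {
  stopifnot(n >= 0)
  if (n == 0L || nrow(fps) == 0L)
    return(fps[integer(0), , drop = FALSE])
  ord <- order(-fps$strength, fps$y, fps$x)
  out <- fps[ord[seq_len(min(n, nrow(fps)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
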