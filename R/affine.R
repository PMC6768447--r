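# ---------------------------------------------------------------------------
# 2D affine transforms, stored as a 2x3 matrix mapping FLU (x, y) to VIS
# (x', y'): [x'; y'] = A %*% [x; y] + t, in 0-based pixel-centre
# coordinates.
# ---------------------------------------------------------------------------

#' Construct an affine transform
#'
#' @param m 2x3 numeric matrix `[A | t]` mapping source (FLU) to target
#'   (VIS) coordinates. The 2x2 linear part must be non-degenerate
#'   (`|det| > 1e-8`).
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 2L, ncol(m) == 3L, all(is.finite(m)))
  if (abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) <= 1e-8)
    stop("degenerate affine transform", call. = FALSE)
  structure(list(matrix = m), class = "affine_transform")
}

#' Identity transform
#' @export
affine_identity <- function() {
  affine_transform(cbind(diag(2), c(0, 0)))
}

#' Build an affine transform from pose parameters
#'
#' Composes `rotate(rotation) %*% [scale_x, shear * scale_y; 0, scale_y]`
#' followed by the translation, the same parameterisation that
#' [decompose_affine()] recovers.
#'
#' @param scale_x,scale_y axis scale factors.
#' @param rotation rotation in degrees (counter-clockwise in the x-right,
#'   y-down image frame).
#' @param shear unitless shear.
#' @param tx,ty translation in pixels.
#' @return `affine_transform`.
#' @export
make_affine <- function(scale_x = 1, scale_y = scale_x, rotation = 0,
                        shear = 0, tx = 0, ty = 0) {
  th <- rotation * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- matrix(c(scale_x, 0, shear * scale_y, scale_y), 2, 2)
  affine_transform(cbind(r %*% s, c(tx, ty)))
}

#' Apply a transform to point coordinates
#'
#' @param t `affine_transform`.
#' @param xy n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
affine_apply <- function(t, xy) {
  stopifnot(inherits(t, "affine_transform"))
  if (is.null(dim(xy))) xy <- matrix(xy, 1L, 2L)
  sweep(xy %*% t(t$matrix[, 1:2]), 2L, t$matrix[, 3], `+`)
}

#' Invert a transform
#' @param t `affine_transform`.
#' @return `affine_transform` mapping target back to source.
#' @export
affine_invert <- function(t) {
  a <- t$matrix[, 1:2]
  ai <- solve(a)
  affine_transform(cbind(ai, -ai %*% t$matrix[, 3]))
}

#' Compose two transforms
#' @param t1,t2 `affine_transform`s.
#' @return transform equivalent to applying `t2` first, then `t1`.
#' @export
affine_compose <- function(t1, t2) {
  a <- t1$matrix[, 1:2] %*% t2$matrix[, 1:2]
  b <- t1$matrix[, 1:2] %*% t2$matrix[, 3] + t1$matrix[, 3]
  affine_transform(cbind(a, b))
}

#' Decompose an affine transform into pose parameters
#'
#' QR-style decomposition: the rotation angle comes from the polar factor
#' of the 2x2 part (first column direction), scales from the triangular
#' remainder. Recomposition via [make_affine()] reproduces the matrix to
#' 1e-9.
#'
#' @param t `affine_transform`.
#' @return list with `scale_x`, `scale_y`, `rotation` (degrees), `shear`,
#'   `tx`, `ty`.
#' @export
decompose_affine <- function(t) {
  stopifnot(inherits(t, "affine_transform"))
  a <- t$matrix[, 1:2]
  th <- atan2(a[2, 1], a[1, 1])
  rinv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  s <- rinv %*% a                # upper triangular: s[2,1] == 0 exactly
  list(scale_x = s[1, 1], scale_y = s[2, 2], rotation = th * 180 / pi,
       shear = s[1, 2] / s[2, 2], tx = t$matrix[1, 3], ty = t$matrix[2, 3])
}

#' @export
print.affine_transform <- function(x, ...) {
  d <- decompose_affine(x)
  cat(sprintf(paste0("<affine_transform scale (%.3f, %.3f), ",
                     "rotation %.2f deg, shear %.3f, translation ",
                     "(%.1f, %.1f) px>\n"),
              d$scale_x, d$scale_y, d$rotation, d$shear, d$tx, d$ty))
  invisible(x)
}

#' Admissibility bounds for estimated transforms
#'
#' Min/max bounds on the decomposed scaling, rotation and translation of a
#' registration transform; estimates outside the bounds are treated as
#' registration failure. Defaults admit the VIS/FLU camera-resolution
#' ratios of typical phenotyping installations (around 1.25-1.67) with
#' headroom.
#'
#' @param scale_min,scale_max admissible axis scales (defaults 0.4, 2.5).
#' @param rotation_max_abs maximal absolute rotation in degrees (20).
#' @param translation_max maximal translation as a fraction of the VIS
#'   image diagonal (0.5).
#' @return list of class `admissibility_bounds`.
#' @export
admissibility_bounds <- function(scale_min = 0.4, scale_max = 2.5,
                                 rotation_max_abs = 20,
                                 translation_max = 0.5) {
  stopifnot(scale_min > 0, scale_min < scale_max, rotation_max_abs >= 0,
            translation_max >= 0)
  structure(list(scale_min = scale_min, scale_max = scale_max,
                 rotation_max_abs = rotation_max_abs,
                 translation_max = translation_max),
            class = "admissibility_bounds")
}

#' Test a transform against admissibility bounds
#'
#' @param t `affine_transform`.
#' @param b [admissibility_bounds()].
#' @param vis_diag VIS image diagonal in pixels (scales the translation
#'   bound).
#' @return `TRUE` iff both scales, the rotation and the translation length
#'   are within bounds.
#' @export
is_admissible <- function(t, b = admissibility_bounds(), vis_diag) {
  d <- decompose_affine(t)
  d$scale_x >= b$scale_min && d$scale_x <= b$scale_max &&
    d$scale_y >= b$scale_min && d$scale_y <= b$scale_max &&
    abs(d$rotation) <= b$rotation_max_abs &&
    sqrt(d$tx^2 + d$ty^2) <= b$translation_max * vis_diag
}

#' Warp an image into the target frame
#'
#' Inverse-mapped resampling: output pixel (x, y) takes the source value at
#' `t^{-1}(x, y)`. Bilinear interpolation for images, nearest-neighbour for
#' masks; pixels mapping outside the source are 0 (`FALSE` for masks).
#'
#' @param img raster image (1 or 3 channels).
#' @param t `affine_transform` mapping source to target.
#' @param out_width,out_height output frame size in pixels.
#' @return warped raster image.
#' @export
warp <- function(img, t, out_width, out_height) {
  assert_raster(img)
  tinv <- affine_invert(t)$matrix
  w1 <- function(ch) {
    out <- cpp_affine_warp(ch, tinv, out_height, out_width, TRUE, 0)
    out[out < 0] <- 0; out[out > 1] <- 1
    out
  }
  if (n_channels(img) == 1L) return(w1(img))
  out <- array(0, c(out_height, out_width, 3L))
  for (k in 1:3) out[, , k] <- w1(img[, , k])
  out
}

#' Warp a binary mask (nearest-neighbour)
#'
#' @param mask logical matrix.
#' @inheritParams warp
#' @return logical matrix of the requested size.
#' @export
warp_mask <- function(mask, t, out_width, out_height) {
  stopifnot(is.logical(mask))
  tinv <- affine_invert(t)$matrix
  cpp_affine_warp(mask * 1, tinv, out_height, out_width, FALSE, 0) > 0.5
}

#' Serialise a transform (with decomposition) to JSON
#' @param t `affine_transform`.
#' @param path optional path; when `NULL` the JSON string is returned.
#' @export
affine_to_json <- function(t, path = NULL) {
  obj <- list(matrix = t$matrix, decomposition = decompose_affine(t))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a transform from JSON written by [affine_to_json()]
#' @param path JSON path.
#' @export
affine_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  m <- obj$matrix
  if (!is.matrix(m)) m <- do.call(rbind, m)
  affine_transform(m)
}
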