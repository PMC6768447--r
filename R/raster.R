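#' @useDynLib phytoreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Raster images are plain numeric matrices (1 channel, rows = y, cols = x)
# or h x w x 3 arrays, with pixel values in [0, 1]. Coordinates used
# throughout the package are 0-based pixel centres: x = column in
# [0, width), y = row in [0, height). This convention is stated here once
# and used by every module.
# ---------------------------------------------------------------------------

#' Validate a raster image
#'
#' A raster image is a numeric matrix (single channel) or a
#' `height x width x 3` array with finite values in `[0, 1]`.
#'
#' @param img object to validate.
#' @param arg name used in error messages.
#' @return `img`, invisibly, if valid; otherwise an error is thrown.
#' @export
assert_raster <- function(img, arg = "img") {
  if (!is.numeric(img)) stop(arg, " must be numeric", call. = FALSE)
  d <- dim(img)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop(arg, " must be a matrix or an h x w x 3 array", call. = FALSE)
  if (d[1] < 1L || d[2] < 1L) stop(arg, " has empty dimensions", call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop(arg, " contains non-finite pixel values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop(arg, " has pixel values outside [0, 1]", call. = FALSE)
  invisible(img)
}

#' Number of channels of a raster image
#' @param img raster image.
#' @return 1 or 3.
#' @export
n_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3] else 1L

#' Image width and height in pixels
#' @param img raster image or binary mask.
#' @return integer vector `c(width, height)`.
#' @export
img_size <- function(img) c(ncol0(img), nrow0(img))

nrow0 <- function(img) dim(img)[1]
ncol0 <- function(img) dim(img)[2]

#' Read an image file
#'
#' Reads PNG or TIFF (8- or 16-bit, grey or RGB). An alpha channel, if
#' present, is dropped. Values are returned in `[0, 1]`.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return raster image (matrix or h x w x 3 array).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3] == 4L) img <- img[, , 1:3, drop = FALSE]
    if (d[3] == 2L) img <- img[, , 1L]          # grey + alpha
    if (!is.na(dim(img)[3]) && dim(img)[3] == 1L) img <- img[, , 1L]
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  assert_raster(img, "image file")
}

#' Write an image file
#'
#' @param img raster image.
#' @param path output path (`.png` or `.tif(f)`).
#' @export
write_image <- function(img, path) {
  assert_raster(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read a binary mask from a single-channel PNG (0/255 convention)
#' @param path PNG path.
#' @return logical matrix, `TRUE` = plant.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (n_channels(img) == 3L) img <- to_greyscale(img)
  img >= 0.5
}

#' Write a binary mask as a single-channel PNG
#' @param mask logical matrix.
#' @param path PNG path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 2L)
  png::writePNG(mask * 1, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# pre-processing operations
# ---------------------------------------------------------------------------

#' Convert to greyscale
#'
#' Luminance-weighted channel combination (weights 0.299, 0.587, 0.114).
#' Idempotent on single-channel input.
#'
#' @param img raster image with 1 or 3 channels.
#' @return single-channel raster image.
#' @export
to_greyscale <- function(img) {
  assert_raster(img)
  if (n_channels(img) == 1L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Colour-edge transform
#'
#' Per-channel spatial gradient magnitude (3x3 Sobel operator), reduced
#' across channels by the maximum and rescaled so the output maximum is 1
#' (an all-zero gradient image stays all-zero). Invariant under addition of
#' a constant to all channels, which suppresses the smooth vertical
#' illumination gradient of visible-light background regions and makes
#' fluorescence and visible-light images structurally more similar.
#'
#' @param img raster image (1 or 3 channels).
#' @return single-channel edge-magnitude image in `[0, 1]`.
#' @export
colour_edge <- function(img) {
  assert_raster(img)
  chans <- if (n_channels(img) == 1L) list(img) else
    lapply(1:3, function(k) img[, , k])
  deriv <- c(-0.5, 0, 0.5)
  smooth <- c(0.25, 0.5, 0.25)
  mags <- lapply(chans, function(ch) {
    gx <- cpp_sepconv2(ch, deriv, smooth)
    gy <- cpp_sepconv2(ch, smooth, deriv)
    sqrt(gx^2 + gy^2)
  })
  out <- Reduce(pmax, mags)
  m <- max(out)
  if (m > 0) out <- out / m
  out
}

#' Mask an image
#'
#' Sets pixels outside the plant mask to `fill`; an ideal background
#' filtering when the mask is a manual ("ground truth") segmentation.
#'
#' @param img raster image.
#' @param mask logical matrix of the same width/height, `TRUE` = keep.
#' @param fill replacement value for background pixels (default 0).
#' @return raster image of the same shape.
#' @export
apply_mask <- function(img, mask, fill = 0) {
  assert_raster(img)
  stopifnot(is.logical(mask))
  if (!all(dim(mask) == dim(img)[1:2]))
    stop("mask dimensions do not match image", call. = FALSE)
  if (n_channels(img) == 1L) {
    img[!mask] <- fill
  } else {
    for (k in 1:3) {
      ch <- img[, , k]; ch[!mask] <- fill; img[, , k] <- ch
    }
  }
  img
}

#' Crop rectangle
#'
#' Half-open pixel rectangle `[x0, x1) x [y0, y1)`, 0-based.
#'
#' @param x0,y0 inclusive top-left corner.
#' @param x1,y1 exclusive bottom-right corner.
#' @return object of class `crop_rect`.
#' @export
crop_rect <- function(x0, y0, x1, y1) {
  stopifnot(x0 >= 0, y0 >= 0, x1 > x0, y1 > y0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "crop_rect")
}

#' @export
print.crop_rect <- function(x, ...) {
  cat(sprintf("<crop_rect [%d,%d) x [%d,%d), %d x %d px>\n",
              x$x0, x$x1, x$y0, x$y1, x$x1 - x$x0, x$y1 - x$y0))
  invisible(x)
}

#' Maximum bounding box of a set of plant masks
#'
#' The smallest rectangle containing every `TRUE` pixel of every mask
#' (e.g. all pre-segmented plants of the same age class), expanded by
#' `margin` pixels and clipped to the image bounds. Used for cropping all
#' images of that class to a common plant region.
#'
#' @param masks list of logical matrices, all of the same dimensions.
#' @param margin expansion in pixels (default 0).
#' @return a [crop_rect()].
#' @export
max_bounding_box <- function(masks, margin = 0) {
  if (is.logical(masks) && !is.null(dim(masks))) masks <- list(masks)
  stopifnot(length(masks) >= 1L, margin >= 0)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!all(dim(m) == d)) stop("masks have differing dimensions", call. = FALSE)
  any_true <- Reduce(`|`, masks)
  if (!any(any_true)) stop("no TRUE pixel in any mask", call. = FALSE)
  idx <- which(any_true, arr.ind = TRUE)
  r0 <- min(idx[, 1]) - 1L; r1 <- max(idx[, 1]) - 1L
  c0 <- min(idx[, 2]) - 1L; c1 <- max(idx[, 2]) - 1L
  crop_rect(max(0L, c0 - margin), max(0L, r0 - margin),
            min(d[2], c1 + 1L + margin), min(d[1], r1 + 1L + margin))
}

#' Crop an image or mask to a rectangle
#'
#' @param img raster image or logical mask.
#' @param rect a [crop_rect()], fully inside the image.
#' @return cropped image; output pixel (0,0) equals input pixel
#'   `(rect$x0, rect$y0)`.
#' @export
crop <- function(img, rect) {
  stopifnot(inherits(rect, "crop_rect"))
  d <- dim(img)
  if (rect$x1 > d[2] || rect$y1 > d[1])
    stop("crop rectangle outside image", call. = FALSE)
  rows <- (rect$y0 + 1L):rect$y1
  cols <- (rect$x0 + 1L):rect$x1
  if (length(d) == 3L) img[rows, cols, , drop = FALSE] else
    img[rows, cols, drop = FALSE]
}

#' Render an image pair variant
#'
#' Applies the pre-processing factors of the benchmark grid to one image:
#' optional ideal background filtering with a manual mask, greyscale or
#' colour-edge rendering, and optional cropping.
#'
#' @param img raster image.
#' @param mode `"original"` or `"masked"` (requires `mask`).
#' @param render `"greyscale"` or `"colour_edge"`.
#' @param mask logical matrix, required when `mode = "masked"`.
#' @param rect optional [crop_rect()]; `NULL` keeps the full frame.
#' @return single-channel raster image.
#' @export
preprocess_image <- function(img, mode = c("original", "masked"),
                             render = c("greyscale", "colour_edge"),
                             mask = NULL, rect = NULL) {
  mode <- match.arg(mode)
  render <- match.arg(render)
  if (mode == "masked") {
    if (is.null(mask)) stop("mode = 'masked' requires a mask", call. = FALSE)
    img <- apply_mask(img, mask)
  }
  out <- if (render == "colour_edge") colour_edge(img) else to_greyscale(img)
  if (!is.null(rect)) out <- crop(out, rect)
  out
}
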