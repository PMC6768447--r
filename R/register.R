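# ---------------------------------------------------------------------------
# End-to-end FLU -> VIS registration of one image pair.
# ---------------------------------------------------------------------------

#' Registration pipeline configuration
#'
#' Bundles the pre-processing choice and all stage parameters of
#' [register_pair()].
#'
#' @param detector a single detector id (`harris`, `min_eigen`, `fast`,
#'   `doh`, `mser`, `adapter:<name>`) or `"combined"`.
#' @param detector_set detectors merged by the combined scheme.
#' @param mode `"original"` (unfiltered) or `"masked"` (ideal background
#'   filtering with the supplied masks).
#' @param render `"greyscale"` or `"colour_edge"`.
#' @param framing `"full"` or `"cropped"` (crop to the plant bounding box).
#' @param crop_margin bounding-box margin in pixels.
#' @param detector_params,match_params,ransac_params,bounds stage
#'   parameter objects.
#' @param flu_mask_threshold intensity threshold used to derive a plant
#'   mask from the FLU image when none is supplied.
#' @return list of class `reg_config`.
#' @export
reg_config <- function(detector = "combined",
                       detector_set = c("harris", "min_eigen", "fast",
                                        "doh", "mser"),
                       mode = c("original", "masked"),
                       render = c("colour_edge", "greyscale"),
                       framing = c("full", "cropped"),
                       crop_margin = 0L,
                       detector_params = phytoreg::detector_params(),
                       match_params = phytoreg::match_params(),
                       ransac_params = phytoreg::ransac_params(),
                       bounds = admissibility_bounds(),
                       flu_mask_threshold = 0.1) {
  structure(list(detector = detector, detector_set = detector_set,
                 mode = match.arg(mode), render = match.arg(render),
                 framing = match.arg(framing),
                 crop_margin = as.integer(crop_margin),
                 detector_params = detector_params,
                 match_params = match_params,
                 ransac_params = ransac_params,
                 bounds = bounds,
                 flu_mask_threshold = flu_mask_threshold),
            class = "reg_config")
}

detect_with <- function(img, config) {
  if (identical(config$detector, "combined"))
    detect_combined(img, config$detector_set, config$detector_params)
  else
    run_detector(config$detector, img, config$detector_params)
}

failed_result <- function(counts) {
  structure(list(transform = NULL, inliers = NULL, counts = counts,
                 success = FALSE), class = "registration_result")
}

#' Register a FLU/VIS image pair
#'
#' Chains the full pipeline: pre-processing (masking, greyscale or
#' colour-edge rendering, optional bounding-box cropping), feature
#' detection with the configured detector(s), descriptor extraction,
#' putative matching, RANSAC affine estimation and admissibility
#' validation. The estimated transform maps FLU coordinates into the VIS
#' frame. Feature coordinates are mapped back to the full-size frames
#' before estimation when cropping was applied, so the transform always
#' relates the original images.
#'
#' Failure to find enough correspondences is reported as
#' `success = FALSE`, not as an error.
#'
#' @param flu,vis raster images (fluorescence and visible light).
#' @param config [reg_config()].
#' @param flu_mask,vis_mask optional logical plant masks (required for
#'   `mode = "masked"` on the VIS side; the FLU mask is derived from
#'   intensity when absent).
#' @param flu_rect,vis_rect optional [crop_rect()]s for
#'   `framing = "cropped"`; computed from the masks when absent.
#' @return object of class `registration_result`: `transform`
#'   (`affine_transform` or `NULL`), `inliers` (match data.frame with
#'   full-frame coordinates), `counts` (named list `n_fp_vis`, `n_fp_flu`,
#'   `n_putative`, `n_selected`) and `success`.
#' @export
register_pair <- function(flu, vis, config = reg_config(),
                          flu_mask = NULL, vis_mask = NULL,
                          flu_rect = NULL, vis_rect = NULL) {
  assert_raster(flu, "flu"); assert_raster(vis, "vis")
  counts <- list(n_fp_vis = 0L, n_fp_flu = 0L, n_putative = 0L,
                 n_selected = 0L)
  if (config$mode == "masked" && is.null(vis_mask))
    stop("mode = 'masked' requires vis_mask", call. = FALSE)
  if (is.null(flu_mask) &&
      (config$mode == "masked" || config$framing == "cropped"))
    flu_mask <- flu_plant_mask(flu, config$flu_mask_threshold)
  if (config$framing == "cropped") {
    if (is.null(vis_rect)) {
      if (is.null(vis_mask))
        stop("framing = 'cropped' requires vis_mask or vis_rect",
             call. = FALSE)
      vis_rect <- max_bounding_box(list(vis_mask), config$crop_margin)
    }
    if (is.null(flu_rect)) {
      if (!any(flu_mask)) return(failed_result(counts))
      flu_rect <- max_bounding_box(list(flu_mask), config$crop_margin)
    }
  } else {
    flu_rect <- vis_rect <- NULL
  }
  pre_f <- preprocess_image(flu, config$mode, config$render,
                            mask = flu_mask, rect = flu_rect)
  pre_v <- preprocess_image(vis, config$mode, config$render,
                            mask = vis_mask, rect = vis_rect)
  fp_f <- detect_with(pre_f, config)
  fp_v <- detect_with(pre_v, config)
  counts$n_fp_flu <- nrow(fp_f)
  counts$n_fp_vis <- nrow(fp_v)
  if (nrow(fp_f) == 0L || nrow(fp_v) == 0L) return(failed_result(counts))
  d_f <- extract_descriptors(pre_f, fp_f)
  d_v <- extract_descriptors(pre_v, fp_v)
  pairs <- match_features(d_f, d_v, config$match_params)
  counts$n_putative <- nrow(pairs)
  if (nrow(pairs) < 3L) return(failed_result(counts))
  # putative coordinates, mapped back to the full-size frames
  src <- cbind(fp_f$x[pairs$index_a], fp_f$y[pairs$index_a])
  dst <- cbind(fp_v$x[pairs$index_b], fp_v$y[pairs$index_b])
  if (!is.null(flu_rect)) src <- sweep(src, 2L, c(flu_rect$x0, flu_rect$y0), `+`)
  if (!is.null(vis_rect)) dst <- sweep(dst, 2L, c(vis_rect$x0, vis_rect$y0), `+`)
  est <- tryCatch(
    estimate_affine_ransac(src, dst, config$ransac_params),
    error = function(e) NULL)
  if (is.null(est)) return(failed_result(counts))
  counts$n_selected <- length(est$inliers)
  vis_diag <- sqrt(nrow(vis)^2 + ncol(vis)^2)
  admissible <- is_admissible(est$transform, config$bounds, vis_diag)
  success <- admissible && counts$n_selected >= 3L
  inl <- pairs[est$inliers, , drop = FALSE]
  inl$x_flu <- src[est$inliers, 1]; inl$y_flu <- src[est$inliers, 2]
  inl$x_vis <- dst[est$inliers, 1]; inl$y_vis <- dst[est$inliers, 2]
  rownames(inl) <- NULL
  structure(list(transform = est$transform, inliers = inl,
                 counts = counts, success = success),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result ",
      if (x$success) "SUCCESS" else "FAILURE", ">\n", sep = "")
  cat(sprintf("  FPs: VIS %d, FLU %d; putative %d; selected %d\n",
              x$counts$n_fp_vis, x$counts$n_fp_flu,
              x$counts$n_putative, x$counts$n_selected))
  if (!is.null(x$transform)) print(x$transform)
  invisible(x)
}
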