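# ---------------------------------------------------------------------------
# Evaluation framework: success rate, overlap ratio, and the full
# factorial pre-processing x detector benchmark grid.
# ---------------------------------------------------------------------------

#' Registration success rate
#'
#' `SR = n_success / n_total`: the fraction of attempted image pairs for
#' which registration produced an admissible transform.
#'
#' @param n_success number of successful registrations.
#' @param n_total total number of attempted pairs (>= 1).
#' @return success rate in `[0, 1]`.
#' @export
success_rate <- function(n_success, n_total) {
  if (n_total < 1) stop("success rate undefined for n_total < 1",
                        call. = FALSE)
  stopifnot(n_success >= 0, n_success <= n_total)
  n_success / n_total
}

#' Overlap ratio of a registered pair
#'
#' `OR = a_r / a`: the fraction of the ground-truth plant area in the VIS
#' image that is covered by the FLU plant region after warping it into the
#' VIS frame with the registration transform (nearest-neighbour warp of
#' the FLU mask).
#'
#' @param flu_mask logical FLU plant mask.
#' @param t `affine_transform` mapping FLU to VIS coordinates.
#' @param vis_gt_mask logical ground-truth VIS plant mask with at least
#'   one `TRUE` pixel.
#' @return overlap ratio in `[0, 1]`.
#' @export
overlap_ratio <- function(flu_mask, t, vis_gt_mask) {
  stopifnot(is.logical(flu_mask), is.logical(vis_gt_mask))
  a <- sum(vis_gt_mask)
  if (a == 0L) stop("overlap ratio undefined: empty ground-truth mask",
                    call. = FALSE)
  warped <- warp_mask(flu_mask, t, ncol(vis_gt_mask), nrow(vis_gt_mask))
  sum(warped & vis_gt_mask) / a
}

#' Derive a plant mask from a FLU image
#'
#' Fluorescence images mainly show chlorophyll-containing plant structures
#' on a near-black background, so a simple intensity threshold (maximum
#' over channels) recovers the plant region; connected components smaller
#' than `min_component` pixels are dropped as noise.
#'
#' @param flu raster image (1 or 3 channels).
#' @param threshold intensity threshold in `[0, 1]` (default 0.1).
#' @param min_component minimal component area in pixels (default 20).
#' @return logical plant mask.
#' @export
flu_plant_mask <- function(flu, threshold = 0.1, min_component = 20L) {
  assert_raster(flu)
  intensity <- if (n_channels(flu) == 3L)
    pmax(flu[, , 1], flu[, , 2], flu[, , 3]) else flu
  m <- intensity > threshold
  if (!any(m)) return(m)
  lab <- cpp_label(m)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_component)
  matrix(lab %in% keep, nrow(m), ncol(m))
}

#' Enumerate the benchmark configuration grid
#'
#' Full factorial grid of segmentation (original/manual) x rendering
#' (greyscale/colour-edge) x framing (full/cropped) x detector, in
#' deterministic order. With seven single detectors plus the combined one
#' this yields the 64 = 2 * 2 * (2 * (7 + 1)) configurations of the full
#' evaluation design.
#'
#' @param detectors character vector of detector ids (no duplicates).
#' @return data.frame with columns `segmentation`, `render`, `framing`,
#'   `detector` and a `config_id` label.
#' @export
enumerate_configurations <- function(detectors = c("harris", "min_eigen",
                                                   "fast", "doh", "mser",
                                                   "adapter:brisk",
                                                   "adapter:kaze",
                                                   "combined")) {
  stopifnot(length(detectors) >= 1L)
  if (anyDuplicated(detectors))
    stop("duplicate detector ids in grid", call. = FALSE)
  grid <- expand.grid(detector = detectors,
                      framing = c("full", "cropped"),
                      render = c("greyscale", "colour_edge"),
                      segmentation = c("original", "manual"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("segmentation", "render", "framing", "detector")]
  grid$config_id <- sprintf("%s/%s/%s/%s", grid$segmentation, grid$render,
                            grid$framing, grid$detector)
  grid
}

config_for_record <- function(row, base) {
  cfg <- base
  cfg$detector <- row$detector
  cfg$mode <- if (row$segmentation == "manual") "masked" else "original"
  cfg$render <- if (row$render == "colour_edge") "colour_edge" else "greyscale"
  cfg$framing <- row$framing
  cfg
}

# small deterministic hash mixing the benchmark seed with record identity
record_seed <- function(seed, pair_id, config_id) {
  h <- sum(utf8ToInt(paste(pair_id, config_id, sep = "|")) *
             seq_along(utf8ToInt(paste(pair_id, config_id, sep = "|"))))
  (as.integer(seed) + (h %% 1000003L)) %% .Machine$integer.max
}

#' Run the benchmark grid over a dataset
#'
#' Registers every image pair of the dataset under every configuration of
#' the grid and records the per-pair outcome: feature counts (VIS, FLU),
#' putative and finally selected pair counts, the success flag and - for
#' successful registrations with masks available - the overlap ratio.
#' Every record uses a seed derived deterministically from
#' `(seed, pair_id, config_id)`.
#'
#' @param dataset data.frame manifest with columns `pair_id`, `flu_path`,
#'   `vis_path`, optional `vis_mask_path`, `flu_mask_path`, `group`; or a
#'   list of in-memory pairs (elements `pair_id`, `flu`, `vis`, optional
#'   `flu_mask`, `vis_mask`, `group`).
#' @param grid configuration grid from [enumerate_configurations()].
#' @param config base [reg_config()] supplying stage parameters.
#' @param seed integer master seed.
#' @return data.frame of class `benchmark_records`, one row per
#'   (pair, configuration).
#' @export
run_benchmark <- function(dataset, grid = enumerate_configurations(),
                          config = reg_config(), seed = 0L) {
  pairs <- if (is.data.frame(dataset)) {
    lapply(seq_len(nrow(dataset)), function(i) {
      row <- dataset[i, ]
      p <- list(pair_id = as.character(row$pair_id),
                flu = read_image(row$flu_path),
                vis = read_image(row$vis_path),
                group = if ("group" %in% names(row))
                  as.character(row$group) else "all")
      if ("vis_mask_path" %in% names(row) && nzchar(row$vis_mask_path) &&
          !is.na(row$vis_mask_path))
        p$vis_mask <- read_mask(row$vis_mask_path)
      if ("flu_mask_path" %in% names(row) && nzchar(row$flu_mask_path) &&
          !is.na(row$flu_mask_path))
        p$flu_mask <- read_mask(row$flu_mask_path)
      p
    })
  } else dataset
  recs <- vector("list", length(pairs) * nrow(grid))
  k <- 0L
  for (pr in pairs) {
    if (is.null(pr$group)) pr$group <- "all"
    for (i in seq_len(nrow(grid))) {
      row <- grid[i, ]
      cfg <- config_for_record(row, config)
      cfg$ransac_params$seed <-
        record_seed(seed, pr$pair_id, row$config_id)
      res <- tryCatch(
        register_pair(pr$flu, pr$vis, cfg,
                      flu_mask = pr$flu_mask, vis_mask = pr$vis_mask),
        error = function(e) NULL)
      or_val <- NA_real_
      success <- !is.null(res) && res$success
      if (success && !is.null(pr$vis_mask)) {
        fm <- if (!is.null(pr$flu_mask)) pr$flu_mask else
          flu_plant_mask(pr$flu, cfg$flu_mask_threshold)
        or_val <- overlap_ratio(fm, res$transform, pr$vis_mask)
      }
      cnt <- if (!is.null(res)) res$counts else
        list(n_fp_vis = NA_integer_, n_fp_flu = NA_integer_,
             n_putative = NA_integer_, n_selected = NA_integer_)
      k <- k + 1L
      recs[[k]] <- data.frame(
        pair_id = pr$pair_id, group = pr$group,
        config_id = row$config_id, segmentation = row$segmentation,
        render = row$render, framing = row$framing,
        detector = row$detector,
        n_fp_vis = cnt$n_fp_vis, n_fp_flu = cnt$n_fp_flu,
        n_putative = cnt$n_putative, n_selected = cnt$n_selected,
        success = success, overlap_ratio = or_val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  class(out) <- c("benchmark_records", class(out))
  out
}

#' Summarise benchmark records
#'
#' Per (group, configuration): the success rate over all attempted pairs,
#' the mean overlap ratio over successful registrations, and mean feature
#' counts (VIS, FLU, putative, selected) averaged over *successful*
#' registrations only, matching the reporting convention of
#' detection-statistics tables for successfully registered images.
#'
#' @param records output of [run_benchmark()].
#' @return summary data.frame, one row per (group, config).
#' @export
summarize_benchmark <- function(records) {
  key <- interaction(records$group, records$config_id, drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    s <- r[r$success, , drop = FALSE]
    data.frame(
      group = r$group[1], config_id = r$config_id[1],
      segmentation = r$segmentation[1], render = r$render[1],
      framing = r$framing[1], detector = r$detector[1],
      n_pairs = nrow(r),
      success_rate = success_rate(nrow(s), nrow(r)),
      mean_or = if (nrow(s)) mean(s$overlap_ratio, na.rm = TRUE) else
        NA_real_,
      mean_fp_vis = if (nrow(s)) mean(s$n_fp_vis) else NA_real_,
      mean_fp_flu = if (nrow(s)) mean(s$n_fp_flu) else NA_real_,
      mean_putative = if (nrow(s)) mean(s$n_putative) else NA_real_,
      mean_selected = if (nrow(s)) mean(s$n_selected) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$config_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
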