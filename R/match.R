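# ---------------------------------------------------------------------------
# Descriptor extraction and putative matching. One uniform descriptor is
# used for every detector so that feature lists merged across detectors
# remain mutually matchable.
# ---------------------------------------------------------------------------

#' Matching parameters
#'
#' @param match_threshold maximal accepted squared descriptor distance as a
#'   percent of the largest possible distance (4 for unit-norm vectors);
#'   default 15.
#' @param max_ratio Lowe ratio test bound: best / second-best squared
#'   distance must not exceed this; default 0.75.
#' @param unique when `TRUE` (default) many-to-one collisions are resolved
#'   by keeping only the smallest-distance pair per target point.
#' @return list of class `match_params`.
#' @export
match_params <- function(match_threshold = 15, max_ratio = 0.75,
                         unique = TRUE) {
  stopifnot(match_threshold > 0, match_threshold <= 100,
            max_ratio > 0, max_ratio <= 1, is.logical(unique))
  structure(list(match_threshold = match_threshold, max_ratio = max_ratio,
                 unique = unique), class = "match_params")
}

#' Extract patch descriptors for feature points
#'
#' For each point a square patch of side `4 * max(scale, 2.5)` pixels is
#' bilinearly resampled to a 16x16 grid, split into 4x4 cells, and each
#' cell contributes a 4-bin gradient-orientation histogram weighted by
#' gradient magnitude, giving a 64-vector that is L2-normalised. Constant
#' patches yield the zero vector. Patches reaching outside the image are
#' padded by edge replication.
#'
#' @param img single-channel raster image the points were detected in.
#' @param fps feature-point data.frame (row `i` yields descriptor row `i`).
#' @return numeric matrix with `nrow(fps)` rows and 64 columns.
#' @export
extract_descriptors <- function(img, fps) {
  assert_raster(img)
  stopifnot(n_channels(img) == 1L)
  if (nrow(fps) == 0L) return(matrix(numeric(), 0L, 64L))
  stopifnot(all(fps$x >= 0), all(fps$x < ncol(img)),
            all(fps$y >= 0), all(fps$y < nrow(img)))
  cpp_descriptors(img, fps$x, fps$y, fps$scale)
}

#' Match descriptors between two feature lists
#'
#' Squared-difference (sum of squared differences) nearest-neighbour
#' matching: for each descriptor in `da` the nearest and second-nearest
#' descriptors in `db` are found; a pair is kept when its distance is at
#' most `match_threshold` percent of the maximal possible distance and the
#' best/second-best ratio is at most `max_ratio`. With `unique = TRUE`,
#' several `a` points matching the same `b` point are reduced to the
#' smallest-distance pair. The result is sorted by distance.
#'
#' @param da,db descriptor matrices from [extract_descriptors()].
#' @param p [match_params()].
#' @return data.frame with columns `index_a`, `index_b` (1-based rows of
#'   `da`/`db`), `distance` and `ratio`.
#' @export
match_features <- function(da, db, p = match_params()) {
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      distance = numeric(), ratio = numeric())
  m <- nrow(da); n <- nrow(db)
  if (m == 0L || n == 0L) return(empty)
  d2 <- matrix(rowSums(da^2), m, n) +
    matrix(rowSums(db^2), m, n, byrow = TRUE) - 2 * tcrossprod(da, db)
  d2[d2 < 0] <- 0
  best_j <- max.col(-d2, ties.method = "first")
  best <- d2[cbind(seq_len(m), best_j)]
  if (n >= 2L) {
    d2[cbind(seq_len(m), best_j)] <- Inf
    second <- d2[cbind(seq_len(m), max.col(-d2, ties.method = "first"))]
  } else {
    second <- rep(Inf, m)
  }
  ratio <- ifelse(second > 0, best / second, ifelse(best > 0, 1, 0))
  ratio <- pmin(ratio, 1)
  dmax <- 4                      # max squared distance of unit-norm vectors
  keep <- best <= (p$match_threshold / 100) * dmax & ratio <= p$max_ratio
  out <- data.frame(index_a = seq_len(m)[keep], index_b = best_j[keep],
                    distance = best[keep], ratio = ratio[keep])
  if (p$unique && nrow(out) > 1L) {
    out <- out[order(out$distance, out$index_a), , drop = FALSE]
    out <- out[!duplicated(out$index_b), , drop = FALSE]
  }
  out <- out[order(out$distance, out$index_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}
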