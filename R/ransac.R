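# ---------------------------------------------------------------------------
# RANSAC affine estimation from putative point correspondences.
# ---------------------------------------------------------------------------

#' RANSAC parameters
#'
#' @param max_distance inlier reprojection tolerance in pixels (default
#'   10).
#' @param confidence percent confidence used for the adaptive trial-count
#'   bound (default 95).
#' @param max_num_trials maximal number of minimal-sample trials (default
#'   5000).
#' @param seed integer seed driving all sampling (default 0).
#' @return list of class `ransac_params`.
#' @export
ransac_params <- function(max_distance = 10, confidence = 95,
                          max_num_trials = 5000L, seed = 0L) {
  stopifnot(max_distance > 0, confidence > 0, confidence < 100,
            max_num_trials >= 1L)
  structure(list(max_distance = max_distance, confidence = confidence,
                 max_num_trials = as.integer(max_num_trials),
                 seed = as.integer(seed)), class = "ransac_params")
}

# evaluate expr with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

solve_affine_exact <- function(src, dst) {
  x <- cbind(src, 1)
  b <- tryCatch(solve(x, dst), error = function(e) NULL)
  if (is.null(b)) return(NULL)
  m <- t(b)
  if (any(!is.finite(m))) return(NULL)
  if (abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) <= 1e-8) return(NULL)
  m
}

#' Estimate an affine transform with RANSAC
#'
#' Repeatedly samples 3 non-collinear correspondences, solves the exactly
#' determined affine system and counts correspondences with reprojection
#' error at most `max_distance`; the largest consensus wins. Sampling
#' stops early once the adaptive bound
#' `log(1 - confidence) / log(1 - w^3)` (`w` = current inlier fraction) is
#' reached. The returned transform is a least-squares refit on all
#' inliers. Three pairs are the minimum: fewer raise an error. Fully
#' deterministic given `p$seed`.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) coordinates
#'   (source/FLU and target/VIS).
#' @param p [ransac_params()].
#' @return list with `transform` (`affine_transform`), `inliers` (integer
#'   indices into the rows of `src`), and `errors` (per-pair reprojection
#'   error under the final transform).
#' @export
estimate_affine_ransac <- function(src, dst, p = ransac_params()) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 3L || nrow(dst) != n)
    stop("at least 3 point pairs are required to determine an affine ",
         "transform", call. = FALSE)
  with_seed(p$seed, {
    best_inl <- integer(0)
    needed <- p$max_num_trials
    trial <- 0L
    while (trial < min(needed, p$max_num_trials)) {
      trial <- trial + 1L
      idx <- sample.int(n, 3L)
      s <- src[idx, , drop = FALSE]
      # collinearity: twice the triangle area
      area2 <- abs((s[2, 1] - s[1, 1]) * (s[3, 2] - s[1, 2]) -
                     (s[3, 1] - s[1, 1]) * (s[2, 2] - s[1, 2]))
      if (area2 < 1e-8) next
      m <- solve_affine_exact(s, dst[idx, , drop = FALSE])
      if (is.null(m)) next
      proj <- cbind(src, 1) %*% t(m)
      err <- sqrt(rowSums((proj - dst)^2))
      inl <- which(err <= p$max_distance)
      if (length(inl) > length(best_inl)) {
        best_inl <- inl
        w <- length(inl) / n
        if (w > 0 && w < 1) {
          bound <- log(1 - p$confidence / 100) / log(1 - w^3)
          needed <- max(trial, ceiling(bound))
        } else if (w >= 1) {
          needed <- trial
        }
      }
    }
    if (length(best_inl) < 3L)
      stop("degenerate geometry: no valid minimal sample found",
           call. = FALSE)
    # local optimisation on the consensus set: a plain least-squares refit
    # would let marginal pseudo-inliers near the distance tolerance bias
    # the transform, so the refit is robustified - three Huber-weighted
    # iterations followed by an iterated trimmed refit on the best half of
    # the residuals (at least 12 pairs)
    xi <- cbind(src[best_inl, , drop = FALSE], 1)
    yi <- dst[best_inl, , drop = FALSE]
    b <- qr.solve(xi, yi)
    for (it in 1:3) {
      ri <- sqrt(rowSums((xi %*% b - yi)^2))
      s <- max(1.4826 * stats::median(ri), 0.3)
      w <- pmin(1, 1.5 * s / pmax(ri, 1e-12))
      sw <- sqrt(w)
      b <- qr.solve(xi * sw, yi * sw)
    }
    for (it in 1:10) {
      ri <- sqrt(rowSums((xi %*% b - yi)^2))
      k <- max(12L, ceiling(0.5 * length(ri)))
      if (k >= length(ri)) break
      keep <- order(ri)[seq_len(k)]
      b2 <- qr.solve(xi[keep, , drop = FALSE], yi[keep, , drop = FALSE])
      conv <- max(abs(b2 - b)) < 1e-9
      b <- b2
      if (conv) break
    }
    m <- t(b)
    tr <- affine_transform(m)
    proj <- cbind(src, 1) %*% t(m)
    err <- sqrt(rowSums((proj - dst)^2))
    # refit can move individual pairs across the tolerance; re-evaluate
    inl <- which(err <= p$max_distance)
    if (length(inl) < 3L) inl <- best_inl
    list(transform = tr, inliers = inl, errors = err)
  })
}
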