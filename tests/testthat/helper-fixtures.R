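# Programmatic fixtures and independent oracles used across the suite.

# white axis-aligned square on black background
square_image <- function(size = 64L, lo = 16L, hi = 48L, fg = 1, bg = 0) {
  img <- matrix(bg, size, size)
  img[lo:hi, lo:hi] <- fg
  img
}

# isotropic Gaussian blob, amplitude 1, centred at (cx, cy) (0-based)
gaussian_blob <- function(size = 64L, cx = (size - 1) / 2,
                          cy = (size - 1) / 2, sigma = 4) {
  xs <- 0:(size - 1)
  m <- exp(-outer((xs - cy)^2, (xs - cx)^2, `+`) / (2 * sigma^2))
  m / max(m)
}

disc_mask <- function(w, h, cx, cy, r) {
  outer((0:(h - 1) - cy)^2, (0:(w - 1) - cx)^2, `+`) <= r^2
}

# --- independent oracles ----------------------------------------------------

# brute-force structure tensor at one pixel (0-based x, y): Sobel gradients
# computed explicitly, Gaussian window accumulated pixel by pixel.
oracle_structure_tensor <- function(img, x, y, filter_size) {
  h <- nrow(img); w <- ncol(img)
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  px <- function(yy, xx) img[cl(yy + 1L, h), cl(xx + 1L, w)]
  grad <- function(xx, yy) {
    gx <- (px(yy - 1, xx + 1) + 2 * px(yy, xx + 1) + px(yy + 1, xx + 1) -
             px(yy - 1, xx - 1) - 2 * px(yy, xx - 1) - px(yy + 1, xx - 1)) / 8
    gy <- (px(yy + 1, xx - 1) + 2 * px(yy + 1, xx) + px(yy + 1, xx + 1) -
             px(yy - 1, xx - 1) - 2 * px(yy - 1, xx) - px(yy - 1, xx + 1)) / 8
    c(gx, gy)
  }
  half <- (filter_size - 1L) / 2
  sigma <- filter_size / 3
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  m <- matrix(0, 2, 2)
  for (dy in -half:half)
    for (dx in -half:half) {
      g <- grad(x + dx, y + dy)
      m <- m + k[dy + half + 1] * k[dx + half + 1] * (g %o% g)
    }
  m
}

# exhaustive FAST segment test at (x, y): enumerate all 16 arc start
# positions explicitly.
oracle_fast_test <- function(img, x, y, t, arc = 9L) {
  dx <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
  dy <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
  v <- img[y + 1L, x + 1L]
  circ <- img[cbind(y + dy + 1L, x + dx + 1L)]
  for (s in 1:16) {
    idx <- ((s - 1L + 0:(arc - 1L)) %% 16L) + 1L
    if (all(circ[idx] > v + t) || all(circ[idx] < v - t)) return(TRUE)
  }
  FALSE
}

# tiny identity-like scene used by several integration tests
quick_scene <- function(seed = 5L, transform = NULL,
                        profile = species_profile("rosette_top")) {
  if (is.null(transform))
    transform <- with_test_seed(seed, sample_transform(profile = profile))
  generate_scene(profile, transform, seed = seed)
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
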