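# Synthetic glyph source pool.
#
# A seeded, programmatic stand-in for a labeled handwritten-digit image
# source: each of the 10 digit classes is drawn as a set of stroke polylines
# on a 28x28 grid, with per-sample random affine jitter (rotation, scale,
# shear, translation) and stroke-width variation, rendered with an
# anti-aliased distance-to-stroke profile.  Foreground (the glyph) is bright
# on a zero background, as in the classic digit datasets.

circle_pts <- function(cx, cy, rx, ry, from = 0, to = 2 * pi, n = 20) {
  t <- seq(from, to, length.out = n)
  cbind(cx + rx * cos(t), cy + ry * sin(t))
}

# Stroke polylines per digit class, in [0,1]^2 with y pointing down.
glyph_strokes <- function(digit) {
  switch(as.character(digit),
    "0" = list(circle_pts(0.5, 0.5, 0.26, 0.36, 0, 2 * pi, 28)),
    "1" = list(rbind(c(0.36, 0.26), c(0.56, 0.12), c(0.56, 0.88))),
    "2" = list(rbind(circle_pts(0.5, 0.33, 0.25, 0.2, pi, 2 * pi, 12),
                     c(0.27, 0.86), c(0.78, 0.86))),
    "3" = list(rbind(circle_pts(0.45, 0.3, 0.25, 0.19, 1.25 * pi, 2.45 * pi, 12),
                     circle_pts(0.45, 0.69, 0.27, 0.2, 1.55 * pi, 2.8 * pi, 12))),
    "4" = list(rbind(c(0.6, 0.12), c(0.18, 0.6), c(0.85, 0.6)),
               rbind(c(0.62, 0.28), c(0.62, 0.9))),
    "5" = list(rbind(c(0.75, 0.12), c(0.3, 0.12), c(0.28, 0.45)),
               circle_pts(0.45, 0.65, 0.28, 0.23, -0.4 * pi, 1.1 * pi, 14)),
    "6" = list(rbind(c(0.68, 0.12), c(0.45, 0.28), c(0.32, 0.48), c(0.3, 0.68)),
               circle_pts(0.5, 0.68, 0.2, 0.2, 0, 2 * pi, 20)),
    "7" = list(rbind(c(0.22, 0.14), c(0.78, 0.14), c(0.42, 0.88))),
    "8" = list(circle_pts(0.5, 0.31, 0.2, 0.19, 0, 2 * pi, 20),
               circle_pts(0.5, 0.7, 0.24, 0.21, 0, 2 * pi, 20)),
    "9" = list(circle_pts(0.52, 0.33, 0.21, 0.21, 0, 2 * pi, 20),
               rbind(c(0.73, 0.33), c(0.71, 0.6), c(0.6, 0.88))),
    stop("digit must be in 0..9")
  )
}

# Minimum distance from each point in (px, py) to segment p-q.
seg_dist <- function(px, py, p, q) {
  vx <- q[1] - p[1]; vy <- q[2] - p[2]
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) return(sqrt((px - p[1])^2 + (py - p[2])^2))
  t <- pmin(1, pmax(0, ((px - p[1]) * vx + (py - p[2]) * vy) / len2))
  sqrt((px - (p[1] + t * vx))^2 + (py - (p[2] + t * vy))^2)
}

render_glyph <- function(digit, side = 28L, jitter = TRUE) {
  strokes <- glyph_strokes(digit)
  if (jitter) {
    ang <- runif(1, -0.2, 0.2)
    sc <- runif(2, 0.85, 1.1)
    sh <- runif(1, -0.12, 0.12)
    tr <- runif(2, -0.05, 0.05)
    hw <- runif(1, 0.04, 0.06)
    A <- matrix(c(cos(ang) * sc[1], sin(ang) * sc[1],
                  -sin(ang) * sc[2] + sh, cos(ang) * sc[2]), 2, 2)
    strokes <- lapply(strokes, function(s) {
      ctr <- matrix(0.5, nrow(s), 2, byrow = TRUE)
      sweep((s - ctr) %*% t(A) + ctr, 2L, -tr)
    })
  } else {
    hw <- 0.05
  }
  # Pixel (r, c) of the image matrix maps to x = g[c], y = g[r]; the pixel
  # vector below is in column-major order (r fastest).
  g <- seq(0.5 / side, 1 - 0.5 / side, length.out = side)
  px <- rep(g, each = side)
  py <- rep(g, times = side)
  d <- rep(Inf, side * side)
  for (s in strokes) {
    for (i in seq_len(nrow(s) - 1L)) {
      d <- pmin(d, seg_dist(px, py, s[i, ], s[i + 1L, ]))
    }
  }
  aa <- 1 / side
  v <- pmin(1, pmax(0, (hw - d) / aa + 1))
  matrix(as.integer(round(255 * v)), side, side)
}

#' Generate a labeled glyph pool
#'
#' Renders `n` jittered glyph images with class labels drawn uniformly from
#' `classes`, as a programmatic, download-free source of labeled small
#' images for bag assembly.
#'
#' @param n Number of images (ignored when `labels` is given).
#' @param classes Integer digit classes to draw from (default 0:9).
#' @param side Image side length in pixels (default 28).
#' @param seed Optional seed for reproducibility.
#' @param labels Optional explicit label vector (one image per entry),
#'   overriding the uniform class draw.
#' @return An object of class `glyph_pool`: list with `images`
#'   (side x side x n integer array, values 0..255), `labels` (integer
#'   vector), and `side`.
#' @export
glyph_pool <- function(n, classes = 0:9, side = 28L, seed = NULL,
                       labels = NULL) {
  if (!is.null(labels)) n <- length(labels)
  stopifnot(n >= 1)
  run <- function() {
    labels <- if (is.null(labels)) sample(classes, n, replace = TRUE) else
      sample(labels)
    images <- array(0L, c(side, side, n))
    for (i in seq_len(n)) images[, , i] <- render_glyph(labels[i], side)
    structure(list(images = images, labels = as.integer(labels),
                   side = as.integer(side)),
              class = "glyph_pool")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.glyph_pool <- function(x, ...) {
  cat("glyph_pool:", length(x$labels), "images,",
      x$side, "x", x$side, "px, classes:",
      paste(sort(unique(x$labels)), collapse = " "), "\n")
  invisible(x)
}

#' Split a labeled source into train / validation / test pools
#'
#' The training pool passes through unchanged; the test pool is randomly
#' partitioned into a validation pool (`val_frac`, default 20%) and the
#' remaining test pool. The two parts are disjoint and exhaustive.
#'
#' @param train_pool,test_pool Two disjoint [glyph_pool()] objects.
#' @param val_frac Fraction of the test pool moved to validation.
#' @param seed Optional seed.
#' @return Named list `train_pool`, `val_pool`, `test_pool`.
#' @export
split_source_pool <- function(train_pool, test_pool, val_frac = 0.2,
                              seed = NULL) {
  n <- length(test_pool$labels)
  pick <- function() sample.int(n, round(val_frac * n))
  vi <- if (is.null(seed)) pick() else with_seed(seed, pick())
  take <- function(pool, idx) {
    structure(list(images = pool$images[, , idx, drop = FALSE],
                   labels = pool$labels[idx], side = pool$side),
              class = "glyph_pool")
  }
  list(train_pool = train_pool,
       val_pool = take(test_pool, vi),
       test_pool = take(test_pool, setdiff(seq_len(n), vi)))
}
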