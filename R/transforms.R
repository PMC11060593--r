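# Image geometry and noise transforms.
#
# Creation-time transforms emulate nuisance variation expected in cytology
# crops (arbitrary cell rotation, optical blur, sensor noise, small scale
# differences); training-time augmentations are restricted to the
# interpolation-free group (flips, rotations by multiples of 90 degrees)
# plus additive Gaussian noise.

# Bilinear sampling of a single-channel image at (non-integer) coordinates.
# Coordinates outside the image sample `fill`.
bilinear_sample <- function(img, xs, ys, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- rep(fill, length(r))
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  v00 <- gv(y0, x0); v10 <- gv(y0 + 1, x0)
  v01 <- gv(y0, x0 + 1); v11 <- gv(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

resample_plane <- function(img, out_h, out_w) {
  # Align centers; coordinates are clamped to the image so borders replicate
  # (bilinear interpolation proper, no frame darkening).
  sy <- nrow(img) / out_h; sx <- ncol(img) / out_w
  ys <- pmin(nrow(img), pmax(1, (seq_len(out_h) - 0.5) * sy + 0.5))
  xs <- pmin(ncol(img), pmax(1, (seq_len(out_w) - 0.5) * sx + 0.5))
  xg <- rep(xs, each = out_h)
  yg <- rep(ys, times = out_w)
  matrix(bilinear_sample(img, xg, yg), out_h, out_w)
}

#' Rescale a glyph image by bilinear interpolation
#'
#' @param glyph Single-channel image matrix.
#' @param target_side Output side length (must be >= the source side).
#' @return A `target_side` x `target_side` matrix.
#' @export
rescale_glyph <- function(glyph, target_side) {
  stopifnot(is.matrix(glyph))
  if (target_side <= 0) stop("target_side must be positive")
  if (target_side < nrow(glyph)) stop("target_side must be >= source side")
  if (target_side == nrow(glyph) && target_side == ncol(glyph)) return(glyph)
  resample_plane(glyph, target_side, target_side)
}

# Rotate a single-channel plane by `angle` degrees about its center
# (bilinear, fill = background).
rotate_plane <- function(img, angle, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  xg <- rep(seq_len(w), each = h) - cx
  yg <- rep(seq_len(h), times = w) - cy
  xs <- cos(th) * xg + sin(th) * yg + cx
  ys <- -sin(th) * xg + cos(th) * yg + cy
  matrix(bilinear_sample(img, xs, ys, fill), h, w)
}

gaussian_blur_plane <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ,
                          drop = FALSE]
  # separable: rows then columns, replicate-padding the borders
  m1 <- pad(img, r)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * m1[(i - 1) + seq_len(h), , drop = FALSE]
  m2 <- t(pad(t(out), r))
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) out2 <- out2 + k[i] * m2[, (i - 1) + seq_len(w), drop = FALSE]
  out2
}

apply_planes <- function(img, f) {
  if (is.matrix(img)) return(f(img))
  for (k in seq_len(dim(img)[3])) img[, , k] <- f(img[, , k])
  img
}

#' Creation-transform configuration
#'
#' Probabilities and magnitudes of the dataset-creation transforms: rotation
#' by an angle uniform in [0, 360), Gaussian blur, additive Gaussian noise,
#' and small scale jitter. Magnitudes are on the 8-bit intensity / pixel
#' scale.
#'
#' @param p_rotate,p_blur,p_noise,p_scale Per-transform application
#'   probabilities.
#' @param blur_sigma Blur standard deviation in pixels.
#' @param noise_sd Noise standard deviation in 8-bit intensity units.
#' @param scale_range Multiplicative scale-jitter interval.
#' @export
creation_transform_config <- function(p_rotate = 1, p_blur = 0.25,
                                      p_noise = 0.25, p_scale = 0.25,
                                      blur_sigma = 0.8, noise_sd = 5,
                                      scale_range = c(0.9, 1.1)) {
  list(p_rotate = p_rotate, p_blur = p_blur, p_noise = p_noise,
       p_scale = p_scale, blur_sigma = blur_sigma, noise_sd = noise_sd,
       scale_range = scale_range)
}

#' Apply creation transforms to one image
#'
#' Draws each transform independently with its configured probability and
#' applies it; output is clipped to [0, 255]. Consumes the current RNG
#' stream, so a fixed seed gives bit-identical output.
#'
#' @param image Matrix (single-channel) or H x W x C array, values 0..255.
#' @param config A [creation_transform_config()].
#' @return Transformed image of the same shape.
#' @export
apply_creation_transforms <- function(image, config = creation_transform_config()) {
  if (runif(1) < config$p_rotate) {
    ang <- runif(1, 0, 360)
    image <- apply_planes(image, function(m) rotate_plane(m, ang))
  }
  if (runif(1) < config$p_scale) {
    s <- runif(1, config$scale_range[1], config$scale_range[2])
    image <- apply_planes(image, function(m) {
      h <- nrow(m); w <- ncol(m)
      big <- resample_plane(m, max(2L, round(h * s)), max(2L, round(w * s)))
      # center-crop or zero-pad back to the original size
      out <- matrix(0, h, w)
      bh <- nrow(big); bw <- ncol(big)
      r0 <- max(0L, (bh - h) %/% 2L); c0 <- max(0L, (bw - w) %/% 2L)
      ro <- max(0L, (h - bh) %/% 2L); co <- max(0L, (w - bw) %/% 2L)
      nr <- min(h, bh); nc <- min(w, bw)
      out[ro + seq_len(nr), co + seq_len(nc)] <-
        big[r0 + seq_len(nr), c0 + seq_len(nc)]
      out
    })
  }
  if (runif(1) < config$p_blur) {
    image <- apply_planes(image, function(m)
      gaussian_blur_plane(m, config$blur_sigma))
  }
  if (runif(1) < config$p_noise) {
    image <- image + array(rnorm(length(image), sd = config$noise_sd),
                           dim(image) %||% length(image))
  }
  image[image < 0] <- 0
  image[image > 255] <- 255
  image
}

rot90_plane <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m) - seq_len(ncol(m)) + 1L, , drop = FALSE]
  m
}

#' Training-time augmentation configuration
#'
#' @param p_flip_h,p_flip_v Horizontal / vertical flip probabilities.
#' @param rot90 If TRUE, rotate by a uniformly drawn multiple of 90 degrees
#'   (a pure pixel permutation, no interpolation).
#' @param noise_sd Additive Gaussian noise sd, on the scale of the input
#'   (applied after standardization during training).
#' @export
augment_config <- function(p_flip_h = 0.5, p_flip_v = 0.5, rot90 = TRUE,
                           noise_sd = 0.05) {
  list(p_flip_h = p_flip_h, p_flip_v = p_flip_v, rot90 = rot90,
       noise_sd = noise_sd)
}

#' Augment a training batch
#'
#' Applies, independently per image: horizontal flip, vertical flip,
#' rotation by a multiple of 90 degrees (pixel permutation), and additive
#' Gaussian noise. Labels and key flags are untouched by construction.
#'
#' @param x Batch array (H, W, C, N).
#' @param config An [augment_config()].
#' @return Augmented batch of the same shape.
#' @export
augment_batch <- function(x, config = augment_config()) {
  d <- dim(x)
  n <- d[4]
  fh <- runif(n) < config$p_flip_h
  fv <- runif(n) < config$p_flip_v
  ks <- if (isTRUE(config$rot90)) sample(0:3, n, replace = TRUE) else rep(0L, n)
  if (any(fh)) x[, , , fh] <- x[, d[2]:1, , fh, drop = FALSE]
  if (any(fv)) x[, , , fv] <- x[d[1]:1, , , fv, drop = FALSE]
  # 90-degree rotations are pure pixel permutations (square images)
  if (d[1] == d[2]) {
    for (k in 1:3) {
      sel <- ks == k
      if (!any(sel)) next
      r <- x[, , , sel, drop = FALSE]
      for (j in seq_len(k)) r <- aperm(r, c(2L, 1L, 3L, 4L))[d[1]:1, , , , drop = FALSE]
      x[, , , sel] <- r
    }
  } else {
    for (i in which(ks > 0L)) {
      for (c in seq_len(d[3])) x[, , c, i] <- rot90_plane(x[, , c, i], ks[i])
    }
  }
  if (config$noise_sd > 0) {
    x <- x + array(rnorm(length(x), sd = config$noise_sd), d)
  }
  x
}
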