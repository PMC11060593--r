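# Channel color model: the background color of each synthetic instance is
# drawn per image from per-channel laws fitted to (or chosen to emulate) the
# turquoise background of PAP-stained liquid-based cytology: a normal law for
# the green and blue channels and a skew-normal law for the red channel.
# Sampling is restricted to the central [q_lo, q_hi] quantile interval of
# each law ("avoiding the tails"), via inverse-CDF sampling of a uniform on
# that interval, which keeps the draw count fixed and the stream
# reproducible.

dsn_ <- function(x, xi, omega, alpha) {
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

# CDF and quantile table of the skew-normal on a fine grid (trapezoid
# integration of the density); plenty of accuracy for 8-bit color values.
sn_cdf_table <- function(xi, omega, alpha, n = 4096L) {
  xs <- seq(xi - 8 * omega, xi + 8 * omega, length.out = n)
  fx <- dsn_(xs, xi, omega, alpha)
  dx <- diff(xs)
  cdf <- c(0, cumsum((fx[-1] + fx[-n]) / 2 * dx))
  cdf <- cdf / cdf[n]
  list(x = xs, p = cdf)
}

qsn_ <- function(p, tab) stats::approx(tab$p, tab$x, xout = p, ties = "ordered")$y

#' Channel color model
#'
#' @param green,blue Numeric `c(mean, sd)` of the normal law for the green
#'   and blue channel (8-bit scale).
#' @param red Numeric `c(location, scale, shape)` of the skew-normal law for
#'   the red channel.
#' @param tail_quantiles Numeric `c(q_lo, q_hi)` in (0,1): sampling is
#'   truncated to the central quantile interval of each law.
#' @return An object of class `channel_color_model`. The defaults emulate a
#'   bright turquoise background (low red, high green/blue).
#' @export
channel_color_model <- function(green = c(185, 12), blue = c(205, 10),
                                red = c(110, 25, 4),
                                tail_quantiles = c(0.025, 0.975)) {
  stopifnot(green[2] >= 0, blue[2] >= 0, red[2] >= 0,
            length(tail_quantiles) == 2,
            tail_quantiles[1] < tail_quantiles[2],
            tail_quantiles[1] > 0, tail_quantiles[2] < 1)
  tab <- sn_cdf_table(red[1], max(red[2], 1e-8), red[3])
  m <- list(green = green, blue = blue, red = red,
            tail_quantiles = tail_quantiles,
            red_tab = tab,
            red_bounds = qsn_(tail_quantiles, tab))
  structure(m, class = "channel_color_model")
}

#' @export
print.channel_color_model <- function(x, ...) {
  cat(sprintf(paste0("channel_color_model: red ~ SN(%.1f, %.1f, %.2f), ",
                     "green ~ N(%.1f, %.1f), blue ~ N(%.1f, %.1f), ",
                     "central [%.3f, %.3f] quantile interval\n"),
              x$red[1], x$red[2], x$red[3], x$green[1], x$green[2],
              x$blue[1], x$blue[2], x$tail_quantiles[1], x$tail_quantiles[2]))
  invisible(x)
}

# One truncated draw per channel per image; n images at once.
sample_background <- function(model, n) {
  q <- model$tail_quantiles
  u <- matrix(runif(3L * n, q[1], q[2]), 3L, n)
  rbind(red = qsn_(pmin(pmax(u[1, ], model$red_tab$p[1]), 1), model$red_tab),
        green = qnorm(u[2, ], model$green[1], model$green[2]),
        blue = qnorm(u[3, ], model$blue[1], model$blue[2]))
}

#' Colorize a grayscale glyph
#'
#' Samples one background color triple from the (truncated) channel laws and
#' renders the glyph foreground as a darker blend of that color: with
#' normalized glyph intensity g in [0,1], the pixel color is
#' `background * (1 - blend * g)`. Colorization is identical for positive
#' and negative classes by construction.
#'
#' @param glyph Single-channel image (matrix, values 0..255).
#' @param model A [channel_color_model()].
#' @param blend Foreground blend factor in [0,1] (default 0.85).
#' @return An H x W x 3 numeric array on the 0..255 scale.
#' @export
colorize_glyph <- function(glyph, model, blend = 0.85) {
  stopifnot(is.matrix(glyph))
  bg <- sample_background(model, 1L)
  g <- glyph / 255
  out <- array(0, c(dim(glyph), 3L))
  for (k in 1:3) out[, , k] <- bg[k] * (1 - blend * g)
  out
}

# ---- fitting ---------------------------------------------------------------

sample_skewness <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# Method-of-moments skew-normal fit, refined by maximum likelihood.
fit_skew_normal <- function(x) {
  m <- mean(x); s <- sd(x); g1 <- sample_skewness(x)
  gmax <- 0.9952  # supremum of skew-normal skewness magnitude
  g1 <- sign(g1) * min(abs(g1), gmax * 0.999)
  skew_of_delta <- function(d) {
    mu <- d * sqrt(2 / pi)
    (4 - pi) / 2 * mu^3 / (1 - mu^2)^1.5
  }
  if (abs(g1) < 1e-8) {
    delta <- 0
  } else {
    delta <- sign(g1) *
      uniroot(function(d) skew_of_delta(d) - abs(g1), c(1e-9, 0.999999))$root
  }
  omega <- s / sqrt(max(1 - 2 * delta^2 / pi, 1e-6))
  xi <- m - omega * delta * sqrt(2 / pi)
  alpha <- delta / sqrt(max(1 - delta^2, 1e-12))
  nll <- function(par) {
    d <- dsn_(x, par[1], exp(par[2]), par[3])
    -sum(log(pmax(d, 1e-300)))
  }
  fit <- tryCatch(
    optim(c(xi, log(omega), alpha), nll, method = "BFGS",
          control = list(maxit = 100)),
    error = function(e) NULL)
  if (!is.null(fit) && is.finite(fit$value)) {
    c(location = fit$par[1], scale = exp(fit$par[2]), shape = fit$par[3])
  } else {
    c(location = xi, scale = omega, shape = alpha)
  }
}

#' Fit channel color laws from an image sample
#'
#' Fits a normal law to the green and blue channels (moment estimates) and a
#' skew-normal law to the red channel (method of moments refined by maximum
#' likelihood) from the pooled pixels of a sample of RGB images. The fit is
#' deterministic given the input (pixel subsampling is evenly spaced, not
#' random).
#'
#' @param sample_images List of H x W x 3 arrays, or one H x W x 3 x N array,
#'   pixel values 0..255.
#' @param tail_quantiles Central quantile interval stored on the resulting
#'   model (default `c(0.025, 0.975)`).
#' @param max_pixels Per-channel cap on pixels used for fitting; larger
#'   samples are thinned deterministically.
#' @return A [channel_color_model()].
#' @export
fit_channel_models <- function(sample_images, tail_quantiles = c(0.025, 0.975),
                               max_pixels = 2e5) {
  if (is.list(sample_images)) {
    stopifnot(length(sample_images) >= 2)
    px <- lapply(1:3, function(k) {
      unlist(lapply(sample_images, function(im) as.vector(im[, , k])))
    })
  } else {
    stopifnot(length(dim(sample_images)) == 4, dim(sample_images)[4] >= 2)
    px <- lapply(1:3, function(k) as.vector(sample_images[, , k, ]))
  }
  px <- lapply(px, function(v) {
    if (length(v) > max_pixels) {
      v[seq(1L, length(v), length.out = max_pixels)]
    } else v
  })
  fit_norm <- function(v, ch) {
    s <- sd(v)
    if (s == 0) warning("degenerate (constant) ", ch, " channel: sd 0 recorded")
    c(mean(v), s)
  }
  red_px <- px[[1]]
  red <- if (sd(red_px) == 0) {
    warning("degenerate (constant) red channel: scale 0 recorded")
    c(mean(red_px), 0, 0)
  } else {
    unname(fit_skew_normal(red_px))
  }
  channel_color_model(green = fit_norm(px[[2]], "green"),
                      blue = fit_norm(px[[3]], "blue"),
                      red = red, tail_quantiles = tail_quantiles)
}
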