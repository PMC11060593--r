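# Bag dataset generation: bags of colorized glyph instances with reliable
# per-instance ground truth.  A bag models one patient sample; a positive
# bag contains a controlled fraction of key-digit instances, a negative bag
# none ("key instances are present only within positive bags").

#' Key-instance fraction model
#'
#' In `fixed` mode every positive bag receives the fraction `p`; in `beta`
#' mode each positive bag draws its fraction from Beta(alpha, beta). The
#' study values are fixed p in \{0.05, 0.1, 0.2, 0.3\}, and beta laws with
#' mean 17.5% and sd 5% (alpha 9.932, beta 46.82) or sd 10% (alpha 2.352,
#' beta 11.086) modeling inter-patient variability in malignant-cell
#' abundance.
#'
#' @param mode `"fixed"` or `"beta"`.
#' @param p Fraction used in fixed mode.
#' @param alpha,beta Positive shape parameters for beta mode.
#' @export
key_fraction_model <- function(mode = c("fixed", "beta"), p = 0.2,
                               alpha = 9.932, beta = 46.82) {
  mode <- match.arg(mode)
  if (mode == "fixed") stopifnot(p >= 0, p <= 1)
  if (mode == "beta") {
    stopifnot(alpha > 0, beta > 0)
    mu <- alpha / (alpha + beta)
    stopifnot(mu > 0, mu < 1)
  }
  structure(list(mode = mode, p = p, alpha = alpha, beta = beta),
            class = "key_fraction_model")
}

#' Draw a key-instance fraction for one bag
#'
#' Negative bags always receive 0; positive bags receive the fixed fraction
#' or one beta draw depending on the model mode.
#'
#' @param model A [key_fraction_model()].
#' @param bag_label `"positive"` or `"negative"`.
#' @return A fraction in [0, 1].
#' @export
sample_key_fraction <- function(model, bag_label) {
  stopifnot(inherits(model, "key_fraction_model"))
  if (bag_label != "positive") return(0)
  if (model$mode == "fixed") model$p else rbeta(1, model$alpha, model$beta)
}

#' Bag-dataset geometry configuration
#'
#' @param n_pos,n_neg Number of positive / negative bags (default 12 + 12,
#'   the cohort size of the emulated patient study).
#' @param bag_size Either a fixed per-bag instance count, or `"lognormal"`
#'   for full-scale bag sizes drawn from a lognormal law with the given mean.
#' @param bag_size_mean,bag_size_cv Mean and coefficient of variation of the
#'   lognormal bag-size law (mean 9300 emulates the average cells-per-patient
#'   count of the target cytology cohort).
#' @param image_side Side length of the generated RGB instances (default 80).
#' @param key_digit Glyph class marking key instances (default 4).
#' @export
bag_geometry <- function(n_pos = 12L, n_neg = 12L, bag_size = "lognormal",
                         bag_size_mean = 9300, bag_size_cv = 0.5,
                         image_side = 80L, key_digit = 4L) {
  list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
       bag_size = bag_size, bag_size_mean = bag_size_mean,
       bag_size_cv = bag_size_cv, image_side = as.integer(image_side),
       key_digit = as.integer(key_digit))
}

draw_bag_sizes <- function(geometry, n) {
  if (identical(geometry$bag_size, "lognormal")) {
    cv <- geometry$bag_size_cv
    sdl <- sqrt(log(1 + cv^2))
    ml <- log(geometry$bag_size_mean) - sdl^2 / 2
    pmax(50L, as.integer(round(exp(rnorm(n, ml, sdl)))))
  } else {
    rep(as.integer(geometry$bag_size), n)
  }
}

#' Assemble a synthetic bag dataset
#'
#' Builds `n_pos` positive and `n_neg` negative bags. Positive bags contain
#' `max(1, round(size * p))` key-digit instances (p drawn from `kf_model`)
#' with the remainder drawn from non-key digit classes; negative bags
#' contain only non-key digits. Instances are drawn from the source pool
#' without replacement, rescaled by bilinear interpolation to
#' `geometry$image_side`, geometrically transformed (rotation/scale on the
#' grayscale glyph so that the fill matches the background), colorized with
#' one truncated background draw per image, then blurred/noised per the
#' transform config. The full generation config, including the seed, is
#' stored for provenance.
#'
#' @param pool A [glyph_pool()] (the source split to draw from).
#' @param kf_model A [key_fraction_model()].
#' @param color_model A [channel_color_model()].
#' @param geometry A [bag_geometry()].
#' @param transforms A [creation_transform_config()].
#' @param seed Master seed for generation.
#' @return An object of class `bag_dataset`: list with `images`
#'   (side x side x 3 x N integer array, 0..255), `instances` (data.frame:
#'   instance_id, bag_id, glyph_class, is_key, bag_label), `bags`
#'   (data.frame: bag_id, label, size, key_fraction_drawn, n_key) and
#'   `config`.
#' @export
assemble_bags <- function(pool, kf_model, color_model,
                          geometry = bag_geometry(),
                          transforms = creation_transform_config(),
                          seed = 1L) {
  stopifnot(inherits(pool, "glyph_pool"))
  with_seed(derive_seed(seed, "assemble"), {
    n_bags <- geometry$n_pos + geometry$n_neg
    labels <- rep(c("positive", "negative"), c(geometry$n_pos, geometry$n_neg))
    sizes <- draw_bag_sizes(geometry, n_bags)
    fracs <- vapply(labels, function(l) sample_key_fraction(kf_model, l),
                    numeric(1))
    n_key <- ifelse(labels == "positive",
                    pmax(1L, as.integer(round(sizes * fracs))), 0L)
    n_key <- pmin(n_key, sizes)

    key_idx <- which(pool$labels == geometry$key_digit)
    oth_idx <- which(pool$labels != geometry$key_digit)
    need_key <- sum(n_key); need_oth <- sum(sizes) - need_key
    if (length(key_idx) < need_key) {
      stop("insufficient key-digit source images: need ", need_key,
           ", have ", length(key_idx))
    }
    if (length(oth_idx) < need_oth) {
      stop("insufficient non-key source images: need ", need_oth,
           ", have ", length(oth_idx))
    }
    key_draw <- sample(key_idx, need_key)
    oth_draw <- sample(oth_idx, need_oth)

    total <- sum(sizes)
    side <- geometry$image_side
    images <- array(0L, c(side, side, 3L, total))
    inst <- data.frame(instance_id = seq_len(total), bag_id = 0L,
                       glyph_class = 0L, is_key = FALSE,
                       bag_label = "", stringsAsFactors = FALSE)
    ki <- 1L; oi <- 1L; pos <- 1L
    for (b in seq_len(n_bags)) {
      nk <- n_key[b]; no <- sizes[b] - nk
      src <- c(if (nk > 0) key_draw[ki + seq_len(nk) - 1L],
               if (no > 0) oth_draw[oi + seq_len(no) - 1L])
      ki <- ki + nk; oi <- oi + no
      src <- sample(src)  # shuffle key/non-key order within the bag
      for (s in src) {
        glyph <- rescale_glyph(pool$images[, , s], side)
        if (runif(1) < transforms$p_rotate) {
          glyph <- rotate_plane(glyph, runif(1, 0, 360))
        }
        if (runif(1) < transforms$p_scale) {
          sc <- runif(1, transforms$scale_range[1], transforms$scale_range[2])
          big <- resample_plane(glyph, max(2L, round(side * sc)),
                                max(2L, round(side * sc)))
          out <- matrix(0, side, side)
          bh <- nrow(big)
          r0 <- max(0L, (bh - side) %/% 2L); ro <- max(0L, (side - bh) %/% 2L)
          nr <- min(side, bh)
          out[ro + seq_len(nr), ro + seq_len(nr)] <-
            big[r0 + seq_len(nr), r0 + seq_len(nr)]
          glyph <- out
        }
        rgb <- colorize_glyph(glyph, color_model)
        if (runif(1) < transforms$p_blur) {
          rgb <- apply_planes(rgb, function(m)
            gaussian_blur_plane(m, transforms$blur_sigma))
        }
        if (runif(1) < transforms$p_noise) {
          rgb <- rgb + array(rnorm(length(rgb), sd = transforms$noise_sd),
                             dim(rgb))
        }
        images[, , , pos] <- as.integer(round(pmin(255, pmax(0, rgb))))
        inst$bag_id[pos] <- b
        inst$glyph_class[pos] <- pool$labels[s]
        inst$is_key[pos] <- (pool$labels[s] == geometry$key_digit) &&
          labels[b] == "positive"
        inst$bag_label[pos] <- labels[b]
        pos <- pos + 1L
      }
    }
    bags <- data.frame(bag_id = seq_len(n_bags), label = labels,
                       size = sizes, key_fraction_drawn = fracs,
                       n_key = n_key, stringsAsFactors = FALSE)
    structure(list(images = images, instances = inst, bags = bags,
                   config = list(seed = seed, geometry = geometry,
                                 kf_model = unclass(kf_model),
                                 transforms = transforms,
                                 color_model = list(
                                   green = color_model$green,
                                   blue = color_model$blue,
                                   red = color_model$red,
                                   tail_quantiles = color_model$tail_quantiles))),
              class = "bag_dataset")
  })
}

#' @export
print.bag_dataset <- function(x, ...) {
  cat("bag_dataset:", nrow(x$bags), "bags (",
      sum(x$bags$label == "positive"), "positive,",
      sum(x$bags$label == "negative"), "negative ),",
      nrow(x$instances), "instances,",
      dim(x$images)[1], "x", dim(x$images)[2], "px, key digit",
      x$config$geometry$key_digit, "\n")
  invisible(x)
}

#' @export
summary.bag_dataset <- function(object, ...) {
  b <- object$bags
  cat("Bags:\n")
  print(b)
  cat("\nKey instances total:", sum(object$instances$is_key), "of",
      nrow(object$instances), "instances\n")
  invisible(b)
}

# Extract instance images by id as a (H, W, C, n) double array.
instance_images <- function(dataset, instance_ids) {
  dataset$images[, , , instance_ids, drop = FALSE] * 1.0
}

#' Write a bag dataset to disk
#'
#' Layout: `bags/bag_<id>/inst_<id>.png` (8-bit RGB PNG, lossless),
#' `manifest.csv` (instance_id, bag_id, bag_label, glyph_class, is_key) and
#' `dataset.json` (generation config including the seed).
#'
#' @param dataset A [assemble_bags()] result.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_bag_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (b in dataset$bags$bag_id) {
    dir.create(file.path(path, "bags", sprintf("bag_%03d", b)),
               recursive = TRUE, showWarnings = FALSE)
  }
  for (i in dataset$instances$instance_id) {
    b <- dataset$instances$bag_id[i]
    png::writePNG(dataset$images[, , , i] / 255,
                  file.path(path, "bags", sprintf("bag_%03d", b),
                            sprintf("inst_%06d.png", i)))
  }
  man <- dataset$instances[, c("instance_id", "bag_id", "bag_label",
                               "glyph_class", "is_key")]
  write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)
  cfg <- dataset$config
  cfg$bags <- dataset$bags
  jsonlite::write_json(cfg, file.path(path, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a bag dataset written by [write_bag_dataset()]
#'
#' @param path Dataset directory.
#' @return A `bag_dataset`; labels, key flags and pixel data round-trip
#'   exactly.
#' @export
read_bag_dataset <- function(path) {
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  man <- read.csv(mf, stringsAsFactors = FALSE)
  man$is_key <- as.logical(man$is_key)
  cfg <- jsonlite::read_json(file.path(path, "dataset.json"),
                             simplifyVector = TRUE)
  bags <- cfg$bags
  cfg$bags <- NULL
  side <- cfg$geometry$image_side
  images <- array(0L, c(side, side, 3L, nrow(man)))
  for (i in seq_len(nrow(man))) {
    f <- file.path(path, "bags", sprintf("bag_%03d", man$bag_id[i]),
                   sprintf("inst_%06d.png", man$instance_id[i]))
    if (!file.exists(f)) {
      stop("missing image for instance ", man$instance_id[i], ": ", f)
    }
    images[, , , i] <- as.integer(round(png::readPNG(f) * 255))
  }
  structure(list(images = images, instances = man, bags = bags, config = cfg),
            class = "bag_dataset")
}
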