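# Shared fixtures and independent oracles, built in code at test time.

# Brightness-separable toy bag dataset: key instances carry a bright disc on
# a dark noisy background, non-key instances are background only.  With
# `all_bright_pos = TRUE` every instance of a positive bag is bright, making
# even the weak (bag-inherited) instance labels perfectly separable.
make_toy_dataset <- function(n_pos = 6, n_neg = 6, bag_size = 40, side = 16,
                             p = 0.3, seed = 1, all_bright_pos = FALSE) {
  set.seed(seed)
  n <- (n_pos + n_neg) * bag_size
  images <- array(0L, c(side, side, 3, n))
  labels <- rep(c("positive", "negative"), c(n_pos, n_neg))
  inst <- data.frame(instance_id = 1:n, bag_id = 0L, glyph_class = 0L,
                     is_key = FALSE, bag_label = "")
  g <- seq(-1, 1, length.out = side)
  disc <- outer(g, g, function(a, b) (a^2 + b^2) < 0.4)
  pos <- 1
  for (b in seq_len(n_pos + n_neg)) {
    nk <- if (labels[b] == "positive") round(bag_size * p) else 0
    if (all_bright_pos && labels[b] == "positive") nk <- bag_size
    keys <- c(rep(TRUE, nk), rep(FALSE, bag_size - nk))
    for (i in seq_len(bag_size)) {
      base <- matrix(runif(side * side, 40, 90), side, side)
      if (keys[i]) base <- base + disc * 140
      for (k in 1:3) {
        images[, , k, pos] <-
          as.integer(pmin(255, base + rnorm(side * side, 0, 5)))
      }
      inst$bag_id[pos] <- b
      inst$is_key[pos] <- keys[i] && labels[b] == "positive"
      inst$glyph_class[pos] <- as.integer(keys[i]) * 4L
      inst$bag_label[pos] <- labels[b]
      pos <- pos + 1
    }
  }
  bags <- data.frame(bag_id = seq_len(n_pos + n_neg), label = labels,
                     size = bag_size,
                     key_fraction_drawn = ifelse(labels == "positive", p, 0),
                     n_key = ifelse(labels == "positive",
                                    round(bag_size * p), 0))
  structure(list(images = images, instances = inst, bags = bags,
                 config = list(seed = seed,
                               geometry = list(image_side = side,
                                               key_digit = 4L))),
            class = "bag_dataset")
}

# A one-fold plan over 12 toy bags (bags 1..6 positive, 7..12 negative).
toy_fold_plan <- function() {
  structure(list(list(train = c(1:3, 7:9), val = c(4L, 10L),
                      test = c(5L, 6L, 11L, 12L))),
            class = "fold_plan")
}

# --- independent oracles ----------------------------------------------------

# 5th percentile by direct linear interpolation between order statistics at
# fractional rank q * (n - 1).
oracle_percentile <- function(x, q = 0.05) {
  x <- sort(x)
  n <- length(x)
  if (n == 1) return(x)
  h <- q * (n - 1)
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
}

oracle_threshold <- function(pos, neg) {
  (oracle_percentile(pos) + oracle_percentile(neg)) / 2
}

# Precision@K by explicit enumeration of the top-k set.
oracle_precision_at_k <- function(scores, is_key, k, predicted_positive,
                                  ids = seq_along(scores)) {
  if (!predicted_positive) return(0)
  ord <- order(-scores, ids)
  top <- ord[seq_len(min(k, length(scores)))]
  sum(is_key[top]) / k
}

# Checkpoint selection by exhaustive enumeration of every window.
oracle_select <- function(metric, window, min_epoch, maximize = TRUE) {
  m <- if (maximize) metric else -metric
  n <- length(m)
  if (n < min_epoch + window) {
    cand <- min_epoch:n
    return(cand[which.max(m[cand])])
  }
  best_avg <- -Inf; best_start <- NA
  for (s in min_epoch:(n - window + 1)) {
    a <- mean(m[s:(s + window - 1)])
    if (a > best_avg) { best_avg <- a; best_start <- s }
  }
  win <- best_start:(best_start + window - 1)
  win[which.max(m[win])]
}
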