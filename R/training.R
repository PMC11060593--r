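# Shared training utilities: dataset-wide channel standardization and
# moving-average checkpoint selection.

#' Compute dataset-wide channel statistics
#'
#' Mean and standard deviation of each of the three color channels over all
#' instances of the dataset (regardless of fold or split), used to
#' standardize images before training and inference.
#'
#' @param dataset A `bag_dataset`.
#' @return List with numeric `mean` and `sd`, each of length 3.
#' @export
compute_channel_stats <- function(dataset) {
  if (nrow(dataset$instances) == 0) stop("empty dataset")
  d <- dim(dataset$images)
  m <- numeric(3); s <- numeric(3)
  for (k in 1:3) {
    v <- as.numeric(dataset$images[, , k, ])
    m[k] <- mean(v)
    s[k] <- sqrt(mean((v - m[k])^2))
  }
  list(mean = m, sd = s)
}

#' Standardize an image batch
#'
#' `(x - mean) / sd` per channel, with an epsilon guard for constant
#' channels.
#'
#' @param x Batch array (H, W, C, N) on the 0..255 scale.
#' @param stats Result of [compute_channel_stats()].
#' @param eps Guard added to a zero sd.
#' @return Standardized double array of the same shape.
#' @export
standardize <- function(x, stats, eps = 1e-8) {
  sdg <- ifelse(stats$sd > 0, stats$sd, eps)
  for (k in seq_len(dim(x)[3])) {
    x[, , k, ] <- (x[, , k, ] - stats$mean[k]) / sdg[k]
  }
  x
}

#' Select a training checkpoint from a validation-metric series
#'
#' Among all moving-average windows of length `window` fully contained in
#' `[min_epoch, length(metric)]`, finds the window with the best average
#' (highest for `mode = "maximize"`, lowest for `"minimize"`), then returns
#' the epoch of the best single value inside that window; ties resolve to
#' the earliest epoch. If the series is too short to contain a full window
#' after `min_epoch`, falls back to the best single epoch at or after
#' `min_epoch`, with a warning. The selected epoch is never below
#' `min_epoch`, guarding against early-training fluctuations.
#'
#' @param metric Numeric per-epoch validation metric series (epoch 1 first).
#' @param window Moving-average window length (default 15).
#' @param min_epoch Earliest selectable epoch (default 20).
#' @param mode `"maximize"` (e.g. F1) or `"minimize"` (e.g. error).
#' @return The selected epoch index.
#' @export
select_checkpoint <- function(metric, window = 15L, min_epoch = 20L,
                              mode = c("maximize", "minimize")) {
  mode <- match.arg(mode)
  stopifnot(window >= 1L)
  n <- length(metric)
  if (n <= min_epoch) stop("metric series must be longer than min_epoch")
  sgn <- if (mode == "maximize") 1 else -1
  m <- sgn * metric
  if (n < min_epoch + window) {
    warning("series shorter than min_epoch + window; ",
            "falling back to best single epoch >= min_epoch")
    cand <- min_epoch:n
    return(cand[which.max(m[cand])])
  }
  starts <- min_epoch:(n - window + 1L)
  avgs <- vapply(starts, function(s) mean(m[s:(s + window - 1L)]), numeric(1))
  s_best <- starts[which.max(avgs)]
  win <- s_best:(s_best + window - 1L)
  win[which.max(m[win])]
}

# F1 of the positive class at a fixed score threshold (strict >).
f1_score <- function(scores, labels_pos, threshold = 0.5) {
  pred <- scores > threshold
  tp <- sum(pred & labels_pos)
  fp <- sum(pred & !labels_pos)
  fn <- sum(!pred & labels_pos)
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}
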