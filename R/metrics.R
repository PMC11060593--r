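# Evaluation protocol: bag-level accuracy, instance-level Precision@K under
# the three-condition rule, fold aggregation, and score-ranked mosaics.

#' Bag-level classification accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of exact matches in [0, 1].
#' @export
bag_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  mean(predicted == truth)
}

#' Instance-level Precision@K for one positive bag
#'
#' An instance counts as a correctly detected key instance when (i) the
#' predicted bag label is positive, (ii) the instance is truly a key
#' instance, and (iii) its score falls among the top `k` scores of the bag,
#' where `k` is the bag's true key-instance count. If the bag is predicted
#' negative the precision is 0 regardless of scores. Ties at the k-th score
#' break by a stable sort: score descending, then instance id ascending.
#'
#' @param scores Per-instance scores of the bag.
#' @param is_key Logical true key flags, same length.
#' @param k Number of true key instances in the bag (must be positive).
#' @param predicted_positive Was the bag predicted positive?
#' @param instance_ids Ids used for deterministic tie-breaking (defaults to
#'   input order).
#' @return Precision in [0, 1].
#' @export
precision_at_k <- function(scores, is_key, k,
                           predicted_positive = TRUE,
                           instance_ids = seq_along(scores)) {
  stopifnot(length(scores) == length(is_key))
  if (k <= 0) stop("a positive bag must contain at least one key instance")
  if (!predicted_positive) return(0)
  ord <- order(-scores, instance_ids)
  top <- ord[seq_len(min(k, length(scores)))]
  sum(is_key[top]) / k
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample (n - 1) standard deviation of each metric
#' over folds. A single fold reports sd 0 with a warning.
#'
#' @param fold_values Numeric vector (one value per fold) or a data.frame
#'   of per-fold metric columns.
#' @return For a vector: list(mean, sd, n). For a data.frame: a data.frame
#'   with one row per metric.
#' @export
summarize_folds <- function(fold_values) {
  one <- function(v) {
    if (length(v) == 1L) {
      warning("single fold: standard deviation reported as 0")
      return(list(mean = v, sd = 0, n = 1L))
    }
    list(mean = mean(v), sd = sd(v), n = length(v))
  }
  if (is.data.frame(fold_values)) {
    out <- do.call(rbind, lapply(fold_values, function(v) {
      s <- one(v); data.frame(mean = s$mean, sd = s$sd, n = s$n)
    }))
    out$metric <- names(fold_values)
    rownames(out) <- NULL
    return(out[, c("metric", "mean", "sd", "n")])
  }
  one(fold_values)
}

#' Export a score-ranked instance mosaic
#'
#' Arranges the `n_top` highest-scoring instances of a bag (score
#' descending, instance id ascending on ties) row-major into a near-square
#' grid, as used to present the top 36 (6x6) or top 25 (5x5) candidate key
#' instances to a human reviewer. If `n_top` exceeds the bag size, all
#' instances are shown.
#'
#' @param dataset The `bag_dataset`.
#' @param bag_id Bag to render.
#' @param scores data.frame with columns `instance_id` and `score` covering
#'   the bag's instances.
#' @param n_top Number of tiles (default 36).
#' @param path Optional PNG output path.
#' @param border If TRUE, tint a 2-pixel tile border by the instance's true
#'   key flag (green key / red non-key) as a debugging aid.
#' @return List with `image` (the mosaic as an H x W x 3 array in [0, 1]),
#'   `manifest` (data.frame: tile, row, col, instance_id, score, is_key)
#'   and the grid shape `nrow`/`ncol`.
#' @export
export_mosaic <- function(dataset, bag_id, scores, n_top = 36L, path = NULL,
                          border = FALSE) {
  sel <- scores[scores$instance_id %in%
                  dataset$instances$instance_id[dataset$instances$bag_id == bag_id], ]
  ord <- sel[order(-sel$score, sel$instance_id), ]
  n <- min(n_top, nrow(ord))
  ord <- ord[seq_len(n), ]
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  side <- dim(dataset$images)[1]
  img <- array(1, c(nr * side, nc * side, 3L))
  man <- data.frame(tile = seq_len(n), row = 0L, col = 0L,
                    instance_id = ord$instance_id, score = ord$score,
                    is_key = dataset$instances$is_key[
                      match(ord$instance_id, dataset$instances$instance_id)])
  for (t in seq_len(n)) {
    r <- (t - 1L) %/% nc + 1L
    c_ <- (t - 1L) %% nc + 1L
    man$row[t] <- r; man$col[t] <- c_
    tile <- dataset$images[, , , ord$instance_id[t]] / 255
    if (border) {
      col3 <- if (man$is_key[t]) c(0, 1, 0) else c(1, 0, 0)
      for (k in 1:3) {
        tile[c(1:2, side - 1:0), , k] <- col3[k]
        tile[, c(1:2, side - 1:0), k] <- col3[k]
      }
    }
    img[(r - 1L) * side + seq_len(side),
        (c_ - 1L) * side + seq_len(side), ] <- tile
  }
  if (!is.null(path)) png::writePNG(img, path)
  list(image = img, manifest = man, nrow = nr, ncol = nc)
}
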