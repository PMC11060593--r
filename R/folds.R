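# Patient-level 9-fold cross-validation plan for 12 positive + 12 negative
# bags: per class, bags are split into 3 test groups of 4; each group serves
# as the test set of 3 folds, and the remaining 8 bags per class rotate
# through 3 distinct train(6)/validation(2) arrangements.  Every bag appears
# in the test set of exactly 3 of the 9 folds, and splitting is at the bag
# (patient) level, so no instance of a test bag is ever seen in training or
# validation of that fold.

#' Build a cross-validation fold plan
#'
#' @param dataset A `bag_dataset`, or a data.frame with columns `bag_id` and
#'   `label`.
#' @param n_folds Number of folds; must equal 3 x (number of test groups),
#'   default 9.
#' @param seed Seed for the (deterministic) bag shuffling.
#' @return An object of class `fold_plan`: a list of `n_folds` folds, each
#'   with integer bag-id vectors `train`, `val`, `test`.
#' @export
make_fold_plan <- function(dataset, n_folds = 9L, seed = 1L) {
  bags <- if (inherits(dataset, "bag_dataset")) dataset$bags else dataset
  pos <- bags$bag_id[bags$label == "positive"]
  neg <- bags$bag_id[bags$label == "negative"]
  if (length(pos) != 12L || length(neg) != 12L || n_folds != 9L) {
    # general pattern: groups of 4 test bags per class, 3 rotations each
    if (length(pos) %% 4L != 0L || length(pos) != length(neg) ||
        n_folds != 3L * length(pos) / 4L) {
      stop("bag counts incompatible with the 6/2/4 per-class fold pattern")
    }
  }
  with_seed(derive_seed(seed, "folds"), {
    pos <- sample(pos)
    neg <- sample(neg)
  })
  n_grp <- length(pos) / 4L
  folds <- vector("list", n_folds)
  for (g in seq_len(n_grp)) {
    test_p <- pos[(g - 1L) * 4L + 1:4]
    test_n <- neg[(g - 1L) * 4L + 1:4]
    rest_p <- setdiff(pos, test_p)
    rest_n <- setdiff(neg, test_n)
    for (r in 1:3) {
      vi <- (r - 1L) * 2L + 1:2
      fold <- list(train = c(rest_p[-vi], rest_n[-vi]),
                   val = c(rest_p[vi], rest_n[vi]),
                   test = c(test_p, test_n))
      folds[[3L * (g - 1L) + r]] <- fold
    }
  }
  structure(folds, class = "fold_plan", bag_labels = bags$label,
            bag_ids = bags$bag_id)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("fold_plan:", length(x), "folds\n")
  for (f in seq_along(x)) {
    cat(sprintf("  fold %d: train {%s} val {%s} test {%s}\n", f,
                paste(sort(x[[f]]$train), collapse = ","),
                paste(sort(x[[f]]$val), collapse = ","),
                paste(sort(x[[f]]$test), collapse = ",")))
  }
  invisible(x)
}
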