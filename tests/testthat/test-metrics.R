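# Evaluation metrics: bag accuracy, Precision@K, fold aggregation, mosaics.

test_that("bag accuracy counts exact matches", {
  expect_equal(bag_accuracy(rep("positive", 4), rep("positive", 4)), 1)
  expect_equal(bag_accuracy(c(rep("positive", 6), rep("negative", 2)),
                            rep("positive", 8)), 0.75)
  expect_equal(bag_accuracy(rep("positive", 3), rep("negative", 3)), 0)
  expect_error(bag_accuracy("positive", c("positive", "negative")),
               "equal length")
})

test_that("Precision@K applies the three-condition rule", {
  # K = 3 with 2 true keys in the top 3
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  keys <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(precision_at_k(sc, keys, 3), 2 / 3)
  # predicted-negative bag scores 0 regardless
  expect_equal(precision_at_k(sc, keys, 3, predicted_positive = FALSE), 0)
  expect_equal(precision_at_k(sc, c(TRUE, TRUE, TRUE, FALSE, FALSE), 3), 1)
  expect_error(precision_at_k(sc, keys, 0), "key instance")
  # ties at the k-th score break by instance id, deterministically
  expect_equal(precision_at_k(c(1, 0.5, 0.5), c(FALSE, TRUE, FALSE), 2,
                              instance_ids = c(10, 2, 5)), 0.5)
  expect_equal(precision_at_k(c(1, 0.5, 0.5), c(FALSE, FALSE, TRUE), 2,
                              instance_ids = c(10, 2, 5)), 0)
})

test_that("Precision@K equals the brute-force oracle on random bags", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    sc <- round(runif(n), 2)   # coarse scores force frequent ties
    keys <- runif(n) < 0.3
    k <- max(1, sum(keys))
    pp <- runif(1) < 0.8
    ids <- sample(1000, n)
    expect_equal(precision_at_k(sc, keys, k, pp, ids),
                 oracle_precision_at_k(sc, keys, k, pp, ids))
  }
})

test_that("random scores concentrate Precision@K near the key fraction", {
  # chance-level baseline: scoring at random, the expected fraction of keys
  # in any fixed-size top set equals the bag's key fraction p
  set.seed(23)
  p <- 0.2; n <- 400
  keys <- c(rep(TRUE, n * p), rep(FALSE, n * (1 - p)))
  vals <- replicate(300, precision_at_k(runif(n), keys, sum(keys)))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - p), 3 * se + 1e-12)
})

test_that("fold summaries use mean and sample sd", {
  s <- summarize_folds(c(0.8, 0.9, 1.0))
  expect_equal(s$mean, 0.9)
  expect_equal(s$sd, sd(c(0.8, 0.9, 1.0)))
  expect_equal(summarize_folds(rep(0.7, 9))$sd, 0)
  expect_warning(s1 <- summarize_folds(0.5), "single fold")
  expect_equal(s1$sd, 0)
  df <- summarize_folds(data.frame(acc = c(1, 1, 0.875),
                                   pk = c(0.9, 0.8, 0.7)))
  expect_equal(df$mean, c(mean(c(1, 1, 0.875)), 0.8))
})

test_that("mosaics are near-square, score-ranked, and manifest-complete", {
  ds <- make_toy_dataset(n_pos = 1, n_neg = 1, bag_size = 40, side = 12,
                         p = 0.3, seed = 5)
  sc <- data.frame(instance_id = 1:80, score = runif(80))
  m36 <- export_mosaic(ds, 1, sc, n_top = 36)
  expect_equal(c(m36$nrow, m36$ncol), c(6, 6))
  expect_equal(dim(m36$image), c(72, 72, 3))
  expect_equal(nrow(m36$manifest), 36)
  # manifest is ranked by score descending
  expect_true(all(diff(m36$manifest$score) <= 0))
  m25 <- export_mosaic(ds, 1, sc, n_top = 25)
  expect_equal(c(m25$nrow, m25$ncol), c(5, 5))
  # n_top beyond the bag size falls back to all instances, still ordered
  mall <- export_mosaic(ds, 1, sc, n_top = 100)
  expect_equal(nrow(mall$manifest), 40)
  f <- tempfile(fileext = ".png")
  export_mosaic(ds, 1, sc, n_top = 9, path = f)
  expect_true(file.exists(f))
  expect_equal(dim(png::readPNG(f)), c(36, 36, 3))
  unlink(f)
})
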