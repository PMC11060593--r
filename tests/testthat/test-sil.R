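# SIL pipeline: weak-label training, instance scoring, the fifth-percentile
# threshold rule, and bag classification.

test_that("percent positive uses a strict 0.5 boundary", {
  expect_equal(percent_positive(rep(0.6, 5)), 100)
  expect_equal(percent_positive(rep(0.5, 5)), 0)
  expect_equal(percent_positive(c(0.6, 0.7, 0.9, rep(0.1, 9))), 25)
  expect_error(percent_positive(numeric(0)), "empty")
})

test_that("the threshold is the midpoint of interpolated fifth percentiles", {
  pos <- c(10, 12, 14, 16, 18, 20, 22, 24)
  neg <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5)
  expect_equal(unname(quantile(pos, 0.05, type = 7)), 10.7)
  t_f <- compute_bag_threshold(pos, neg)
  expect_equal(t_f, (10.7 + 0.175) / 2)
  expect_equal(t_f, 5.4375)
  # same list on both sides: the threshold is that list's 5th percentile
  expect_equal(compute_bag_threshold(pos, pos),
               unname(quantile(pos, 0.05, type = 7)))
  # linearity: scaling all inputs scales the threshold
  expect_equal(compute_bag_threshold(3 * pos, 3 * neg), 3 * t_f)
  expect_error(compute_bag_threshold(numeric(0), neg), "non-empty")
})

test_that("threshold equals the brute-force percentile oracle on random lists", {
  set.seed(31)
  for (i in 1:1000) {
    pos <- runif(sample(2:40, 1), 0, 100)
    neg <- runif(sample(2:40, 1), 0, 100)
    expect_equal(compute_bag_threshold(pos, neg), oracle_threshold(pos, neg))
  }
})

test_that("bag classification is strict at the threshold", {
  expect_equal(unname(classify_bags_sil(6.0, 5.4375)), "positive")
  expect_equal(unname(classify_bags_sil(5.4375, 5.4375)), "negative")
  expect_equal(unname(classify_bags_sil(0.1, 0)), "positive")
})

test_that("SIL reaches F1 1.0 within 30 epochs on separable weak labels", {
  # positive bags entirely bright, so even the weak instance labels are
  # separable by a brightness threshold (the oracle classifier is exact)
  ds <- make_toy_dataset(n_pos = 6, n_neg = 6, bag_size = 16, side = 12,
                         seed = 21, all_bright_pos = TRUE)
  # brightness oracle: mean intensity separates the weak classes perfectly
  bright <- apply(ds$images, 4, mean)
  weak_pos <- ds$instances$bag_label == "positive"
  cut <- mean(range(tapply(bright, weak_pos, mean)))
  expect_equal(milbench:::f1_score(as.numeric(bright > cut), weak_pos, 0.5), 1)

  ctl <- sil_control(max_epochs = 30L, min_epoch = 10L, window = 5L,
                     lr = 1e-3, seed = 1)
  m <- sil_fit(ds, toy_fold_plan(), 1, encoder_config("tiny_test"), ctl)
  expect_equal(max(m$val_f1), 1)
  expect_gte(m$selected_epoch, 10)

  # every true key instance of the separable toy scores above 0.5
  sc <- score_instances(m, ds)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  keys <- ds$instances$is_key[match(sc$instance_id, ds$instances$instance_id)]
  expect_true(all(sc$score[keys] > 0.5))

  # reproducibility: same control, same seed, same F1 series
  m2 <- sil_fit(ds, toy_fold_plan(), 1, encoder_config("tiny_test"), ctl)
  expect_identical(m$val_f1, m2$val_f1)
  sc2 <- score_instances(m2, ds)
  expect_identical(sc$score, sc2$score)
})

test_that("the fold threshold never sees test bags", {
  ds <- make_toy_dataset(n_pos = 6, n_neg = 6, bag_size = 16, side = 12,
                         seed = 22, all_bright_pos = TRUE)
  ctl <- sil_control(max_epochs = 12L, min_epoch = 5L, window = 3L,
                     lr = 1e-3, seed = 2)
  r <- sil_run_fold(ds, toy_fold_plan(), 1, encoder_config("tiny_test"), ctl)
  fd <- toy_fold_plan()[[1]]
  labels <- setNames(ds$bags$label, ds$bags$bag_id)
  trval <- as.character(c(fd$train, fd$val))
  # recomputing the threshold from train+val percents alone reproduces t_f
  t_check <- compute_bag_threshold(
    r$percents[trval][labels[trval] == "positive"],
    r$percents[trval][labels[trval] == "negative"])
  expect_identical(r$t_f, t_check)
  expect_named(r$predictions, as.character(fd$test))
})
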