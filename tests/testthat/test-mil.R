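# ABMIL with within-bag sampling: mini-bag draws, inference planning,
# attention pooling, majority voting, and attention aggregation.

test_that("mini-bags are uniform with-replacement draws", {
  expect_length(sample_minibag(1:50, 1), 1)
  expect_error(sample_minibag(integer(0), 5), "empty")
  # pigeonhole: more draws than distinct instances forces duplicates
  set.seed(1)
  mb <- sample_minibag(1:5, 10)
  expect_length(mb, 10)
  expect_true(any(duplicated(mb)))
  # uniformity over 1e5 draws, 3 Monte-Carlo SEs
  set.seed(2)
  draws <- unlist(replicate(2e4, sample_minibag(1:10, 5), simplify = FALSE))
  counts <- table(factor(draws, levels = 1:10))
  expected <- length(draws) / 10
  se <- sqrt(length(draws) * 0.1 * 0.9)
  expect_true(all(abs(counts - expected) < 3 * se))
})

test_that("the inference plan follows the evaluations-per-instance rule", {
  pl <- plan_inference(c(3000, 9300, 5000), m = 500, target_evals = 10)
  expect_equal(pl$M, 186)
  expect_equal(pl$evals_per_instance, 10)
  expect_equal(plan_inference(500, m = 500)$M, 10)
  # doubling the mini-bag size halves the number of mini-bags (up to rounding)
  expect_equal(plan_inference(9300, m = 1000)$M, 93)
  expect_gte(plan_inference(10, m = 1000)$M, 1)
})

test_that("majority vote is strict with ties resolved to positive", {
  expect_equal(predict_bag_majority(rep(c("positive", "negative"),
                                        c(100, 86))), "positive")
  expect_equal(predict_bag_majority(rep("negative", 7)), "negative")
  expect_equal(predict_bag_majority(rep(c("positive", "negative"),
                                        c(93, 93))), "positive")
})

test_that("attention weights normalize per mini-bag and aggregate by majority", {
  expect_equal(milbench:::normalize_minibag_weights(c(0.1, 0.2, 0.4)),
               c(0, 1 / 3, 1))
  expect_equal(milbench:::normalize_minibag_weights(rep(0.25, 4)),
               rep(0.5, 4))
  records <- list(
    list(instance_ids = 1L, weights = 0.2, pred = "positive"),
    list(instance_ids = 1L, weights = 0.8, pred = "positive"),
    list(instance_ids = 1L, weights = 0.9, pred = "negative"))
  ag <- aggregate_instance_attention(records, "positive", 1:2)
  expect_equal(ag$score[1], 0.5)   # mean of the two qualifying weights
  expect_equal(ag$n_evals[1], 2L)
  # instance 2 never appears in a qualifying mini-bag
  expect_equal(ag$score[2], 0)
  expect_false(ag$coverage[2])
  # duplicates within one mini-bag each contribute
  rec2 <- list(list(instance_ids = c(5L, 5L, 6L), weights = c(0, 1, 0.5),
                    pred = "positive"))
  ag2 <- aggregate_instance_attention(rec2, "positive", 5:6)
  expect_equal(ag2$score, c(0.5, 0.5))
  expect_equal(ag2$n_evals, c(2L, 1L))
  expect_true(all(ag2$score >= 0 & ag2$score <= 1))
})

test_that("attention pooling is permutation-equivariant", {
  set.seed(8)
  att <- milbench:::attention_init(6L, 8L)
  E <- matrix(rnorm(6 * 10), 6, 10)
  f <- milbench:::attention_forward(att, E)
  expect_true(all(f$a >= 0))
  expect_equal(sum(f$a), 1)
  perm <- sample(10)
  fp <- milbench:::attention_forward(att, E[, perm])
  expect_equal(fp$logits, f$logits)   # bag score unchanged
  expect_equal(fp$a, f$a[perm])       # weights permuted along
  # single-instance mini-bag concentrates all attention
  f1 <- milbench:::attention_forward(att, E[, 3, drop = FALSE])
  expect_equal(f1$a, 1)
})

test_that("default inference plan leaves under 1% of the largest bag uncovered", {
  n <- 200
  for (seed in 1:5) {
    set.seed(seed)
    pl <- plan_inference(n, m = 50, target_evals = 10)
    seen <- unique(unlist(replicate(pl$M, sample_minibag(1:n, pl$m),
                                    simplify = FALSE)))
    expect_lt((n - length(seen)) / n, 0.01)
  }
})

test_that("ABMIL classifies separable toy bags perfectly at 30% keys", {
  # mini-bag of 20 at 30% keys carries ~6 expected keys, above the
  # reliability floor observed for attention-MIL bag classification
  ds <- make_toy_dataset(n_pos = 6, n_neg = 6, bag_size = 40, side = 16,
                         p = 0.3, seed = 7)
  ctl <- abmil_control(m = 20L, max_epochs = 45L, min_epoch = 20L,
                       window = 15L, lr = 1e-3, val_minibags = 3L, seed = 1)
  r <- abmil_run_fold(ds, toy_fold_plan(), 1, encoder_config("tiny_test"),
                      ctl)
  expect_equal(r$bag_accuracy, 1)
  # aggregated attention is in [0, 1] and ranks keys above non-keys
  for (b in names(r$attention)) {
    at <- r$attention[[b]]
    expect_true(all(at$score >= 0 & at$score <= 1))
  }
  expect_true(all(r$precision_at_k > 0.8))
})
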