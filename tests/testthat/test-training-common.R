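# Standardization, augmentation, encoders, checkpoint selection.

test_that("standardization yields zero-mean unit-sd channels dataset-wide", {
  ds <- make_toy_dataset(n_pos = 2, n_neg = 2, bag_size = 10, side = 12,
                         seed = 3)
  st <- compute_channel_stats(ds)
  z <- standardize(ds$images * 1.0, st)
  for (k in 1:3) {
    v <- as.numeric(z[, , k, ])
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  }
  # idempotence up to the epsilon guard: re-standardizing already
  # standardized data with its own stats changes nothing
  st2 <- list(mean = sapply(1:3, function(k) mean(z[, , k, ])),
              sd = sapply(1:3, function(k) sd(as.numeric(z[, , k, ]))))
  z2 <- standardize(z, st2)
  expect_lt(max(abs(z2 - z)), 1e-3)
  # constant channel is guarded, not divided by zero
  cds <- ds; cds$images[, , 2, ] <- 100L
  stc <- compute_channel_stats(cds)
  zc <- standardize(cds$images * 1.0, stc)
  expect_true(all(is.finite(zc)))
  expect_true(all(zc[, , 2, ] == 0))
})

test_that("training augmentations are permutations plus noise", {
  x <- array(runif(10 * 10 * 3 * 4), c(10, 10, 3, 4))
  off <- augment_config(p_flip_h = 0, p_flip_v = 0, rot90 = FALSE,
                        noise_sd = 0)
  expect_identical(augment_batch(x, off), x)
  # four successive 90-degree rotations are the identity
  r <- x[, , 1, 1]
  for (i in 1:4) r <- milbench:::rot90_plane(r, 1)
  expect_identical(r, x[, , 1, 1])
  # a 90-degree rotation is a pixel permutation: same multiset of values
  r1 <- milbench:::rot90_plane(x[, , 1, 1], 1)
  expect_equal(sort(as.numeric(r1)), sort(as.numeric(x[, , 1, 1])))
  # augmented output of one pass is a valid input to another (closure)
  set.seed(1)
  y <- augment_batch(augment_batch(x, augment_config()), augment_config())
  expect_equal(dim(y), dim(x))
})

test_that("encoders honor shape contracts and seed-deterministic init", {
  for (nm in c("lenet_small", "tiny_test")) {
    cfg <- encoder_config(nm)
    e1 <- milbench:::with_seed(5, build_encoder(cfg, c(40, 40, 3)))
    e2 <- milbench:::with_seed(5, build_encoder(cfg, c(40, 40, 3)))
    expect_identical(milbench:::net_params(e1$layers),
                     milbench:::net_params(e2$layers))
    out <- milbench:::net_forward(e1$layers,
                                  array(rnorm(40 * 40 * 3 * 2),
                                        c(40, 40, 3, 2)), train = FALSE)$out
    expect_equal(dim(out), c(cfg$embedding_dim, 2))
  }
  # lenet_small also accepts the full-scale 80x80 input
  e80 <- build_encoder(encoder_config("lenet_small"), c(80, 80, 3))
  out80 <- milbench:::net_forward(e80$layers,
                                  array(0, c(80, 80, 3, 1)), FALSE)$out
  expect_equal(nrow(out80), 500)
  # deeper backbones construct for both input sizes and emit 512 features
  for (nm in c("resnet18", "squeezenet")) {
    for (side in c(40, 80)) {
      e <- build_encoder(encoder_config(nm), c(side, side, 3))
      out <- milbench:::net_forward(e$layers, array(rnorm(side * side * 3),
                                                    c(side, side, 3, 1)),
                                    train = TRUE)$out
      expect_equal(nrow(out), 512)
    }
  }
  expect_error(encoder_config("vgg"), "should be one of|arg")
})

test_that("checkpoint selection matches exhaustive window search", {
  # monotonically increasing series: last epoch wins
  expect_equal(select_checkpoint(seq(0, 1, length.out = 60)), 60)
  # never selects before min_epoch
  set.seed(99)
  for (i in 1:200) {
    s <- runif(sample(40:200, 1))
    sel <- select_checkpoint(s, window = 15, min_epoch = 20)
    expect_gte(sel, 20)
    expect_equal(sel, oracle_select(s, 15, 20, maximize = TRUE))
    selmin <- select_checkpoint(s, window = 15, min_epoch = 20,
                                mode = "minimize")
    expect_equal(selmin, oracle_select(s, 15, 20, maximize = FALSE))
  }
  # short series falls back to the best epoch at or after min_epoch
  s <- c(runif(25))
  expect_warning(sel <- select_checkpoint(s, window = 15, min_epoch = 20),
                 "falling back")
  expect_equal(sel, 19 + which.max(s[20:25]))
  expect_error(select_checkpoint(runif(10), min_epoch = 20), "longer")
})
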