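# Synthetic bag generation: glyph pools, color model, transforms, assembly,
# key-instance exclusivity, and dataset I/O.

test_that("glyph pool renders labeled 8-bit images and splits cleanly", {
  pool <- glyph_pool(60, seed = 1)
  expect_equal(dim(pool$images), c(28, 28, 60))
  expect_true(all(pool$images >= 0 & pool$images <= 255))
  expect_true(all(pool$labels %in% 0:9))
  # glyph classes are visually distinct: mean pairwise pixel difference
  # between a clean 4 and a clean 1 is substantial
  g4 <- milbench:::render_glyph(4, jitter = FALSE)
  g1 <- milbench:::render_glyph(1, jitter = FALSE)
  expect_gt(mean(abs(g4 - g1)), 10)

  test_pool <- glyph_pool(100, seed = 2)
  sp <- split_source_pool(pool, test_pool, val_frac = 0.2, seed = 3)
  expect_equal(length(sp$val_pool$labels), 20)
  expect_equal(length(sp$test_pool$labels), 80)
  # disjoint and exhaustive partition of the test pool
  expect_equal(sort(c(sp$val_pool$labels, sp$test_pool$labels)),
               sort(test_pool$labels))
  sp2 <- split_source_pool(pool, test_pool, val_frac = 0.2, seed = 3)
  expect_identical(sp$val_pool$images, sp2$val_pool$images)
})

test_that("channel model fitting recovers moments and flags degenerate input", {
  set.seed(42)
  # blue channel drawn from N(120, 10): fitted mean within 0.2 at 1e5 pixels
  n <- 40L
  imgs <- array(0, c(50, 50, 3, n))  # 1e5 pixels per channel
  imgs[, , 1, ] <- pmin(255, pmax(0, 110 + 20 * abs(rnorm(2500 * n))))
  imgs[, , 2, ] <- 100  # constant green
  imgs[, , 3, ] <- rnorm(2500 * n, 120, 10)
  expect_warning(m <- fit_channel_models(imgs), "degenerate")
  expect_equal(m$green[1], 100)
  expect_equal(m$green[2], 0)
  expect_lt(abs(m$blue[1] - 120), 0.2)
  expect_lt(abs(m$blue[2] - 10), 0.2)
  # red was built right-skewed: fitted skew-normal shape must be positive
  expect_gt(m$red[3], 0)
  expect_error(fit_channel_models(list()), "at least 2|length")
})

test_that("colorization samples only the central quantile interval", {
  mod <- channel_color_model(green = c(150, 20), blue = c(180, 15),
                             red = c(100, 30, 5),
                             tail_quantiles = c(0.025, 0.975))
  set.seed(7)
  bg <- milbench:::sample_background(mod, 5000)
  expect_true(all(bg["green", ] >= qnorm(0.025, 150, 20) - 1e-9))
  expect_true(all(bg["green", ] <= qnorm(0.975, 150, 20) + 1e-9))
  expect_true(all(bg["blue", ] >= qnorm(0.025, 180, 15) - 1e-9))
  expect_true(all(bg["red", ] >= mod$red_bounds[1] - 1e-6))
  expect_true(all(bg["red", ] <= mod$red_bounds[2] + 1e-6))
  # the truncated red sample stays strictly inside the untruncated range
  expect_gt(min(bg["red", ]), 100 - 3 * 30)

  # degenerate model: constant background color, uniform image
  degm <- channel_color_model(green = c(80, 0), blue = c(90, 0),
                              red = c(70, 0, 0))
  img <- colorize_glyph(matrix(0, 8, 8), degm)
  expect_equal(unname(img[1, 1, ]), c(70, 80, 90), tolerance = 1e-6)
  expect_true(all(apply(img, 3, function(m) diff(range(m)) == 0)))

  # foreground is a darker blend of the background color
  img2 <- colorize_glyph(matrix(255, 8, 8), degm, blend = 0.85)
  expect_equal(unname(img2[1, 1, ]), c(70, 80, 90) * 0.15, tolerance = 1e-6)
})

test_that("rescaling is bilinear and preserves constants and fixed points", {
  g <- matrix(as.integer(round(runif(28 * 28) * 255)), 28, 28)
  expect_identical(rescale_glyph(g, 28), g)
  up <- rescale_glyph(g, 80)
  expect_equal(dim(up), c(80, 80))
  const <- matrix(37, 28, 28)
  expect_true(all(abs(rescale_glyph(const, 80) - 37) < 1e-9))
  expect_error(rescale_glyph(g, 0), "positive")
  expect_error(rescale_glyph(g, 14), "source side")
})

test_that("creation transforms are seeded, clipped, and identity at p = 0", {
  img <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  off <- creation_transform_config(p_rotate = 0, p_blur = 0, p_noise = 0,
                                   p_scale = 0)
  expect_identical(apply_creation_transforms(img, off), img)
  cfg <- creation_transform_config()
  set.seed(11); a <- apply_creation_transforms(img, cfg)
  set.seed(11); b <- apply_creation_transforms(img, cfg)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 255))
  # rotation by a full turn is a near-identity away from the border
  rot360 <- milbench:::rotate_plane(img[, , 1], 360)
  expect_lt(max(abs(rot360 - img[, , 1])), 1e-8)
})

test_that("key fractions follow the fixed and beta laws", {
  fixed <- key_fraction_model("fixed", 0.2)
  expect_identical(sample_key_fraction(fixed, "negative"), 0)
  expect_equal(replicate(5, sample_key_fraction(fixed, "positive")),
               rep(0.2, 5))
  for (par in list(c(9.932, 46.82), c(2.352, 11.086))) {
    bm <- key_fraction_model("beta", alpha = par[1], beta = par[2])
    expect_identical(sample_key_fraction(bm, "negative"), 0)
    set.seed(105)
    draws <- replicate(1e5, sample_key_fraction(bm, "positive"))
    mu <- par[1] / sum(par)
    sg <- sqrt(par[1] * par[2] / (sum(par)^2 * (sum(par) + 1)))
    se <- sg / sqrt(1e5)
    expect_lt(abs(mean(draws) - mu), 3 * se)
    # sd of the sample sd is approx sg / sqrt(2 (n - 1)) for moderate skew;
    # allow a generous factor
    expect_lt(abs(sd(draws) - sg), 5 * sg / sqrt(2 * (1e5 - 1)))
  }
})

test_that("assembled bags respect geometry, composition, and exclusivity", {
  ds <- generate_bag_dataset(
    bag_geometry(3, 3, bag_size = 50, image_side = 32),
    key_fraction_model("fixed", 0.2), seed = 9)
  expect_equal(nrow(ds$bags), 6)
  expect_equal(sum(ds$bags$label == "positive"), 3)
  expect_equal(nrow(ds$instances), 300)
  expect_equal(dim(ds$images), c(32, 32, 3, 300))
  # positive bag of size 50 at p = 0.2 holds exactly 10 key-digit instances
  for (b in ds$bags$bag_id[ds$bags$label == "positive"]) {
    expect_equal(sum(ds$instances$is_key[ds$instances$bag_id == b]), 10)
  }
  # negative bags contain no key digit at all
  neg <- ds$instances[ds$instances$bag_label == "negative", ]
  expect_equal(sum(neg$glyph_class == 4), 0)
  # key-instance exclusivity over the manifest
  expect_true(all(ds$instances$bag_label[ds$instances$is_key] == "positive"))
  expect_false(any(duplicated(ds$instances$instance_id)))
  expect_equal(sum(ds$bags$size), nrow(ds$instances))
  # insufficient pool errors with the shortfall
  small <- glyph_pool(30, seed = 1)
  expect_error(
    assemble_bags(small, key_fraction_model("fixed", 0.2),
                  channel_color_model(),
                  bag_geometry(3, 3, bag_size = 50, image_side = 32)),
    "insufficient")
})

test_that("key-instance exclusivity and determinism hold for every seed", {
  for (seed in c(2, 13, 77)) {
    ds <- generate_bag_dataset(
      bag_geometry(2, 2, bag_size = 20, image_side = 28),
      key_fraction_model("beta", alpha = 9.932, beta = 46.82), seed = seed)
    expect_true(all(ds$instances$bag_label[ds$instances$is_key] == "positive"))
    expect_true(all(ds$instances$is_key ==
                      (ds$instances$glyph_class == 4 &
                         ds$instances$bag_label == "positive")))
    # positive bags at beta-drawn fractions still hold at least one key
    pos <- ds$bags[ds$bags$label == "positive", ]
    expect_true(all(pos$n_key >= 1))
  }
  a <- generate_bag_dataset(bag_geometry(2, 2, bag_size = 15, image_side = 28),
                            seed = 4)
  b <- generate_bag_dataset(bag_geometry(2, 2, bag_size = 15, image_side = 28),
                            seed = 4)
  expect_identical(a$images, b$images)
  expect_identical(a$instances, b$instances)
  expect_identical(make_fold_plan(data.frame(bag_id = 1:24,
                                             label = rep(c("positive",
                                                           "negative"),
                                                         each = 12)),
                                  seed = 4)[[5]],
                   make_fold_plan(data.frame(bag_id = 1:24,
                                             label = rep(c("positive",
                                                           "negative"),
                                                         each = 12)),
                                  seed = 4)[[5]])
})

test_that("dataset round-trips through PNG + manifest exactly", {
  ds <- generate_bag_dataset(bag_geometry(2, 2, bag_size = 8, image_side = 28),
                             seed = 3)
  dir <- tempfile("ds_io_")
  write_bag_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), nrow(ds$instances))
  back <- read_bag_dataset(dir)
  expect_identical(back$images, ds$images)
  expect_equal(back$instances$is_key, ds$instances$is_key)
  expect_equal(back$instances$bag_id, ds$instances$bag_id)
  # a missing image file is reported with the record
  unlink(list.files(file.path(dir, "bags"), recursive = TRUE,
                    full.names = TRUE)[1])
  expect_error(read_bag_dataset(dir), "missing image")
  unlink(dir, recursive = TRUE)
})
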