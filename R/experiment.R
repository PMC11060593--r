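# Experiment orchestration: generate a dataset once, build one fold plan,
# and run the requested method / encoder / mini-bag combinations on the SAME
# data, so the two learners are always compared on identical bags and folds.

#' Generate a complete synthetic bag dataset
#'
#' Sizes and renders a glyph source pool sufficient for the requested
#' geometry (with a safety margin on the key class), then assembles,
#' colorizes and transforms the bags. One master seed drives pool
#' rendering, bag assembly, color sampling and transforms through named
#' sub-streams.
#'
#' @param geometry A [bag_geometry()].
#' @param kf_model A [key_fraction_model()].
#' @param color_model A [channel_color_model()].
#' @param transforms A [creation_transform_config()].
#' @param seed Master seed.
#' @param pool Optional pre-built [glyph_pool()]; sized automatically when
#'   `NULL`.
#' @return A `bag_dataset`.
#' @export
generate_bag_dataset <- function(geometry = bag_geometry(),
                                 kf_model = key_fraction_model("fixed", 0.2),
                                 color_model = channel_color_model(),
                                 transforms = creation_transform_config(),
                                 seed = 1L, pool = NULL) {
  if (is.null(pool)) {
    n_bags <- geometry$n_pos + geometry$n_neg
    est_total <- if (identical(geometry$bag_size, "lognormal")) {
      ceiling(1.35 * n_bags * geometry$bag_size_mean)
    } else {
      n_bags * geometry$bag_size
    }
    kf_cap <- if (kf_model$mode == "fixed") kf_model$p else {
      mu <- kf_model$alpha / (kf_model$alpha + kf_model$beta)
      s <- sqrt(kf_model$alpha * kf_model$beta /
                  ((kf_model$alpha + kf_model$beta)^2 *
                     (kf_model$alpha + kf_model$beta + 1)))
      min(1, mu + 4 * s)
    }
    need_key <- ceiling(est_total / 2 * max(kf_cap, 0.02) * 1.2) + 10L
    need_oth <- ceiling(est_total * 1.05) + 10L
    others <- setdiff(0:9, geometry$key_digit)
    labels <- c(rep(geometry$key_digit, need_key),
                rep(others, length.out = need_oth))
    pool <- glyph_pool(seed = derive_seed(seed, "pool"), labels = labels)
  }
  assemble_bags(pool, kf_model, color_model, geometry, transforms, seed = seed)
}

#' Desk-scale experiment preset
#'
#' The default configuration: 24 bags (12 positive + 12 negative) of 300
#' instances each, 40 x 40 pixel images, fixed 20% key fraction, the
#' `tiny_test` encoder (12/24 conv maps, 96-wide embedding), SIL capped at
#' 50 epochs and ABMIL at 60 epochs with mini-bag size 100 — sized to run
#' on a single CPU. The desk SIL control uses stronger regularization
#' (weight decay 1e-4, embedding dropout 0.3, augmentation noise sd 0.2)
#' than the full-scale defaults: with only 3,600 training instances per
#' fold the classifier otherwise memorizes its training bags, which biases
#' the percentile threshold computed from them. `fullscale_config()`
#' gives the full-scale geometry (80 x 80 images, lognormal bag sizes with
#' mean 9300, `lenet_small`, 150/1500 epoch caps), which is intended for
#' GPU-class budgets.
#'
#' @param key_fraction Fixed key fraction (or a [key_fraction_model()]).
#' @param seed Master seed.
#' @return A named configuration list consumed by [run_experiment()].
#' @export
desk_config <- function(key_fraction = 0.2, seed = 1L) {
  kf <- if (inherits(key_fraction, "key_fraction_model")) key_fraction else
    key_fraction_model("fixed", key_fraction)
  list(geometry = bag_geometry(12L, 12L, bag_size = 300L, image_side = 40L),
       kf_model = kf,
       color_model = channel_color_model(),
       transforms = creation_transform_config(),
       encoder = encoder_config("tiny_test", 96L, filters = c(12L, 24L)),
       sil = sil_control(max_epochs = 50L, lr = 1e-3, weight_decay = 1e-4,
                         dropout = 0.3,
                         augment = augment_config(noise_sd = 0.2),
                         early_stop_patience = 15L, seed = seed),
       abmil = abmil_control(m = 100L, max_epochs = 60L, lr = 1e-3,
                             early_stop_patience = 15L, seed = seed),
       methods = c("sil", "abmil"),
       folds = 1:9,
       seed = seed)
}

#' @rdname desk_config
#' @export
fullscale_config <- function(key_fraction = 0.2, seed = 1L) {
  cfg <- desk_config(key_fraction, seed)
  cfg$geometry <- bag_geometry(12L, 12L, bag_size = "lognormal",
                               bag_size_mean = 9300, image_side = 80L)
  cfg$encoder <- encoder_config("lenet_small")
  cfg$sil <- sil_control(max_epochs = 150L, seed = seed)
  cfg$abmil <- abmil_control(m = 500L, max_epochs = 1500L, seed = seed)
  cfg
}

#' Read an experiment configuration file
#'
#' Loads a YAML (or JSON) configuration and merges it over a preset.
#' Recognized keys: `preset` ("desk" or "fullscale"), `seed`,
#' `key_fraction` (a number, or a map with `mode`/`p`/`alpha`/`beta`),
#' `methods`, `folds`, `encoder` (a name for [encoder_config()]),
#' `minibag_size`, `sil_epochs`, `abmil_epochs`.
#'
#' @param path Configuration file path.
#' @return A configuration list as from [desk_config()].
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  seed <- cfg$seed %||% 1L
  kf <- cfg$key_fraction
  kfm <- if (is.null(kf)) {
    key_fraction_model("fixed", 0.2)
  } else if (is.numeric(kf)) {
    key_fraction_model("fixed", kf)
  } else if (identical(kf$mode, "beta")) {
    key_fraction_model("beta", alpha = kf$alpha, beta = kf$beta)
  } else {
    key_fraction_model("fixed", kf$p %||% 0.2)
  }
  base <- if (identical(cfg$preset, "fullscale")) {
    fullscale_config(kfm, seed)
  } else {
    desk_config(kfm, seed)
  }
  if (!is.null(cfg$methods)) base$methods <- cfg$methods
  if (!is.null(cfg$folds)) base$folds <- as.integer(cfg$folds)
  if (!is.null(cfg$encoder)) base$encoder <- encoder_config(cfg$encoder)
  if (!is.null(cfg$minibag_size)) base$abmil$m <- as.integer(cfg$minibag_size)
  if (!is.null(cfg$sil_epochs)) base$sil$max_epochs <- as.integer(cfg$sil_epochs)
  if (!is.null(cfg$abmil_epochs)) {
    base$abmil$max_epochs <- as.integer(cfg$abmil_epochs)
  }
  base
}

#' Run a full benchmark experiment
#'
#' Generates the dataset and fold plan once, runs every requested method on
#' every requested fold on that same data, and writes per-run scores,
#' predictions and metrics under `out_dir` (CSV/JSON). Re-running with the
#' same config and seed reproduces the outputs bit-identically.
#'
#' @param config A configuration list as from [desk_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return List with the `dataset`, `plan`, per-method per-fold `runs`, and
#'   a fold-aggregated `report` (mean and sd of bag accuracy and
#'   Precision@K per method).
#' @export
run_experiment <- function(config = desk_config(), out_dir = NULL) {
  dataset <- generate_bag_dataset(config$geometry, config$kf_model,
                                  config$color_model, config$transforms,
                                  seed = config$seed)
  plan <- make_fold_plan(dataset, seed = config$seed)
  runs <- list()
  for (method in config$methods) {
    for (f in config$folds) {
      key <- sprintf("%s_fold%d", method, f)
      runs[[key]] <- if (method == "sil") {
        sil_run_fold(dataset, plan, f, config$encoder, config$sil)
      } else {
        abmil_run_fold(dataset, plan, f, config$encoder, config$abmil)
      }
      if (!is.null(out_dir)) {
        dir.create(file.path(out_dir, key), recursive = TRUE,
                   showWarnings = FALSE)
        r <- runs[[key]]
        if (method == "sil") {
          write.csv(r$scores, file.path(out_dir, key, "scores.csv"),
                    row.names = FALSE)
          jsonlite::write_json(list(t_f = r$t_f),
                               file.path(out_dir, key, "thresholds.json"),
                               auto_unbox = TRUE, digits = NA)
        } else {
          att <- do.call(rbind, lapply(names(r$attention), function(b) {
            cbind(bag_id = as.integer(b), r$attention[[b]], fold = f)
          }))
          write.csv(att, file.path(out_dir, key, "attention.csv"),
                    row.names = FALSE)
        }
        write.csv(data.frame(bag_id = names(r$predictions),
                             predicted = unname(r$predictions)),
                  file.path(out_dir, key, "bag_predictions.csv"),
                  row.names = FALSE)
      }
    }
  }
  report <- do.call(rbind, lapply(config$methods, function(method) {
    keys <- sprintf("%s_fold%d", method, config$folds)
    acc <- vapply(runs[keys], `[[`, numeric(1), "bag_accuracy")
    pk <- vapply(runs[keys], function(r) mean(r$precision_at_k), numeric(1))
    sa <- suppressWarnings(summarize_folds(acc))
    sp <- suppressWarnings(summarize_folds(pk))
    data.frame(method = method,
               bag_accuracy_mean = sa$mean, bag_accuracy_sd = sa$sd,
               precision_at_k_mean = sp$mean, precision_at_k_sd = sp$sd,
               n_folds = sa$n)
  }))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(dataset = dataset, plan = plan, runs = runs, report = report)
}
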