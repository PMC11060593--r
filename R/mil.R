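# Attention-based multiple instance learning with within-bag sampling.
# Original bags (up to thousands of instances) are too large to embed in
# one pass, so training and inference operate on fixed-size mini-bags drawn
# with replacement from a bag.  The bag embedding is the attention-weighted
# sum of instance embeddings (two-layer tanh attention, softmax-normalized
# over the mini-bag); test bags are labeled by majority vote over mini-bag
# predictions, and per-instance attention is aggregated for key-instance
# ranking.

#' Sample a mini-bag
#'
#' `m` independent uniform draws with replacement from the bag's instances
#' (duplicates allowed and expected when `m` approaches or exceeds the bag
#' size).
#'
#' @param instance_ids The bag's instance ids.
#' @param m Mini-bag size.
#' @return Integer vector of length `m`.
#' @export
sample_minibag <- function(instance_ids, m) {
  if (length(instance_ids) == 0) stop("empty bag")
  stopifnot(m >= 1)
  sample(instance_ids, m, replace = TRUE)
}

#' Plan the number of inference mini-bags
#'
#' `M = round(target_evals * N_max / m)` where `N_max` is the largest bag
#' size, so that each instance of the largest bag is evaluated approximately
#' `target_evals` times; the same `M` applies to every bag.
#'
#' @param bag_sizes Instance counts of all bags.
#' @param m Mini-bag size.
#' @param target_evals Expected evaluations per instance of the largest bag
#'   (default 10).
#' @return List with `m`, `M` (>= 1), `n_max`, and `evals_per_instance`
#'   (`M * m / n_max`, the realized expectation for the largest bag).
#' @export
plan_inference <- function(bag_sizes, m, target_evals = 10) {
  stopifnot(length(bag_sizes) >= 1, m >= 1)
  n_max <- max(bag_sizes)
  M <- max(1L, as.integer(round(target_evals * n_max / m)))
  list(m = as.integer(m), M = M, n_max = n_max,
       evals_per_instance = M * m / n_max)
}

#' Majority-voted bag label
#'
#' The label with strictly more mini-bag votes wins; an exact tie resolves
#' to positive (favoring sensitivity, like the fifth-percentile rule on the
#' SIL side).
#'
#' @param pred_labels Character vector of per-mini-bag predicted labels.
#' @return `"positive"` or `"negative"`.
#' @export
predict_bag_majority <- function(pred_labels) {
  stopifnot(length(pred_labels) >= 1)
  npos <- sum(pred_labels == "positive")
  if (npos >= length(pred_labels) / 2) "positive" else "negative"
}

# Min-max normalize attention weights within one mini-bag to [0, 1]; if all
# weights are equal the normalization is degenerate and all weights map to
# the neutral mid-range 0.5.
normalize_minibag_weights <- function(w) {
  rng <- range(w)
  if (rng[2] - rng[1] < 1e-12) return(rep(0.5, length(w)))
  (w - rng[1]) / (rng[2] - rng[1])
}

#' Aggregate per-instance attention over a bag's mini-bags
#'
#' Averages the min-max-normalized attention weights of each instance over
#' the qualifying mini-bags only — those whose predicted label equals the
#' bag's majority label. Duplicate draws of an instance within one mini-bag
#' each contribute their weight. Instances never seen in a qualifying
#' mini-bag get score 0 and `coverage = FALSE`.
#'
#' @param records List of mini-bag records, each a list with `instance_ids`,
#'   `weights` (already normalized to [0, 1]) and `pred` (predicted label).
#' @param majority_label The bag's majority-voted label.
#' @param instance_ids All instance ids of the bag.
#' @return data.frame (instance_id, score, n_evals, coverage).
#' @export
aggregate_instance_attention <- function(records, majority_label,
                                         instance_ids) {
  acc <- setNames(numeric(length(instance_ids)), instance_ids)
  cnt <- setNames(numeric(length(instance_ids)), instance_ids)
  qual <- Filter(function(r) r$pred == majority_label, records)
  if (length(qual) > 0) {
    ids <- as.character(unlist(lapply(qual, `[[`, "instance_ids")))
    w <- unlist(lapply(qual, `[[`, "weights"))
    sums <- rowsum(w, group = ids)
    n <- rowsum(rep(1, length(ids)), group = ids)
    acc[rownames(sums)] <- sums[, 1L]
    cnt[rownames(n)] <- n[, 1L]
  }
  score <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  data.frame(instance_id = instance_ids, score = unname(score),
             n_evals = as.integer(unname(cnt)), coverage = unname(cnt > 0))
}

#' ABMIL training control parameters
#'
#' @param m Mini-bag size (the study uses 500, 1200, 2500 at full scale).
#' @param max_epochs Maximum training epochs (default 1500); one epoch draws
#'   one mini-bag per training bag.
#' @param lr,weight_decay Adam learning rate and weight decay.
#' @param window,min_epoch Checkpoint selection parameters (15, 20).
#' @param target_evals Inference evaluations per instance of the largest
#'   bag (default 10).
#' @param att_dim Attention hidden width.
#' @param gated Use the gated attention variant.
#' @param val_minibags Mini-bags sampled per validation bag for the
#'   per-epoch validation classification error (mini-bag level).
#' @param early_stop_patience As in [sil_control()]; counts epochs since the
#'   lowest validation error.
#' @param augment An [augment_config()].
#' @param seed Master seed.
#' @param checkpoint_dir,verbose As in [sil_control()].
#' @export
abmil_control <- function(m = 500L, max_epochs = 1500L, lr = 1e-4,
                          weight_decay = 1e-5, window = 15L, min_epoch = 20L,
                          target_evals = 10, att_dim = 128L, gated = FALSE,
                          val_minibags = 3L, early_stop_patience = Inf,
                          augment = augment_config(), seed = 1L,
                          checkpoint_dir = NULL, verbose = FALSE) {
  list(m = as.integer(m), max_epochs = as.integer(max_epochs), lr = lr,
       weight_decay = weight_decay, window = as.integer(window),
       min_epoch = as.integer(min_epoch), target_evals = target_evals,
       att_dim = as.integer(att_dim), gated = gated,
       val_minibags = as.integer(val_minibags),
       early_stop_patience = early_stop_patience, augment = augment,
       seed = seed, checkpoint_dir = checkpoint_dir, verbose = verbose)
}

abmil_forward_minibag <- function(layers, att, x, train = TRUE) {
  fe <- net_forward(layers, x, train = train)
  af <- attention_forward(att, fe$out)
  list(logits = af$logits, a = af$a, enc_caches = fe$caches,
       att_cache = af$cache)
}

#' Fit an attention-MIL model with within-bag sampling for one fold
#'
#' Each training step samples one mini-bag per training bag, embeds its
#' instances, pools them by softmax attention into a bag embedding, and
#' minimizes bag-level cross-entropy. Validation classification error is
#' measured on mini-bags sampled from the validation bags; the inference
#' checkpoint is chosen by [select_checkpoint()] (minimize error).
#'
#' @inheritParams sil_fit
#' @param control An [abmil_control()].
#' @return An object of class `abmil_model`.
#' @export
abmil_fit <- function(dataset, plan, fold,
                      encoder = encoder_config("lenet_small"),
                      control = abmil_control()) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1, fold <= length(plan))
  fd <- plan[[fold]]
  inst <- dataset$instances
  bag_inst <- split(inst$instance_id, inst$bag_id)
  labels <- setNames(dataset$bags$label, dataset$bags$bag_id)
  if (length(fd$train) == 0) stop("empty train split")
  stats <- compute_channel_stats(dataset)
  std <- standardize(dataset$images * 1.0, stats)
  side <- dim(dataset$images)[1]
  m <- control$m

  init <- with_seed(derive_seed(control$seed, paste0("abmil-init-", fold)), {
    e <- build_encoder(encoder, c(side, side, 3L))
    list(layers = e$layers,
         att = attention_init(e$embedding_dim, control$att_dim,
                              gated = control$gated))
  })
  layers <- init$layers
  att <- init$att

  ckdir <- control$checkpoint_dir %||% tempfile("abmil_ckpt_")
  dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)
  nested <- list(enc = net_params(layers), att = attention_params(att))
  flat <- flatten_params(nested)
  opt <- adam_init(flat, lr = control$lr, weight_decay = control$weight_decay)

  errs <- numeric(0)
  best_err <- Inf; best_epoch <- 0L
  with_seed(derive_seed(control$seed, paste0("abmil-train-", fold)), {
    for (epoch in seq_len(control$max_epochs)) {
      for (b in sample(fd$train)) {
        ids <- sample_minibag(bag_inst[[as.character(b)]], m)
        x <- augment_batch(std[, , , ids, drop = FALSE], control$augment)
        y <- if (labels[as.character(b)] == "positive") 2L else 1L
        fw <- abmil_forward_minibag(layers, att, x, train = TRUE)
        ls <- ce_loss(fw$logits, y)
        ab <- attention_backward(att, ls$dlogits, fw$att_cache)
        bwd <- net_backward(layers, ab$dE, fw$enc_caches)
        gflat <- flatten_params(list(enc = bwd$grads, att = ab$grads))
        st <- adam_step(opt, flat, gflat)
        opt <- st$opt; flat <- st$params
        nested <- unflatten_into(nested, flat)
        layers <- net_set_params(layers, nested$enc)
        att <- attention_set_params(att, nested$att)
      }
      # validation mini-bag classification error
      nerr <- 0L; ntot <- 0L
      for (b in fd$val) {
        for (r in seq_len(control$val_minibags)) {
          ids <- sample_minibag(bag_inst[[as.character(b)]], m)
          fw <- abmil_forward_minibag(layers, att,
                                      std[, , , ids, drop = FALSE],
                                      train = FALSE)
          pred <- if (fw$logits[2L] > fw$logits[1L]) "positive" else "negative"
          nerr <- nerr + (pred != labels[as.character(b)])
          ntot <- ntot + 1L
        }
      }
      errs[epoch] <- nerr / max(ntot, 1L)
      if (control$verbose) {
        message(sprintf("epoch %4d  val err %.3f", epoch, errs[epoch]))
      }
      if (epoch >= control$min_epoch && errs[epoch] < best_err) {
        best_err <- errs[epoch]; best_epoch <- epoch
      }
      if (epoch >= control$min_epoch) {
        saveRDS(flat, file.path(ckdir, sprintf("epoch_%04d.rds", epoch)))
      }
      if (is.finite(control$early_stop_patience) &&
          epoch >= control$min_epoch + control$window &&
          (epoch - best_epoch) >= control$early_stop_patience) {
        break
      }
    }
  })

  sel <- select_checkpoint(errs, window = control$window,
                           min_epoch = control$min_epoch, mode = "minimize")
  flat <- readRDS(file.path(ckdir, sprintf("epoch_%04d.rds", sel)))
  nested <- unflatten_into(nested, flat)
  layers <- net_set_params(layers, nested$enc)
  att <- attention_set_params(att, nested$att)
  unlink(ckdir, recursive = TRUE)

  structure(list(layers = layers, att = att, stats = stats,
                 encoder = encoder, fold = fold, splits = fd, m = m,
                 val_error = errs, selected_epoch = sel, control = control),
            class = "abmil_model")
}

#' @export
print.abmil_model <- function(x, ...) {
  cat(sprintf(paste0("abmil_model (%s encoder, mini-bag size %d), fold %d: ",
                     "trained %d epochs, selected epoch %d (val error %.3f)\n"),
              x$encoder$name, x$m, x$fold, length(x$val_error),
              x$selected_epoch, x$val_error[x$selected_epoch]))
  invisible(x)
}

#' @export
plot.abmil_model <- function(x, ...) {
  plot(seq_along(x$val_error), x$val_error, type = "l", xlab = "epoch",
       ylab = "validation error", main = sprintf("ABMIL fold %d", x$fold), ...)
  graphics::abline(v = x$selected_epoch, lty = 2)
  invisible(x)
}

#' Mini-bag inference for one bag
#'
#' Draws `M` mini-bags with replacement, predicts each, and records
#' per-instance attention weights min-max normalized to [0, 1] within each
#' mini-bag.
#'
#' @param model An [abmil_fit()] result.
#' @param dataset The `bag_dataset`.
#' @param bag_id Bag to infer.
#' @param M Number of inference mini-bags (from [plan_inference()]).
#' @return List of mini-bag records (`instance_ids`, `weights`, `pred`).
#' @export
abmil_infer_bag <- function(model, dataset, bag_id, M, std = NULL) {
  std <- std %||% standardize(dataset$images * 1.0, model$stats)
  ids_all <- dataset$instances$instance_id[dataset$instances$bag_id == bag_id]
  records <- vector("list", M)
  for (r in seq_len(M)) {
    ids <- sample_minibag(ids_all, model$m)
    x <- std[, , , ids, drop = FALSE]
    fw <- abmil_forward_minibag(model$layers, model$att, x, train = FALSE)
    records[[r]] <- list(
      instance_ids = ids,
      weights = normalize_minibag_weights(fw$a),
      pred = if (fw$logits[2L] > fw$logits[1L]) "positive" else "negative")
  }
  records
}

#' @export
predict.abmil_model <- function(object, dataset, bag_ids = NULL,
                                target_evals = NULL, ...) {
  bag_ids <- bag_ids %||% object$splits$test
  pl <- plan_inference(dataset$bags$size, object$m,
                       target_evals %||% object$control$target_evals)
  std <- standardize(dataset$images * 1.0, object$stats)
  out <- lapply(bag_ids, function(b) {
    rec <- abmil_infer_bag(object, dataset, b, pl$M, std = std)
    maj <- predict_bag_majority(vapply(rec, `[[`, "", "pred"))
    ids <- dataset$instances$instance_id[dataset$instances$bag_id == b]
    att <- aggregate_instance_attention(rec, maj, ids)
    list(bag_id = b, label = maj, attention = att)
  })
  names(out) <- bag_ids
  out
}

#' Run the full ABMIL chain on one fold
#'
#' Trains the attention-MIL model, infers every test bag with the
#' mini-bag inference plan, majority-votes bag labels, aggregates attention
#' for key-instance ranking, and evaluates bag accuracy and Precision@K
#' for the truly positive test bags.
#'
#' @inheritParams abmil_fit
#' @return List with the fitted `model`, per-bag `predictions`, the
#'   aggregated `attention` tables, `bag_accuracy` and `precision_at_k`.
#' @export
abmil_run_fold <- function(dataset, plan, fold,
                           encoder = encoder_config("lenet_small"),
                           control = abmil_control()) {
  model <- abmil_fit(dataset, plan, fold, encoder, control)
  fd <- plan[[fold]]
  labels <- setNames(dataset$bags$label, dataset$bags$bag_id)
  preds <- with_seed(derive_seed(control$seed, paste0("abmil-infer-", fold)),
                     predict(model, dataset, fd$test))
  pred_labels <- vapply(preds, `[[`, "", "label")
  acc <- bag_accuracy(pred_labels, labels[as.character(fd$test)])
  pos_test <- fd$test[labels[as.character(fd$test)] == "positive"]
  pk <- vapply(pos_test, function(b) {
    at <- preds[[as.character(b)]]$attention
    keys <- dataset$instances$is_key[match(at$instance_id,
                                           dataset$instances$instance_id)]
    precision_at_k(at$score, keys, k = sum(keys),
                   predicted_positive =
                     preds[[as.character(b)]]$label == "positive",
                   instance_ids = at$instance_id)
  }, numeric(1))
  list(model = model, predictions = pred_labels,
       attention = lapply(preds, `[[`, "attention"),
       bag_accuracy = acc, precision_at_k = setNames(pk, pos_test))
}
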