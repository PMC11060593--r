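# Single-instance learning (SIL): a CNN instance classifier trained on weak
# bag-inherited labels, with bag labels derived from the fraction of
# positively classified instances via a fifth-percentile threshold rule.

#' SIL training control parameters
#'
#' @param batch_size Mini-batch size (default 56).
#' @param max_epochs Maximum training epochs (default 150).
#' @param lr,weight_decay Adam learning rate and weight decay.
#' @param lr_decay_epoch,lr_decay_factor Step decay: from `lr_decay_epoch`
#'   on, the learning rate is multiplied by `lr_decay_factor` (1 = none).
#' @param window,min_epoch Checkpoint-selection moving-average window and
#'   earliest selectable epoch (defaults 15 and 20).
#' @param early_stop_patience Stop when the best validation F1 has not
#'   improved for this many epochs (only once a full selection window is
#'   available); `Inf` disables early stopping.
#' @param augment An [augment_config()] applied to training batches.
#' @param dropout Dropout probability on the embedding during training
#'   (0 disables).
#' @param class_weights Optional length-2 weights (negative, positive) for
#'   the weak-label cross-entropy; `NULL` means unweighted.
#' @param seed Master seed for initialization, shuffling and augmentation.
#' @param checkpoint_dir Directory for per-epoch weight snapshots (a
#'   temporary directory by default).
#' @param verbose Print per-epoch progress.
#' @export
sil_control <- function(batch_size = 56L, max_epochs = 150L, lr = 1e-4,
                        weight_decay = 1e-5, lr_decay_epoch = Inf,
                        lr_decay_factor = 0.2, window = 15L, min_epoch = 20L,
                        early_stop_patience = Inf,
                        augment = augment_config(), dropout = 0,
                        class_weights = NULL,
                        seed = 1L, checkpoint_dir = NULL, verbose = FALSE) {
  list(batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
       lr = lr, weight_decay = weight_decay,
       lr_decay_epoch = lr_decay_epoch, lr_decay_factor = lr_decay_factor,
       window = as.integer(window), min_epoch = as.integer(min_epoch),
       early_stop_patience = early_stop_patience, augment = augment,
       dropout = dropout, class_weights = class_weights, seed = seed,
       checkpoint_dir = checkpoint_dir, verbose = verbose)
}

# Forward a set of instances through encoder + head in eval mode, in chunks;
# returns the positive-class softmax score per instance.
sil_scores_raw <- function(layers, head, std, ids, chunk = 256L) {
  out <- numeric(length(ids))
  for (i in seq(1L, length(ids), by = chunk)) {
    sel <- ids[i:min(i + chunk - 1L, length(ids))]
    x <- std[, , , sel, drop = FALSE]
    E <- net_forward(layers, x, train = FALSE)$out
    logits <- head$W %*% E + head$b
    p <- softmax_cols(logits)
    out[i:(i + length(sel) - 1L)] <- p[2L, ]
  }
  out
}

#' Fit a single-instance (SIL) weak-label classifier for one fold
#'
#' Every instance inherits the label of its bag; a CNN instance classifier
#' is trained with cross-entropy on the fold's training bags, monitored by
#' positive-class F1 (score threshold 0.5) on the validation bags, and the
#' inference checkpoint is chosen by [select_checkpoint()] (moving-average
#' window, maximize F1).
#'
#' @param dataset A `bag_dataset`.
#' @param plan A [make_fold_plan()] result.
#' @param fold Fold index.
#' @param encoder An [encoder_config()].
#' @param control A [sil_control()].
#' @return An object of class `sil_model`.
#' @export
sil_fit <- function(dataset, plan, fold, encoder = encoder_config("lenet_small"),
                    control = sil_control()) {
  stopifnot(inherits(plan, "fold_plan"), fold >= 1, fold <= length(plan))
  fd <- plan[[fold]]
  inst <- dataset$instances
  train_ids <- inst$instance_id[inst$bag_id %in% fd$train]
  val_ids <- inst$instance_id[inst$bag_id %in% fd$val]
  if (length(train_ids) == 0) stop("empty train split")
  train_y <- ifelse(inst$bag_label[match(train_ids, inst$instance_id)] ==
                      "positive", 2L, 1L)
  val_pos <- inst$bag_label[match(val_ids, inst$instance_id)] == "positive"
  stats <- compute_channel_stats(dataset)
  std <- standardize(dataset$images * 1.0, stats)
  side <- dim(dataset$images)[1]

  enc <- with_seed(derive_seed(control$seed, paste0("sil-init-", fold)), {
    e <- build_encoder(encoder, c(side, side, 3L))
    list(layers = e$layers,
         head = list(W = he_init(2L, e$embedding_dim, e$embedding_dim),
                     b = numeric(2L)),
         embedding_dim = e$embedding_dim)
  })
  layers <- enc$layers
  head <- enc$head

  ckdir <- control$checkpoint_dir %||% tempfile("sil_ckpt_")
  dir.create(ckdir, recursive = TRUE, showWarnings = FALSE)

  nested <- list(enc = net_params(layers), head = head)
  flat <- flatten_params(nested)
  opt <- adam_init(flat, lr = control$lr, weight_decay = control$weight_decay)
  cw <- control$class_weights

  f1s <- numeric(0)
  best_f1 <- -Inf; best_epoch <- 0L
  with_seed(derive_seed(control$seed, paste0("sil-train-", fold)), {
    for (epoch in seq_len(control$max_epochs)) {
      if (is.finite(control$lr_decay_epoch) &&
          epoch == control$lr_decay_epoch) {
        opt$lr <- opt$lr * control$lr_decay_factor
      }
      ord <- sample(seq_along(train_ids))
      for (i in seq(1L, length(ord), by = control$batch_size)) {
        bi <- ord[i:min(i + control$batch_size - 1L, length(ord))]
        x <- std[, , , train_ids[bi], drop = FALSE]
        x <- augment_batch(x, control$augment)
        y <- train_y[bi]
        fwd <- net_forward(layers, x, train = TRUE)
        E <- fwd$out
        if (control$dropout > 0) {
          dmask <- matrix(runif(length(E)) >= control$dropout, nrow(E)) /
            (1 - control$dropout)
          E <- E * dmask
        }
        logits <- head$W %*% E + head$b
        ls <- ce_loss(logits, y)
        dlog <- ls$dlogits
        if (!is.null(cw)) dlog <- sweep(dlog, 2L, cw[y], `*`)
        gh <- list(W = tcrossprod(dlog, E), b = rowSums(dlog))
        dE <- crossprod(head$W, dlog)
        if (control$dropout > 0) dE <- dE * dmask
        bwd <- net_backward(layers, dE, fwd$caches)
        gflat <- flatten_params(list(enc = bwd$grads, head = gh))
        st <- adam_step(opt, flat, gflat)
        opt <- st$opt; flat <- st$params
        nested <- unflatten_into(nested, flat)
        layers <- net_set_params(layers, nested$enc)
        head <- nested$head
      }
      vs <- sil_scores_raw(layers, head, std, val_ids)
      f1s[epoch] <- f1_score(vs, val_pos)
      if (control$verbose) {
        message(sprintf("epoch %3d  val F1 %.4f", epoch, f1s[epoch]))
      }
      if (epoch >= control$min_epoch && f1s[epoch] > best_f1) {
        best_f1 <- f1s[epoch]; best_epoch <- epoch
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

  sel <- select_checkpoint(f1s, window = control$window,
                           min_epoch = control$min_epoch, mode = "maximize")
  flat <- readRDS(file.path(ckdir, sprintf("epoch_%04d.rds", sel)))
  nested <- unflatten_into(nested, flat)
  layers <- net_set_params(layers, nested$enc)
  head <- nested$head
  unlink(ckdir, recursive = TRUE)

  structure(list(layers = layers, head = head, stats = stats,
                 encoder = encoder, fold = fold, splits = fd,
                 val_f1 = f1s, selected_epoch = sel, control = control),
            class = "sil_model")
}

#' @export
print.sil_model <- function(x, ...) {
  cat(sprintf(paste0("sil_model (%s encoder), fold %d: trained %d epochs, ",
                     "selected epoch %d (val F1 %.3f)\n"),
              x$encoder$name, x$fold, length(x$val_f1), x$selected_epoch,
              x$val_f1[x$selected_epoch]))
  invisible(x)
}

#' @export
summary.sil_model <- function(object, ...) {
  print(object)
  cat(sprintf("  validation F1: last %.3f, best %.3f at epoch %d\n",
              object$val_f1[length(object$val_f1)], max(object$val_f1),
              which.max(object$val_f1)))
  invisible(object)
}

#' @export
plot.sil_model <- function(x, ...) {
  plot(seq_along(x$val_f1), x$val_f1, type = "l", xlab = "epoch",
       ylab = "validation F1", main = sprintf("SIL fold %d", x$fold), ...)
  graphics::abline(v = x$selected_epoch, lty = 2)
  invisible(x)
}

#' Score instances with a fitted SIL model
#'
#' @param model A [sil_fit()] result.
#' @param dataset The `bag_dataset` the instances live in.
#' @param instance_ids Instances to score (default: all).
#' @return A data.frame (instance_id, bag_id, fold, score) where `score` is
#'   the positive-class softmax probability in [0, 1]. Deterministic in
#'   inference mode.
#' @export
score_instances <- function(model, dataset, instance_ids = NULL) {
  stopifnot(inherits(model, "sil_model"))
  ids <- instance_ids %||% dataset$instances$instance_id
  data.frame(instance_id = ids,
             bag_id = dataset$instances$bag_id[match(ids, dataset$instances$instance_id)],
             fold = model$fold,
             score = sil_scores_raw(model$layers, model$head,
                                    standardize(dataset$images * 1.0,
                                                model$stats), ids))
}

#' @export
predict.sil_model <- function(object, dataset, instance_ids = NULL, ...) {
  score_instances(object, dataset, instance_ids)
}

#' Percentage of positively classified instances in a bag
#'
#' 100 x the fraction of instance scores strictly above 0.5 (a score of
#' exactly 0.5 is not counted as positive).
#'
#' @param scores Instance scores of one bag.
#' @return A percentage in [0, 100].
#' @export
percent_positive <- function(scores) {
  if (length(scores) == 0) stop("empty bag")
  100 * mean(scores > 0.5)
}

#' Fifth-percentile bag-classification threshold
#'
#' The midpoint between the 5th percentiles (linear interpolation between
#' order statistics, at fractional rank 0.05 * (n - 1)) of the
#' positive-instance percentages in positive and negative train+validation
#' bags of a fold. The low percentile trades specificity for sensitivity:
#' a questionable bag should be flagged rather than missed.
#'
#' @param pos_percents,neg_percents Percent-positive values of the fold's
#'   positive resp. negative train+validation bags.
#' @return The threshold t_f.
#' @export
compute_bag_threshold <- function(pos_percents, neg_percents) {
  if (length(pos_percents) == 0 || length(neg_percents) == 0) {
    stop("both percentage lists must be non-empty")
  }
  p5 <- function(v) unname(quantile(v, 0.05, type = 7))
  (p5(pos_percents) + p5(neg_percents)) / 2
}

#' Classify test bags by the percent-positive threshold rule
#'
#' A bag is positive iff its percentage of positively classified instances
#' strictly exceeds `t_f`.
#'
#' @param percents Named or plain vector of per-bag percent-positive values.
#' @param t_f Threshold from [compute_bag_threshold()].
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_bags_sil <- function(percents, t_f) {
  ifelse(percents > t_f, "positive", "negative")
}

#' Run the full SIL chain on one fold
#'
#' Trains the instance classifier, scores every instance of the dataset,
#' computes the fold threshold from train+validation bags only, classifies
#' the test bags, and evaluates bag accuracy and Precision@K for the truly
#' positive test bags.
#'
#' @inheritParams sil_fit
#' @return List with the fitted `model`, the instance `scores` table, the
#'   fold threshold `t_f`, per-bag `percents`, test-bag `predictions`,
#'   `bag_accuracy`, and `precision_at_k` (one value per truly positive
#'   test bag).
#' @export
sil_run_fold <- function(dataset, plan, fold,
                         encoder = encoder_config("lenet_small"),
                         control = sil_control()) {
  model <- sil_fit(dataset, plan, fold, encoder, control)
  scores <- score_instances(model, dataset)
  fd <- plan[[fold]]
  labels <- setNames(dataset$bags$label, dataset$bags$bag_id)
  percents <- tapply(scores$score, scores$bag_id, percent_positive)
  trval <- as.character(c(fd$train, fd$val))
  t_f <- compute_bag_threshold(
    percents[trval][labels[trval] == "positive"],
    percents[trval][labels[trval] == "negative"])
  test_ids <- as.character(fd$test)
  pred <- classify_bags_sil(percents[test_ids], t_f)
  acc <- bag_accuracy(pred, labels[test_ids])
  pos_test <- fd$test[labels[as.character(fd$test)] == "positive"]
  pk <- vapply(pos_test, function(b) {
    sel <- scores$bag_id == b
    keys <- dataset$instances$is_key[match(scores$instance_id[sel],
                                           dataset$instances$instance_id)]
    precision_at_k(scores$score[sel], keys,
                   k = sum(keys),
                   predicted_positive = pred[as.character(b)] == "positive",
                   instance_ids = scores$instance_id[sel])
  }, numeric(1))
  list(model = model, scores = scores, t_f = t_f, percents = percents,
       predictions = pred, bag_accuracy = acc,
       precision_at_k = setNames(pk, pos_test))
}
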