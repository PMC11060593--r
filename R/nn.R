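# Minimal CPU convolutional network engine.
#
# Image batches are numeric arrays of dim (H, W, C, N).  Convolutions are
# computed as im2col + GEMM (the im2col/col2im kernels live in src/), so the
# heavy lifting is done by the BLAS.  Backpropagation is hand-derived per
# layer.  Everything is deterministic given the R RNG state at init time and
# the order of training batches.

# ---- layer constructors ----------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L) {
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch,
       W = he_init(out_ch, in_ch * k * k, in_ch * k * k),
       b = numeric(out_ch))
}

layer_relu <- function() list(type = "relu")

layer_pool2 <- function() list(type = "pool2")

layer_flatten <- function() list(type = "flatten")

layer_gap <- function() list(type = "gap")

layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", W = he_init(out_dim, in_dim, in_dim),
       b = numeric(out_dim))
}

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(ch)
  st$rv <- rep(1, ch)
  list(type = "bn", ch = ch, momentum = momentum, eps = eps,
       gamma = rep(1, ch), beta = numeric(ch), state = st)
}

layer_resblock <- function(in_ch, out_ch, stride = 1L) {
  short <- NULL
  if (stride != 1L || in_ch != out_ch) {
    short <- list(layer_conv(in_ch, out_ch, 1L, stride = stride),
                  layer_bn(out_ch))
  }
  list(type = "resblock",
       main = list(layer_conv(in_ch, out_ch, 3L, stride = stride, pad = 1L),
                   layer_bn(out_ch),
                   layer_relu(),
                   layer_conv(out_ch, out_ch, 3L, pad = 1L),
                   layer_bn(out_ch)),
       short = short)
}

layer_fire <- function(in_ch, squeeze_ch, expand_ch) {
  list(type = "fire",
       squeeze = layer_conv(in_ch, squeeze_ch, 1L),
       e1 = layer_conv(squeeze_ch, expand_ch, 1L),
       e3 = layer_conv(squeeze_ch, expand_ch, 3L, pad = 1L),
       expand_ch = expand_ch)
}

# ---- forward / backward ----------------------------------------------------

channel_reduce <- function(a, f) {
  d <- dim(a)
  f(matrix(aperm(a, c(1L, 2L, 4L, 3L)), ncol = d[3]))
}

layer_forward <- function(layer, x, train = TRUE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      oh <- (d[1] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
      ow <- (d[2] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
      cols <- im2col_cpp(x, d[1], d[2], d[3], d[4],
                         layer$k, layer$stride, layer$pad)
      om <- layer$W %*% cols + layer$b
      out <- aperm(array(om, c(layer$out_ch, oh, ow, d[4])), c(2L, 3L, 1L, 4L))
      list(out = out, cache = list(cols = cols, d = d, oh = oh, ow = ow))
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask)
    },
    pool2 = {
      d <- dim(x)
      oh <- d[1] %/% 2L; ow <- d[2] %/% 2L
      if (oh == 0L || ow == 0L) {
        # input smaller than the pooling window: identity
        return(list(out = x, cache = list(identity = TRUE)))
      }
      i1 <- seq_len(oh) * 2L - 1L; j1 <- seq_len(ow) * 2L - 1L
      a <- x[i1, j1, , , drop = FALSE]
      b <- x[i1 + 1L, j1, , , drop = FALSE]
      cc <- x[i1, j1 + 1L, , , drop = FALSE]
      dd <- x[i1 + 1L, j1 + 1L, , , drop = FALSE]
      out <- pmax(a, b, cc, dd)
      w1 <- out == a
      w2 <- !w1 & out == b
      w3 <- !w1 & !w2 & out == cc
      w4 <- !(w1 | w2 | w3)
      list(out = out,
           cache = list(d = d, masks = list(w1, w2, w3, w4), oh = oh, ow = ow))
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, nrow = prod(d[1:3])), cache = d)
    },
    gap = {
      d <- dim(x)
      out <- matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
      list(out = out, cache = d)
    },
    dense = {
      list(out = layer$W %*% x + layer$b, cache = x)
    },
    bn = {
      d <- dim(x)
      m <- prod(d[c(1, 2, 4)])
      if (train) {
        mu <- channel_reduce(x, colMeans)
        v <- channel_reduce(x, function(z) colMeans(z * z)) - mu^2
        layer$state$rm <- (1 - layer$momentum) * layer$state$rm + layer$momentum * mu
        layer$state$rv <- (1 - layer$momentum) * layer$state$rv + layer$momentum * v
      } else {
        mu <- layer$state$rm
        v <- layer$state$rv
      }
      inv <- 1 / sqrt(v + layer$eps)
      xc <- sweep(x, 3L, mu)
      xhat <- sweep(xc, 3L, inv, `*`)
      out <- sweep(sweep(xhat, 3L, layer$gamma, `*`), 3L, layer$beta, `+`)
      list(out = out, cache = list(xhat = xhat, inv = inv, m = m, xc = xc))
    },
    resblock = {
      fm <- net_forward(layer$main, x, train)
      if (is.null(layer$short)) {
        ys <- x; cs <- NULL
      } else {
        fs <- net_forward(layer$short, x, train)
        ys <- fs$out; cs <- fs$caches
      }
      s <- fm$out + ys
      mask <- s > 0
      list(out = s * mask,
           cache = list(cm = fm$caches, cs = cs, mask = mask))
    },
    fire = {
      fs <- layer_forward(layer$squeeze, x, train)
      smask <- fs$out > 0
      sact <- fs$out * smask
      f1 <- layer_forward(layer$e1, sact, train)
      f3 <- layer_forward(layer$e3, sact, train)
      m1 <- f1$out > 0; m3 <- f3$out > 0
      d1 <- dim(f1$out)
      out <- array(0, c(d1[1], d1[2], 2L * layer$expand_ch, d1[4]))
      out[, , seq_len(layer$expand_ch), ] <- f1$out * m1
      out[, , layer$expand_ch + seq_len(layer$expand_ch), ] <- f3$out * m3
      list(out = out, cache = list(cs = fs$cache, smask = smask,
                                   c1 = f1$cache, c3 = f3$cache,
                                   m1 = m1, m3 = m3))
    },
    stop("unknown layer type: ", layer$type)
  )
}

conv_backward <- function(layer, dout, cache) {
  dmat <- matrix(aperm(dout, c(3L, 1L, 2L, 4L)), nrow = layer$out_ch)
  dW <- tcrossprod(dmat, cache$cols)
  db <- rowSums(dmat)
  dcols <- crossprod(layer$W, dmat)
  d <- cache$d
  dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4],
                   layer$k, layer$stride, layer$pad)
  list(dx = dx, grads = list(W = dW, b = db))
}

layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    conv = conv_backward(layer, dout, cache),
    relu = list(dx = dout * cache, grads = NULL),
    pool2 = {
      if (isTRUE(cache$identity)) return(list(dx = dout, grads = NULL))
      d <- cache$d
      oh <- cache$oh; ow <- cache$ow
      i1 <- seq_len(oh) * 2L - 1L; j1 <- seq_len(ow) * 2L - 1L
      dx <- array(0, d)
      dx[i1, j1, , ] <- dout * cache$masks[[1]]
      dx[i1 + 1L, j1, , ] <- dout * cache$masks[[2]]
      dx[i1, j1 + 1L, , ] <- dout * cache$masks[[3]]
      dx[i1 + 1L, j1 + 1L, , ] <- dout * cache$masks[[4]]
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(dout, cache), grads = NULL),
    gap = {
      d <- cache
      dx <- array(rep(as.vector(dout) / (d[1] * d[2]), each = d[1] * d[2]), d)
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = crossprod(layer$W, dout),
           grads = list(W = tcrossprod(dout, cache), b = rowSums(dout)))
    },
    bn = {
      xhat <- cache$xhat; inv <- cache$inv; m <- cache$m
      dgamma <- channel_reduce(dout * xhat, colSums)
      dbeta <- channel_reduce(dout, colSums)
      dxhat <- sweep(dout, 3L, layer$gamma, `*`)
      s1 <- channel_reduce(dxhat, colSums)
      s2 <- channel_reduce(dxhat * xhat, colSums)
      dx <- sweep(dxhat - sweep(xhat, 3L, s2 / m, `*`), 3L, s1 / m) |>
        sweep(MARGIN = 3L, STATS = inv, FUN = `*`)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    resblock = {
      ds <- dout * cache$mask
      bm <- net_backward(layer$main, ds, cache$cm)
      if (is.null(layer$short)) {
        dx <- bm$dx + ds
        list(dx = dx, grads = list(main = bm$grads))
      } else {
        bs <- net_backward(layer$short, ds, cache$cs)
        list(dx = bm$dx + bs$dx,
             grads = list(main = bm$grads, short = bs$grads))
      }
    },
    fire = {
      ec <- layer$expand_ch
      d1 <- dout[, , seq_len(ec), , drop = FALSE] * cache$m1
      d3 <- dout[, , ec + seq_len(ec), , drop = FALSE] * cache$m3
      b1 <- conv_backward(layer$e1, d1, cache$c1)
      b3 <- conv_backward(layer$e3, d3, cache$c3)
      dsact <- (b1$dx + b3$dx) * cache$smask
      bsq <- conv_backward(layer$squeeze, dsact, cache$cs)
      list(dx = bsq$dx,
           grads = list(squeeze = bsq$grads, e1 = b1$grads, e3 = b3$grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

net_forward <- function(layers, x, train = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], x, train)
    x <- f$out
    caches[[i]] <- f$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  names(grads) <- paste0("L", seq_along(layers))
  for (i in rev(seq_along(layers))) {
    b <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- b$dx
    grads[[i]] <- b$grads
  }
  list(dx = dout, grads = grads)
}

# ---- parameter bookkeeping -------------------------------------------------

layer_params <- function(layer) {
  switch(layer$type,
    conv = list(W = layer$W, b = layer$b),
    dense = list(W = layer$W, b = layer$b),
    bn = list(gamma = layer$gamma, beta = layer$beta),
    resblock = {
      p <- list(main = net_params(layer$main))
      if (!is.null(layer$short)) p$short <- net_params(layer$short)
      p
    },
    fire = list(squeeze = layer_params(layer$squeeze),
                e1 = layer_params(layer$e1),
                e3 = layer_params(layer$e3)),
    NULL
  )
}

layer_set_params <- function(layer, p) {
  switch(layer$type,
    conv = , dense = { layer$W <- p$W; layer$b <- p$b },
    bn = { layer$gamma <- p$gamma; layer$beta <- p$beta },
    resblock = {
      layer$main <- net_set_params(layer$main, p$main)
      if (!is.null(layer$short)) layer$short <- net_set_params(layer$short, p$short)
    },
    fire = {
      layer$squeeze <- layer_set_params(layer$squeeze, p$squeeze)
      layer$e1 <- layer_set_params(layer$e1, p$e1)
      layer$e3 <- layer_set_params(layer$e3, p$e3)
    }
  )
  layer
}

net_params <- function(layers) {
  p <- lapply(layers, layer_params)
  names(p) <- paste0("L", seq_along(layers))
  p
}

net_set_params <- function(layers, p) {
  for (i in seq_along(layers)) {
    if (!is.null(p[[paste0("L", i)]])) {
      layers[[i]] <- layer_set_params(layers[[i]], p[[paste0("L", i)]])
    }
  }
  layers
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    key <- paste0(prefix, nm)
    if (is.list(v)) {
      out <- c(out, flatten_params(v, paste0(key, ".")))
    } else {
      out[[key]] <- v
    }
  }
  out
}

unflatten_into <- function(template, flat, prefix = "") {
  for (nm in names(template)) {
    v <- template[[nm]]
    if (is.null(v)) next
    key <- paste0(prefix, nm)
    if (is.list(v)) {
      template[[nm]] <- unflatten_into(v, flat, paste0(key, "."))
    } else {
      template[[nm]] <- flat[[key]]
    }
  }
  template
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(flat_params, lr = 1e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2, eps = eps, t = 0L,
       m = lapply(flat_params, function(p) p * 0),
       v = lapply(flat_params, function(p) p * 0))
}

adam_step <- function(opt, flat_params, flat_grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(flat_params)) {
    g <- flat_grads[[nm]] + opt$wd * flat_params[[nm]]
    opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
    opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
    flat_params[[nm]] <- flat_params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = flat_params)
}

# ---- losses ----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Cross-entropy on logits (K x N) against integer labels in 1..K.
# Returns loss and the gradient wrt logits.
ce_loss <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[cbind(labels, seq_len(n))], 1e-12)))
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, dlogits = dlog / n, probs = p)
}
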