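# Instance encoders.  Every encoder maps a batch of images (H, W, C, N) to an
# embedding matrix (d x N).  `lenet_small` follows the classic two-conv-block
# LeNet variant used widely in attention-MIL work (20 then 50 feature maps,
# 5x5 kernels, 2x2 max-pooling, fully connected embedding of 500);
# `tiny_test` is a deliberately small desk-scale encoder; `resnet18` and
# `squeezenet` are the standard deeper backbones with their stems adapted to
# small inputs.

#' Encoder configuration
#'
#' @param name One of `"lenet_small"`, `"tiny_test"`, `"resnet18"`,
#'   `"squeezenet"`.
#' @param embedding_dim Width of the final embedding. Only adjustable for
#'   `lenet_small` (default 500) and `tiny_test` (default 64); the deeper
#'   backbones emit their native 512-wide pooled features.
#' @param pretrained Accepted for interface compatibility; no pretrained
#'   weights ship with the package.
#' @param filters Optional two conv widths for `tiny_test` (default c(8, 16)).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(name = c("lenet_small", "tiny_test", "resnet18",
                                    "squeezenet"),
                           embedding_dim = NULL, pretrained = FALSE,
                           filters = NULL) {
  name <- match.arg(name)
  if (is.null(embedding_dim)) {
    embedding_dim <- switch(name, lenet_small = 500L, tiny_test = 64L, 512L)
  }
  structure(list(name = name, embedding_dim = as.integer(embedding_dim),
                 pretrained = isTRUE(pretrained),
                 filters = if (!is.null(filters)) as.integer(filters)),
            class = "encoder_config")
}

probe_dim <- function(layers, input_shape) {
  x <- array(0, c(input_shape, 1L))
  out <- net_forward(layers, x, train = FALSE)$out
  if (is.matrix(out)) nrow(out) else prod(dim(out)[1:3])
}

#' Build an instance encoder
#'
#' Constructs the parameterized feature extractor named in `config` for
#' images of shape `input_shape` (height, width, channels). Parameter
#' initialization consumes the current R RNG stream, so a fixed seed gives
#' identical initial parameters.
#'
#' @param config An [encoder_config()].
#' @param input_shape Integer vector `c(H, W, C)`.
#' @return A list with elements `layers`, `embedding_dim`, `name`,
#'   `input_shape`.
#' @export
build_encoder <- function(config, input_shape) {
  stopifnot(inherits(config, "encoder_config"), length(input_shape) == 3)
  input_shape <- as.integer(input_shape)
  ch <- input_shape[3]
  layers <- switch(config$name,
    lenet_small = {
      stack <- list(layer_conv(ch, 20L, 5L), layer_relu(), layer_pool2(),
                    layer_conv(20L, 50L, 5L), layer_relu(), layer_pool2(),
                    layer_flatten())
      d <- probe_dim(stack, input_shape)
      c(stack, list(layer_dense(d, config$embedding_dim), layer_relu()))
    },
    tiny_test = {
      fl <- config$filters %||% c(8L, 16L)
      stack <- list(layer_conv(ch, fl[1], 5L, stride = 3L), layer_relu(),
                    layer_conv(fl[1], fl[2], 3L), layer_relu(), layer_pool2(),
                    layer_flatten())
      d <- probe_dim(stack, input_shape)
      c(stack, list(layer_dense(d, config$embedding_dim), layer_relu()))
    },
    resnet18 = list(
      layer_conv(ch, 64L, 7L, stride = 2L, pad = 3L), layer_bn(64L),
      layer_relu(), layer_pool2(),
      layer_resblock(64L, 64L), layer_resblock(64L, 64L),
      layer_resblock(64L, 128L, stride = 2L), layer_resblock(128L, 128L),
      layer_resblock(128L, 256L, stride = 2L), layer_resblock(256L, 256L),
      layer_resblock(256L, 512L, stride = 2L), layer_resblock(512L, 512L),
      layer_gap()),
    squeezenet = list(
      layer_conv(ch, 64L, 3L, stride = 2L), layer_relu(), layer_pool2(),
      layer_fire(64L, 16L, 64L), layer_fire(128L, 16L, 64L), layer_pool2(),
      layer_fire(128L, 32L, 128L), layer_fire(256L, 32L, 128L), layer_pool2(),
      layer_fire(256L, 48L, 192L), layer_fire(384L, 48L, 192L),
      layer_fire(384L, 64L, 256L), layer_fire(512L, 64L, 256L),
      layer_gap()),
    stop("unknown encoder name: ", config$name,
         " (valid: lenet_small, tiny_test, resnet18, squeezenet)")
  )
  emb <- if (config$name %in% c("resnet18", "squeezenet")) 512L else
    config$embedding_dim
  list(layers = layers, embedding_dim = emb, name = config$name,
       input_shape = input_shape)
}

# ---- attention pooling (two-layer tanh attention, optionally gated) --------

attention_init <- function(d, L = 128L, gated = FALSE, n_class = 2L) {
  att <- list(V = he_init(L, d, d), w = he_init(1L, L, L),
              Wc = he_init(n_class, d, d), bc = numeric(n_class),
              gated = gated, L = L)
  if (gated) att$U <- he_init(L, d, d)
  att
}

attention_params <- function(att) {
  p <- list(V = att$V, w = att$w, Wc = att$Wc, bc = att$bc)
  if (att$gated) p$U <- att$U
  p
}

attention_set_params <- function(att, p) {
  att$V <- p$V; att$w <- p$w; att$Wc <- p$Wc; att$bc <- p$bc
  if (att$gated) att$U <- p$U
  att
}

# E: embedding matrix (d x m) for one mini-bag.  Attention weights are
# softmax-normalized over the mini-bag, so they are nonnegative and sum to 1.
attention_forward <- function(att, E) {
  A1 <- tanh(att$V %*% E)
  if (att$gated) {
    G <- 1 / (1 + exp(-(att$U %*% E)))
    Ag <- A1 * G
  } else {
    G <- NULL; Ag <- A1
  }
  s <- att$w %*% Ag
  s <- s - max(s)
  a <- exp(s) / sum(exp(s))
  z <- E %*% t(a)
  logits <- att$Wc %*% z + att$bc
  list(logits = logits, a = as.vector(a),
       cache = list(E = E, A1 = A1, G = G, Ag = Ag, a = a, z = z))
}

attention_backward <- function(att, dlogits, cache) {
  E <- cache$E; a <- cache$a
  dWc <- tcrossprod(dlogits, cache$z)
  dbc <- as.vector(dlogits)
  dz <- crossprod(att$Wc, dlogits)
  da <- crossprod(E, dz)
  dE <- dz %*% a
  ds <- a * (as.vector(da) - sum(a * as.vector(da)))
  ds <- matrix(ds, nrow = 1L)
  dw <- tcrossprod(ds, cache$Ag)
  dAg <- crossprod(att$w, ds)
  grads <- list(Wc = dWc, bc = dbc, w = dw)
  if (att$gated) {
    dA1 <- dAg * cache$G
    dGpre <- dAg * cache$A1 * cache$G * (1 - cache$G)
    grads$U <- tcrossprod(dGpre, E)
    dE <- dE + crossprod(att$U, dGpre)
  } else {
    dA1 <- dAg
  }
  dpre <- dA1 * (1 - cache$A1^2)
  grads$V <- tcrossprod(dpre, E)
  dE <- dE + crossprod(att$V, dpre)
  list(dE = dE, grads = grads)
}
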