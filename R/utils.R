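#' @keywords internal
"_PACKAGE"

#' @useDynLib milbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rnorm runif rbeta sd qnorm pnorm dnorm optim
#'   integrate uniroot predict
#' @importFrom utils read.csv write.csv head
NULL

# Deterministic fan-out of one master seed into named sub-streams, so that
# e.g. data generation, fold assignment, weight init and mini-bag sampling
# each consume an independent, reproducible RNG stream.
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(master) * 2654435.0 + h * 97.0 + 1.0) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
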