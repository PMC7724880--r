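# Internal helpers: classed conditions, seeded evaluation, activations.

amn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("amnet_", class), "amnet_error")))
}

#' @importFrom stats plogis rnorm runif
NULL

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-epoch seed derivation; stays below 2^31 and is
# collision-free in (epoch, stream) for epochs up to ~60000.
# `stream` separates independent randomness sources within one epoch.
derive_seed <- function(seed, epoch, stream = 0L) {
  ((abs(seed) %% 4001) * 500009 + abs(epoch) * 8 + (stream %% 8L)) %% 2147483647
}

act_fun <- function(name) {
  switch(name,
    relu     = function(x) pmax(x, 0),
    identity = function(x) x,
    logistic = function(x) plogis(x),
    tanh     = function(x) tanh(x),
    amn_stop(sprintf("unknown activation '%s'", name), "value_error")
  )
}

# Derivative expressed from pre-activation and output, whichever is cheaper.
act_deriv <- function(name) {
  switch(name,
    relu     = function(pre, out) (pre > 0) + 0,
    identity = function(pre, out) array(1, dim = dim(as.matrix(pre))),
    logistic = function(pre, out) out * (1 - out),
    tanh     = function(pre, out) 1 - out^2,
    amn_stop(sprintf("unknown activation '%s'", name), "value_error")
  )
}

check_ids <- function(ids, what) {
  if (length(ids) == 0) return(invisible(ids))
  if (!is.character(ids)) amn_stop(sprintf("%s must be character", what), "value_error")
  if (anyDuplicated(ids)) amn_stop(sprintf("duplicate ids in %s", what), "validation_error")
  if (any(grepl("[\t\n,]", ids))) {
    amn_stop(sprintf("%s must not contain tabs, commas or newlines", what), "value_error")
  }
  invisible(ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
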