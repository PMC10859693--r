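# Internal numerical utilities shared across modules.

#' @importFrom stats rnorm runif setNames predict
#' @importFrom utils head
#' @importFrom rlang .data
#' @import Matrix
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adam optimizer state
#'
#' Creates the first/second-moment accumulators for a named list of parameter
#' matrices. Used by both the embedding cascade and the classifier trainers.
#'
#' @param params named list of numeric matrices/vectors.
#' @keywords internal
#' @noRd
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# One Adam update. `grads` must carry the same names as `params`; entries
# missing from `grads` are left untouched.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Glorot-style initialization for a weight matrix.
glorot <- function(nin, nout) {
  sd <- sqrt(2 / (nin + nout))
  matrix(rnorm(nin * nout, sd = sd), nin, nout)
}

# Maximum of x within groups g (integer 1..ng). Returns length-ng vector,
# -Inf for empty groups.
grouped_max <- function(x, g, ng) {
  o <- order(g, x)
  cnt <- tabulate(g, nbins = ng)
  idx <- cumsum(cnt)
  out <- rep(-Inf, ng)
  nz <- cnt > 0
  out[nz] <- x[o][idx[nz]]
  out
}

# Numerically stable softmax over rows grouped by g: returns per-element
# weights summing to one within each group.
grouped_softmax <- function(x, g, ng) {
  m <- grouped_max(x, g, ng)
  e <- exp(x - m[g])
  s <- rowsum_vec(e, g, ng)
  e / s[g]
}

# rowsum() convenience for a plain vector with dense group ids 1..ng.
rowsum_vec <- function(x, g, ng) {
  out <- numeric(ng)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# rowsum for a matrix with dense group ids 1..ng; absent groups give zeros.
rowsum_mat <- function(x, g, ng) {
  out <- matrix(0, ng, ncol(x))
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Softmax over the rows of a matrix.
softmax_rows <- function(z) {
  m <- apply(z, 1, max)
  e <- exp(z - m)
  e / rowSums(e)
}

# Small FNV-1a content hash so artifacts can embed a configuration
# fingerprint without an external hashing dependency.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# Derive a reproducible child seed (kept below 2^31) from a base seed and a
# stream label, so independent stages never share a random stream.
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483629) + 1L
}
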