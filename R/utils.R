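# Internal numerical helpers shared across the package.

# All logarithms of probabilities go through ln_safe() so that impossible
# states produce a bounded (-16 nat) rather than infinite prediction error.
EPS_LOG <- exp(-16)

ln_safe <- function(x) log(x + EPS_LOG)

softmax <- function(v) {
  w <- exp(v - max(v))
  w / sum(w)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shannon entropy in nats; 0 * log 0 handled by the epsilon floor consistently
# with ln_safe so that entropy comparisons and free-energy decompositions use
# the same logarithm everywhere.
entropy_nats <- function(p) -sum(p * ln_safe(p))

one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

# Contract one axis of an array with a vector; remaining axes keep their
# original relative order.
contract_one <- function(x, v, axis) {
  d <- dim(x)
  if (is.null(d)) {
    stopifnot(axis == 1L)
    return(sum(x * v))
  }
  if (length(d) == 1L) {
    return(sum(as.vector(x) * v))
  }
  perm <- c(seq_along(d)[-axis], axis)
  xp <- aperm(x, perm)
  m <- matrix(xp, ncol = d[axis])
  res <- as.vector(m %*% v)
  nd <- d[-axis]
  if (length(nd) > 1L) array(res, dim = nd) else res
}

# Generalised dot product: contract every axis of `x` whose entry in `vecs`
# is non-NULL.  `vecs` must have one entry per axis of `x`.
tensor_contract <- function(x, vecs) {
  d <- dim(x) %||% length(x)
  stopifnot(length(vecs) == length(d))
  for (axis in rev(seq_along(vecs))) {
    if (is.null(vecs[[axis]])) next
    x <- contract_one(x, vecs[[axis]], axis)
  }
  x
}

# argmax with deterministic lowest-index tie-break
argmax1 <- function(x) which.max(x)

# run `expr` under a local, restored RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
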