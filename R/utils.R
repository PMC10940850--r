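# Small numerical and RNG helpers shared across the package.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(M) {
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  out <- m + log(rowSums(exp(M - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded package functions do not perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed from a base seed and integer keys.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    x <- (x * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Dirichlet log-density; terms with alpha == 1 contribute nothing even when
# the corresponding weight is exactly zero.
ldirichlet <- function(p, alpha) {
  alpha <- rep_len(alpha, length(p))
  s <- (alpha - 1) * log(p)
  s[alpha == 1] <- 0
  if (any(!is.finite(s))) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum(s)
}
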