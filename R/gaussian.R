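# Gaussian component distribution: the default base distribution of the
# coupled mixture model. The interface is pluggable so other component
# families can be supplied, provided they expose the same three closures.

# Multivariate normal log-density via the Cholesky factor of the covariance.
mvn_loglik <- function(X, mu, Sigma) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  d <- ncol(X)
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("component covariance is not symmetric positive definite"))
  z <- forwardsolve(t(L), t(X) - mu)
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

# Raise the covariance diagonal to at least `eps` and jitter until the
# Cholesky factorization succeeds.
ensure_spd <- function(S, eps) {
  d <- nrow(S)
  diag(S) <- pmax(diag(S), eps)
  jit <- eps
  for (i in 1:12) {
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    if (ok) return(S)
    S <- S + diag(jit, d)
    jit <- jit * 10
  }
  diag(max(eps, 1e-8), d)
}

#' Gaussian base distribution for mixture components
#'
#' Bundles the three operations the inference engine needs from a component
#' family: the log-density of data under a component, the maximum-likelihood
#' estimate of component parameters from a set of points (1/n covariance
#' convention with a diagonal regularization floor), and a draw from the base
#' prior used to refresh components whose cluster empties out.
#'
#' @return a list of closures `loglik(X, theta)`, `mle(X, eps)`,
#'   `resample(stats)` and `logprior(theta)`; `theta` is a list with elements
#'   `mean` and `cov`.
#' @examples
#' g <- gaussian_base()
#' g$loglik(matrix(0, 1, 1), list(mean = 0, cov = diag(1)))  # -0.5 * log(2*pi)
#' @export
gaussian_base <- function() {
  list(
    loglik = function(X, theta) mvn_loglik(X, theta$mean, theta$cov),
    mle = function(X, eps = 1e-8) {
      n <- nrow(X)
      mu <- colMeans(X)
      if (n >= 2) {
        Xc <- sweep(X, 2, mu)
        S <- crossprod(Xc) / n
      } else {
        S <- diag(0, ncol(X))
      }
      list(mean = mu, cov = ensure_spd(S, eps))
    },
    # Base-prior draw for an emptied component: mean from a Gaussian centred
    # on the view's grand mean with the per-feature variances, covariance set
    # to the diagonal of the grand variances.
    resample = function(stats) {
      d <- length(stats$mean)
      sdv <- sqrt(pmax(stats$var, stats$eps))
      list(mean = stats$mean + sdv * stats::rnorm(d),
           cov = ensure_spd(diag(pmax(stats$var, stats$eps), d), stats$eps))
    },
    logprior = function(theta) 0
  )
}

# Per-view N x K matrix of component log-densities.
component_loglik <- function(X, theta, base) {
  K <- length(theta)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) out[, k] <- base$loglik(X, theta[[k]])
  out
}
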