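# Modified hard-EM inference for the coupled multi-view mixture model.
#
# Each restart alternates: (E) coordinate-ascent reassignment of entities,
# view by view, to the argmax of their full conditional; (M1) analytical
# maximum-likelihood component parameters; (M2) greedy local search over the
# cluster-correspondence matchings; (M3) gradient ascent (ADAM, or BBVI with
# reparameterized Monte-Carlo gradients) on the mixture weights and coupling
# strengths under the pseudolikelihood. The best restart by final objective
# is returned.

#' Configuration for [fit_bmvc()]
#'
#' @param K clusters per view (scalar recycled across views).
#' @param mode `"auto"`, `"pseudo"` or `"exact"` treatment of the assignment
#'   prior's partition function. `"auto"` picks exact enumeration when the
#'   joint assignment space is within `enum_cap` and the pseudolikelihood
#'   otherwise.
#' @param max_iter maximum EM iterations per restart.
#' @param estep_max_sweeps maximum full passes over the views within one
#'   E-step.
#' @param tol relative objective-improvement tolerance for EM convergence.
#' @param optimizer `"adam"` (direct MAP ascent) or `"bbvi"` (mean-field
#'   Gaussian variational inference with the reparameterization trick) for
#'   the mixture-weight / coupling-strength update.
#' @param opt_steps,opt_lr optimizer iteration count and step size.
#' @param opt_mc_samples Monte-Carlo samples per BBVI gradient estimate.
#' @param restarts number of random restarts.
#' @param init `"kmeans"` (k-means++ initialized k-means) or `"random"`.
#' @param seed integer seed; every restart derives its own stream from it.
#' @param phi_fixed_zero freeze every coupling strength at zero (the
#'   independent-mixture special case).
#' @param enum_cap maximum enumerable joint-assignment count for exact mode.
#' @param priors a [bmvc_priors] object.
#' @param init_labels optional list of integer label vectors (one per view)
#'   used verbatim as the initial assignments of every restart, bypassing
#'   `init`.
#' @param phi_init initial coupling strength.
#' @param pi_update `"occupancy"` (default): mixture weights take their
#'   closed-form Dirichlet-MAP value from the cluster occupancies and only
#'   the coupling strengths are optimized by gradient; `"joint"`: weights
#'   and coupling strengths are optimized jointly against the full
#'   objective, including the assignment-normalizer's dependence on the
#'   weights.
#' @param row_normalize_relations divide each relationship row by its total
#'   weight before fitting.
#' @return an object of class `bmvc_config`.
#' @export
bmvc_config <- function(K, mode = c("auto", "pseudo", "exact"), max_iter = 30L,
                        estep_max_sweeps = 10L, tol = 1e-6,
                        optimizer = c("adam", "bbvi"), opt_steps = 150L,
                        opt_lr = 0.05, opt_mc_samples = 5L, restarts = 10L,
                        init = c("kmeans", "random"), seed = 1L,
                        phi_fixed_zero = FALSE, enum_cap = 1e6,
                        priors = bmvc_priors(), init_labels = NULL,
                        phi_init = 0.5, pi_update = c("occupancy", "joint"),
                        row_normalize_relations = FALSE) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer)
  init <- match.arg(init)
  pi_update <- match.arg(pi_update)
  stopifnot(all(K >= 1), max_iter >= 1, estep_max_sweeps >= 1, tol > 0,
            opt_steps >= 1, opt_lr > 0, opt_mc_samples >= 1, restarts >= 1,
            inherits(priors, "bmvc_priors"))
  structure(list(K = as.integer(K), mode = mode, max_iter = as.integer(max_iter),
                 estep_max_sweeps = as.integer(estep_max_sweeps), tol = tol,
                 optimizer = optimizer, opt_steps = as.integer(opt_steps),
                 opt_lr = opt_lr, opt_mc_samples = as.integer(opt_mc_samples),
                 restarts = as.integer(restarts), init = init,
                 seed = as.integer(seed), phi_fixed_zero = phi_fixed_zero,
                 enum_cap = enum_cap, priors = priors,
                 init_labels = init_labels, phi_init = phi_init,
                 pi_update = pi_update,
                 row_normalize_relations = row_normalize_relations),
            class = "bmvc_config")
}

#' k-means clustering with k-means++ seeding
#'
#' Runs `n_init` independent k-means++ seedings followed by Lloyd iterations
#' and keeps the solution with the lowest within-cluster sum of squares (the
#' convention of the standard toolkits). Deterministic given `seed`. Used to
#' initialize every clustering algorithm in the package.
#'
#' @param X numeric matrix (entities in rows).
#' @param K number of clusters (`K <= nrow(X)`).
#' @param seed integer seed.
#' @param n_init number of independent seedings.
#' @return integer vector of hard labels in `1..K`.
#' @export
kmeans_init <- function(X, K, seed = 1L, n_init = 30L) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  n <- nrow(X)
  if (K > n) stop("K exceeds the number of entities")
  if (K == n) return(seq_len(n))
  with_seed(seed, {
    best <- NULL
    best_ss <- Inf
    for (rep in seq_len(n_init)) {
      centers <- kmeanspp_centers(X, K)
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 100L)),
        error = function(e) NULL)
      if (is.null(km)) {
        lab <- nearest_center(X, centers)
        ss <- sum((X - centers[lab, , drop = FALSE])^2)
      } else {
        lab <- as.integer(km$cluster)
        ss <- km$tot.withinss
      }
      if (ss < best_ss) {
        best_ss <- ss
        best <- lab
      }
    }
    best
  })
}

kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[idx[1], , drop = TRUE])^2)
  for (k in seq_len(K)[-1]) {
    if (sum(d2) <= 0) {
      idx[k] <- sample.int(n, 1L)
    } else {
      idx[k] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[k], , drop = TRUE])^2))
  }
  X[idx, , drop = FALSE]
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1L)
  out <- do.call(rbind, lapply(seq_len(K), function(pos) {
    if (pos == 1) cbind(K, sub)
    else if (pos == K) cbind(sub, K)
    else cbind(sub[, 1:(pos - 1), drop = FALSE], K,
               sub[, pos:(K - 1), drop = FALSE])
  }))
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

nearest_center <- function(X, centers) {
  D <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) + outer(rep(1, nrow(X)), rowSums(centers^2))
  max.col(-D, ties.method = "first")
}

# ---- internal fitting context -------------------------------------------

build_ctx <- function(data, relations, config, base = gaussian_base()) {
  stopifnot(inherits(data, "mv_dataset"), inherits(config, "bmvc_config"))
  V <- length(data$views)
  N <- view_sizes(data)
  K <- rep_len(config$K, V)
  X <- lapply(data$views, `[[`, "X")
  ids <- lapply(data$views, `[[`, "ids")
  pairs <- compile_relations(relations %||% mv_relations(), N, view_names(data), ids)
  if (config$row_normalize_relations) {
    pairs <- lapply(pairs, function(pr) {
      if (length(pr$ti)) {
        tot <- rowsum(pr$tw, pr$ti)
        pr$tw <- pr$tw / tot[match(pr$ti, as.integer(rownames(tot)))]
      }
      pr
    })
  }
  for (pr in pairs) {
    if (length(pr$ti) == 0) next
    if (K[pr$v] != K[pr$u])
      stop(sprintf("coupled views '%s' have different cluster counts (%d vs %d)",
                   pr$name, K[pr$v], K[pr$u]))
  }
  # Degree of every entity in the union relationship graph. When every
  # related entity has degree one, the partition function decomposes into a
  # closed form per edge and exact mode is cheap at any scale; "auto" then
  # selects exact normalization and falls back to the pseudolikelihood for
  # graphs with larger connected components.
  n_tot <- sum(N)
  offs <- cumsum(c(0L, N))
  deg <- tabulate(as.integer(unlist(lapply(pairs, function(pr)
    c(offs[pr$v] + pr$ti, offs[pr$u] + pr$tj)))), n_tot)
  edge_decomposable <- length(pairs) > 0 && total_edges(pairs) > 0 && all(deg <= 1L)
  mode <- config$mode
  if (mode == "auto") mode <- if (edge_decomposable) "exact" else "pseudo"
  eps <- vapply(X, function(x) {
    e <- 1e-6 * mean(apply(x, 2, stats::var))
    if (!is.finite(e) || e <= 0) 1e-8 else e
  }, numeric(1))
  gstats <- lapply(seq_len(V), function(v) {
    vr <- apply(X[[v]], 2, stats::var)
    vr[!is.finite(vr)] <- eps[v]  # single-entity views have no variance
    list(mean = colMeans(X[[v]]), var = vr, eps = eps[v])
  })
  priors <- config$priors
  if (config$phi_fixed_zero) priors$phi_prior <- "flat"
  degenerate <- vapply(seq_len(V), function(v) all(gstats[[v]]$var < 1e-12), logical(1))
  list(V = V, N = N, K = K, X = X, ids = ids, vnames = view_names(data),
       pairs = pairs, n_edges = total_edges(pairs), mode = mode,
       edge_decomposable = edge_decomposable,
       base = base, eps = eps, gstats = gstats, priors = priors,
       config = config, degenerate = degenerate)
}

init_state <- function(ctx, restart_seed) {
  cfg <- ctx$config
  z <- vector("list", ctx$V)
  if (!is.null(cfg$init_labels)) {
    z <- check_assignments(cfg$init_labels, ctx$N, ctx$K)
  } else {
    for (v in seq_len(ctx$V)) {
      z[[v]] <- if (cfg$init == "kmeans") {
        kmeans_init(ctx$X[[v]], ctx$K[v], seed = derive_seed(restart_seed, v))
      } else {
        # entirely random initialization: a single k-means pass seeded with
        # K entities drawn uniformly at random (no k-means++ spreading, no
        # best-of-n selection)
        with_seed(derive_seed(restart_seed, v), {
          ctr <- ctx$X[[v]][sample.int(ctx$N[v], min(ctx$K[v], ctx$N[v])), ,
                            drop = FALSE]
          km <- tryCatch(suppressWarnings(stats::kmeans(ctx$X[[v]], centers = ctr, iter.max = 100L)),
                         error = function(e) NULL)
          if (is.null(km)) nearest_center(ctx$X[[v]], ctr)
          else as.integer(km$cluster)
        })
      }
    }
  }
  phi0 <- if (cfg$phi_fixed_zero) 0 else (cfg$phi_init %||% 0.5)
  st <- list(z = z,
             pi = lapply(seq_len(ctx$V), function(v) {
               occ <- tabulate(z[[v]], ctx$K[v]) + 1e-8
               occ / sum(occ)
             }),
             theta = NULL, loglik = NULL,
             C = default_matching(ctx$pairs, ctx$K),
             phi = rep(phi0, length(ctx$pairs)))
  st <- m_theta(ctx, st)
  # align the correspondence matchings with the initial labelings so the
  # first E-step is invariant to label permutations of the initialization
  m_corr(ctx, st)
}

# ---- EM sub-steps --------------------------------------------------------

# (M1) analytical component MLEs given the hard assignments; empty clusters
# are refreshed from the base prior. Refreshes the data log-likelihood cache.
m_theta <- function(ctx, st) {
  for (v in seq_len(ctx$V)) {
    th <- vector("list", ctx$K[v])
    for (k in seq_len(ctx$K[v])) {
      rows <- which(st$z[[v]] == k)
      th[[k]] <- if (length(rows) == 0) {
        ctx$base$resample(ctx$gstats[[v]])
      } else {
        ctx$base$mle(ctx$X[[v]][rows, , drop = FALSE], eps = ctx$eps[v])
      }
    }
    st$theta[[v]] <- th
    st$loglik[[v]] <- component_loglik(ctx$X[[v]], th, ctx$base)
  }
  st
}

# (E) coordinate ascent over views: every entity of a view is reassigned to
# the argmax of its full conditional (data term included) given the other
# views; entities within a view are conditionally independent, so a view is
# updated in one vectorized pass. Sweeps repeat until a full pass changes
# nothing. Ties break toward the lowest cluster index.
e_step <- function(ctx, st) {
  for (sweep in seq_len(ctx$config$estep_max_sweeps)) {
    changed <- FALSE
    for (v in seq_len(ctx$V)) {
      ct <- coupling_terms(st$z, ctx$pairs, st$C, st$phi, ctx$K)
      S <- st$loglik[[v]] + ct$logW[[v]] +
        matrix(log(st$pi[[v]]), ctx$N[v], ctx$K[v], byrow = TRUE)
      znew <- max.col(S, ties.method = "first")
      if (!identical(znew, st$z[[v]])) changed <- TRUE
      st$z[[v]] <- znew
    }
    if (!changed) break
  }
  st
}

# Assignment-prior part of the objective in the fitting mode (the data and
# hyperprior terms do not depend on C).
prior_objective <- function(ctx, st) {
  assignment_log_prior_normalized(st$z, st$pi, ctx$pairs, st$C, st$phi, ctx$K,
                                  mode = ctx$mode, enum_cap = ctx$config$enum_cap)
}

# (M2) re-match clusters across each coupled view pair. For small cluster
# counts every permutation is scored (the search is then exact and invariant
# to label permutations of the views); for larger K a greedy local search
# over pairwise row swaps applies the best strictly improving swap until
# none remains. Ties keep the incumbent matching.
m_corr <- function(ctx, st, exhaustive_max = 720L) {
  for (p in seq_along(ctx$pairs)) {
    if (length(ctx$pairs[[p]]$ti) == 0 || ctx$K[ctx$pairs[[p]]$v] < 2) next
    K <- ctx$K[ctx$pairs[[p]]$v]
    if (factorial(K) <= exhaustive_max) {
      perms <- all_permutations(K)
      cur <- prior_objective(ctx, st)
      best_val <- cur
      best_m <- NULL
      for (r in seq_len(nrow(perms))) {
        cand <- st
        cand$C[[p]] <- perms[r, ]
        val <- prior_objective(ctx, cand)
        if (val > best_val + 1e-10 * (abs(cur) + 1)) {
          best_val <- val
          best_m <- perms[r, ]
        }
      }
      if (!is.null(best_m)) st$C[[p]] <- best_m
      next
    }
    repeat {
      cur <- prior_objective(ctx, st)
      best_gain <- 0
      best_C <- NULL
      K <- ctx$K[ctx$pairs[[p]]$v]
      for (k1 in seq_len(K - 1)) {
        for (k2 in seq((k1 + 1), K)) {
          cand <- st
          cand$C[[p]][c(k1, k2)] <- cand$C[[p]][c(k2, k1)]
          val <- prior_objective(ctx, cand)
          gain <- val - cur
          if (gain > best_gain + 1e-10 * (abs(cur) + 1)) {
            best_gain <- gain
            best_C <- cand$C[[p]]
          }
        }
      }
      if (is.null(best_C)) break
      st$C[[p]] <- best_C
    }
  }
  st
}

# ---- (M3) mixture weights and coupling strengths -------------------------

# During the weight/coupling update the assignments and matchings are fixed,
# so the edge aggregation pattern is constant and only the per-edge factors
# log1p(w * phi) change. Edges are grouped by distinct weight once; each
# optimizer step then reduces to dense matrix arithmetic. Returns NULL when
# the weights are too heterogeneous to group (per-edge fallback is used).
precompute_coupling_counts <- function(ctx, z, C, max_groups = 64L) {
  out <- vector("list", length(ctx$pairs))
  for (p in seq_along(ctx$pairs)) {
    pr <- ctx$pairs[[p]]
    if (!length(pr$ti)) { out[[p]] <- list(); next }
    ws <- unique(pr$tw)
    if (length(ws) > max_groups) return(NULL)
    m <- C[[p]]
    minv <- order(m)
    out[[p]] <- lapply(ws, function(w) {
      sel <- pr$tw == w
      list(w = w,
           Cv = edge_agg(pr$ti[sel], z[[pr$u]][pr$tj[sel]],
                         rep(1, sum(sel)), pr$Nv, ctx$K[pr$u])[, m, drop = FALSE],
           Cu = edge_agg(pr$tj[sel], z[[pr$v]][pr$ti[sel]],
                         rep(1, sum(sel)), pr$Nu, ctx$K[pr$v])[, minv, drop = FALSE])
    })
  }
  out
}

unpack_weights_par <- function(par, ctx) {
  a <- vector("list", ctx$V)
  off <- 0
  pi <- vector("list", ctx$V)
  for (v in seq_len(ctx$V)) {
    av <- par[(off + 1):(off + ctx$K[v])]
    e <- exp(av - max(av))
    pi[[v]] <- e / sum(e)
    off <- off + ctx$K[v]
  }
  nP <- length(ctx$pairs)
  b <- if (nP) par[(off + 1):(off + nP)] else numeric(0)
  list(pi = pi, b = b, phi = softplus(b))
}

weights_fg_grouped <- function(par, ctx, z, counts, want_grad = TRUE) {
  up <- unpack_weights_par(par, ctx)
  pi <- up$pi; phi <- up$phi
  K <- ctx$K
  nP <- length(ctx$pairs)
  logW <- lapply(seq_len(ctx$V), function(v) matrix(0, ctx$N[v], K[v]))
  Dm <- if (want_grad) vector("list", nP)
  for (p in seq_len(nP)) {
    if (!length(counts[[p]])) next
    pr <- ctx$pairs[[p]]
    if (want_grad)
      Dm[[p]] <- list(v = matrix(0, pr$Nv, K[pr$v]), u = matrix(0, pr$Nu, K[pr$u]))
    for (g in counts[[p]]) {
      lw <- log1p(g$w * phi[p])
      logW[[pr$v]] <- logW[[pr$v]] + g$Cv * lw
      logW[[pr$u]] <- logW[[pr$u]] + g$Cu * lw
      if (want_grad) {
        dfac <- g$w / (1 + g$w * phi[p])
        Dm[[p]]$v <- Dm[[p]]$v + g$Cv * dfac
        Dm[[p]]$u <- Dm[[p]]$u + g$Cu * dfac
      }
    }
  }
  obj <- 0
  alpha <- lapply(seq_len(ctx$V), function(v) rep_len(ctx$priors$alpha, K[v]))
  P <- vector("list", ctx$V)
  ga <- vector("list", ctx$V)
  for (v in seq_len(ctx$V)) {
    S <- logW[[v]] + matrix(log(pi[[v]]), ctx$N[v], K[v], byrow = TRUE)
    lse <- row_logsumexp(S)
    obj <- obj + sum(S[cbind(seq_len(ctx$N[v]), z[[v]])] - lse) +
      ldirichlet(pi[[v]], alpha[[v]])
    if (want_grad) {
      P[[v]] <- exp(S - lse)
      ga[[v]] <- tabulate(z[[v]], K[v]) - colSums(P[[v]]) +
        (alpha[[v]] - 1) - pi[[v]] * sum(alpha[[v]] - 1)
    }
  }
  if (nP) obj <- obj + phi_log_prior(phi, ctx$priors)
  if (!want_grad) return(list(obj = obj))
  gphi <- numeric(nP)
  for (p in seq_len(nP)) {
    if (is.null(Dm[[p]])) next
    pr <- ctx$pairs[[p]]
    zv <- z[[pr$v]]; zu <- z[[pr$u]]
    gphi[p] <- sum(Dm[[p]]$v[cbind(seq_along(zv), zv)]) - sum(P[[pr$v]] * Dm[[p]]$v) +
      sum(Dm[[p]]$u[cbind(seq_along(zu), zu)]) - sum(P[[pr$u]] * Dm[[p]]$u)
  }
  gphi <- gphi + phi_log_prior_grad(pmax(phi, 1e-12), ctx$priors)
  list(obj = obj, grad = c(unlist(ga), gphi * sigmoid(up$b)))
}

# Objective and analytic gradient of the pseudolikelihood MAP target in the
# unconstrained parameterization: per-view softmax for pi, softplus for phi.
# Per-edge fallback for heterogeneous relation weights.
weights_obj_grad <- function(par, ctx, z, C, want_grad = TRUE) {
  V <- ctx$V
  K <- ctx$K
  nP <- length(ctx$pairs)
  a <- vector("list", V)
  off <- 0
  for (v in seq_len(V)) {
    a[[v]] <- par[(off + 1):(off + K[v])]
    off <- off + K[v]
  }
  b <- if (nP) par[(off + 1):(off + nP)] else numeric(0)
  pi <- lapply(a, function(av) {
    e <- exp(av - max(av))
    e / sum(e)
  })
  phi <- softplus(b)
  ct <- coupling_terms(z, ctx$pairs, C, phi, K, grad = want_grad)
  obj <- 0
  P <- vector("list", V)
  alpha <- lapply(seq_len(V), function(v) rep_len(ctx$priors$alpha, K[v]))
  ga <- vector("list", V)
  for (v in seq_len(V)) {
    S <- ct$logW[[v]] + matrix(log(pi[[v]]), ctx$N[v], K[v], byrow = TRUE)
    lse <- row_logsumexp(S)
    obj <- obj + sum(S[cbind(seq_len(ctx$N[v]), z[[v]])] - lse)
    obj <- obj + ldirichlet(pi[[v]], alpha[[v]])
    if (want_grad) {
      P[[v]] <- exp(S - lse)
      ga[[v]] <- tabulate(z[[v]], K[v]) - colSums(P[[v]]) +
        (alpha[[v]] - 1) - pi[[v]] * sum(alpha[[v]] - 1)
    }
  }
  if (nP) obj <- obj + phi_log_prior(phi, ctx$priors)
  if (!want_grad) return(list(obj = obj))
  gphi <- numeric(nP)
  for (p in seq_len(nP)) {
    g <- ct$grad[[p]]
    if (is.null(g)) next
    pr <- ctx$pairs[[p]]
    zv <- z[[pr$v]]; zu <- z[[pr$u]]
    gphi[p] <- sum(g$Dv[cbind(seq_along(zv), zv)]) - sum(P[[pr$v]] * g$Dv) +
      sum(g$Du[cbind(seq_along(zu), zu)]) - sum(P[[pr$u]] * g$Du)
  }
  if (nP) gphi <- gphi + phi_log_prior_grad(pmax(phi, 1e-12), ctx$priors)
  gb <- gphi * sigmoid(b)
  list(obj = obj, grad = c(unlist(ga), gb))
}

adam_maximize <- function(par, fg, steps, lr) {
  m <- v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_par <- par
  best_obj <- fg(par, want_grad = FALSE)$obj
  for (t in seq_len(steps)) {
    res <- fg(par, want_grad = TRUE)
    g <- res$grad
    if (any(!is.finite(g)))
      stop("non-finite gradient in the weight/coupling update")
    if (res$obj > best_obj) {
      best_obj <- res$obj
      best_par <- par
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    par <- par + lr * mh / (sqrt(vh) + eps)
  }
  fin <- fg(par, want_grad = FALSE)$obj
  if (fin > best_obj) {
    best_obj <- fin
    best_par <- par
  }
  list(par = best_par, obj = best_obj)
}

# Mean-field Gaussian variational update over the unconstrained parameters,
# reparameterized Monte-Carlo gradients; returns the variational mean mapped
# back to the constrained space.
bbvi_maximize <- function(par, fg, steps, lr, n_mc) {
  d <- length(par)
  mu <- par
  rho <- rep(log(0.05), d)
  st_m <- st_v <- numeric(2 * d)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(steps)) {
    gmu <- numeric(d)
    grho <- numeric(d)
    sdv <- exp(rho)
    for (s in seq_len(n_mc)) {
      epsn <- stats::rnorm(d)
      res <- fg(mu + sdv * epsn, want_grad = TRUE)
      if (any(!is.finite(res$grad)))
        stop("non-finite gradient in the BBVI update")
      gmu <- gmu + res$grad / n_mc
      grho <- grho + (res$grad * epsn * sdv) / n_mc
    }
    grho <- grho + 1  # entropy term d/drho of sum(rho)
    g <- c(gmu, grho)
    st_m <- b1 * st_m + (1 - b1) * g
    st_v <- b2 * st_v + (1 - b2) * g^2
    upd <- lr * (st_m / (1 - b1^t)) / (sqrt(st_v / (1 - b2^t)) + eps)
    mu <- mu + upd[seq_len(d)]
    rho <- rho + upd[(d + 1):(2 * d)]
  }
  list(par = mu, obj = fg(mu, want_grad = FALSE)$obj)
}

m_weights <- function(ctx, st) {
  cfg <- ctx$config
  alpha <- lapply(seq_len(ctx$V), function(v) rep_len(ctx$priors$alpha, ctx$K[v]))
  occupancy_pi <- function() lapply(seq_len(ctx$V), function(v) {
    w <- pmax(tabulate(st$z[[v]], ctx$K[v]) + alpha[[v]] - 1, 0)
    w / sum(w)
  })
  decoupled <- cfg$phi_fixed_zero || ctx$n_edges == 0
  if (decoupled) {
    # With no active coupling the MAP factorizes: Dirichlet-smoothed cluster
    # occupancies for pi, and phi at its prior mode (or frozen at zero).
    st$pi <- occupancy_pi()
    st$phi <- rep(if (cfg$phi_fixed_zero) 0 else phi_prior_mode(ctx$priors),
                  length(ctx$pairs))
    return(st)
  }
  if (cfg$pi_update == "occupancy") st$pi <- occupancy_pi()
  aref <- unlist(lapply(st$pi, function(p) log(pmax(p, 1e-300))))
  b0 <- softplus_inv(pmax(st$phi, 1e-8))
  if (ctx$mode == "exact" && ctx$edge_decomposable) {
    pre <- precompute_exact_edge_stats(ctx, st$z, st$C)
    fg_full <- function(par, want_grad = TRUE)
      weights_fg_exact_edges(par, ctx, pre, want_grad)
  } else if (ctx$mode == "exact") {
    # generic exact mode (small instances only): numerical gradient of the
    # exactly normalized log-prior plus hyperpriors
    fg_full <- function(par, want_grad = TRUE) exact_weights_fg(par, ctx, st, want_grad)
  } else {
    counts <- precompute_coupling_counts(ctx, st$z, st$C)
    fg_full <- if (!is.null(counts)) {
      function(par, want_grad = TRUE)
        weights_fg_grouped(par, ctx, st$z, counts, want_grad)
    } else {
      function(par, want_grad = TRUE)
        weights_obj_grad(par, ctx, st$z, st$C, want_grad)
    }
  }
  na <- length(aref)
  if (cfg$pi_update == "occupancy") {
    # weights fixed at their closed-form MAP; only the coupling strengths
    # move by gradient
    fg <- function(bv, want_grad = TRUE) {
      r <- fg_full(c(aref, bv), want_grad)
      if (want_grad) r$grad <- r$grad[(na + 1):(na + length(bv))]
      r
    }
    par0 <- b0
  } else {
    fg <- fg_full
    par0 <- c(aref, b0)
  }
  res <- if (cfg$optimizer == "adam") {
    adam_maximize(par0, fg, cfg$opt_steps, cfg$opt_lr)
  } else {
    bbvi_maximize(par0, fg, cfg$opt_steps, cfg$opt_lr, cfg$opt_mc_samples)
  }
  # never move to a worse point than the incumbent
  if (fg(par0, want_grad = FALSE)$obj > res$obj) res$par <- par0
  if (cfg$pi_update == "occupancy") {
    st$phi <- softplus(res$par)
  } else {
    off <- 0
    for (v in seq_len(ctx$V)) {
      av <- res$par[(off + 1):(off + ctx$K[v])]
      e <- exp(av - max(av))
      st$pi[[v]] <- e / sum(e)
      off <- off + ctx$K[v]
    }
    st$phi <- softplus(res$par[(off + 1):(off + length(ctx$pairs))])
  }
  st
}

# Exact-mode sufficient statistics when every related entity has degree one.
# The normalized log-prior then has the closed form
#   sum_vk n_vk log pi_vk
#   + sum_{matched edges} log(1 + w phi)
#   - sum_{edges} log(1 + w phi s_p),   s_p = sum_k pi_vk pi_u,m(k)
# so the (pi, phi) update only needs cluster occupancies and per-pair
# matched-edge counts grouped by distinct edge weight.
precompute_exact_edge_stats <- function(ctx, z, C) {
  nvk <- lapply(seq_len(ctx$V), function(v) tabulate(z[[v]], ctx$K[v]))
  pair_stats <- lapply(seq_along(ctx$pairs), function(p) {
    pr <- ctx$pairs[[p]]
    if (!length(pr$ti)) return(NULL)
    matched <- C[[p]][z[[pr$v]][pr$ti]] == z[[pr$u]][pr$tj]
    ws <- unique(pr$tw)
    lapply(ws, function(w) {
      sel <- pr$tw == w
      list(w = w, n = sum(sel), n_matched = sum(sel & matched))
    })
  })
  list(nvk = nvk, pair_stats = pair_stats, matchings = C)
}

weights_fg_exact_edges <- function(par, ctx, pre, want_grad = TRUE) {
  up <- unpack_weights_par(par, ctx)
  pi <- up$pi; phi <- up$phi
  K <- ctx$K
  nP <- length(ctx$pairs)
  alpha <- lapply(seq_len(ctx$V), function(v) rep_len(ctx$priors$alpha, K[v]))
  obj <- 0
  ga <- vector("list", ctx$V)
  for (v in seq_len(ctx$V)) {
    nz <- pre$nvk[[v]] > 0
    obj <- obj + sum((pre$nvk[[v]] * log(pi[[v]]))[nz]) +
      ldirichlet(pi[[v]], alpha[[v]])
    if (want_grad)
      ga[[v]] <- pre$nvk[[v]] - ctx$N[v] * pi[[v]] +
        (alpha[[v]] - 1) - pi[[v]] * sum(alpha[[v]] - 1)
  }
  gphi <- numeric(nP)
  for (p in seq_len(nP)) {
    stp <- pre$pair_stats[[p]]
    if (is.null(stp)) next
    pr <- ctx$pairs[[p]]
    m <- pre$matchings[[p]]
    minv <- order(m)
    s <- sum(pi[[pr$v]] * pi[[pr$u]][m])
    for (g in stp) {
      obj <- obj + g$n_matched * log1p(g$w * phi[p]) - g$n * log1p(g$w * phi[p] * s)
      if (want_grad) {
        gphi[p] <- gphi[p] + g$n_matched * g$w / (1 + g$w * phi[p]) -
          g$n * g$w * s / (1 + g$w * phi[p] * s)
        # d/da of -n log(1 + w phi s): ds/da_vk = pi_vk (pi_u,m(k) - s),
        # ds/da_ul = pi_ul (pi_v,minv(l) - s)
        fac <- g$n * g$w * phi[p] / (1 + g$w * phi[p] * s)
        ga[[pr$v]] <- ga[[pr$v]] - fac * pi[[pr$v]] * (pi[[pr$u]][m] - s)
        ga[[pr$u]] <- ga[[pr$u]] - fac * pi[[pr$u]] * (pi[[pr$v]][minv] - s)
      }
    }
  }
  if (nP) obj <- obj + phi_log_prior(phi, ctx$priors)
  if (!want_grad) return(list(obj = obj))
  gphi <- gphi + phi_log_prior_grad(pmax(phi, 1e-12), ctx$priors)
  list(obj = obj, grad = c(unlist(ga), gphi * sigmoid(up$b)))
}

exact_weights_fg <- function(par, ctx, st, want_grad) {
  val_at <- function(p) {
    V <- ctx$V; K <- ctx$K
    off <- 0
    pi <- vector("list", V)
    for (v in seq_len(V)) {
      av <- p[(off + 1):(off + K[v])]
      e <- exp(av - max(av))
      pi[[v]] <- e / sum(e)
      off <- off + K[v]
    }
    phi <- softplus(p[(off + 1):(off + length(ctx$pairs))])
    obj <- assignment_log_prior_normalized(st$z, pi, ctx$pairs, st$C, phi, K,
                                           mode = "exact",
                                           enum_cap = ctx$config$enum_cap)
    obj <- obj + sum(vapply(seq_len(V), function(v)
      ldirichlet(pi[[v]], rep_len(ctx$priors$alpha, K[v])), numeric(1)))
    obj + phi_log_prior(phi, ctx$priors)
  }
  obj <- val_at(par)
  if (!want_grad) return(list(obj = obj))
  h <- 1e-5
  g <- vapply(seq_along(par), function(j) {
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (val_at(pp) - val_at(pm)) / (2 * h)
  }, numeric(1))
  list(obj = obj, grad = g)
}

objective_full <- function(ctx, st) {
  ll <- 0
  for (v in seq_len(ctx$V))
    ll <- ll + sum(st$loglik[[v]][cbind(seq_len(ctx$N[v]), st$z[[v]])])
  lp <- prior_objective(ctx, st)
  lh <- sum(vapply(seq_len(ctx$V), function(v)
    ldirichlet(st$pi[[v]], rep_len(ctx$priors$alpha, ctx$K[v])), numeric(1)))
  if (length(st$phi)) lh <- lh + phi_log_prior(st$phi, ctx$priors)
  ll + lp + lh
}

# ---- the fitting loop ----------------------------------------------------

#' Fit the Bayesian multi-view clustering model
#'
#' Runs the modified hard-EM procedure over `config$restarts` restarts and
#' returns the best restart by final objective. Fully reproducible from
#' `(data, relations, config)`: all randomness derives from `config$seed`.
#'
#' @param data an [mv_dataset].
#' @param relations an [mv_relations] object (may be empty).
#' @param config a [bmvc_config].
#' @param base component distribution, see [gaussian_base()].
#' @return an object of class `bmvc_fit` with elements `state` (assignments
#'   `z`, mixture weights `pi`, component parameters `theta`, matchings `C`,
#'   coupling strengths `phi`), `objective`, `trace` (objective per EM
#'   iteration of the best restart), `restarts` (per-restart summary),
#'   `mode`, `seeds`, and `entity_ids`.
#' @examples
#' sim <- gen_two_view_shift(shift_config(n = 20), "complete_one_to_one", seed = 1)
#' fit <- fit_bmvc(sim$data, sim$relations,
#'                 bmvc_config(K = 2, restarts = 2, seed = 1, mode = "pseudo"))
#' fit$phi
#' @export
fit_bmvc <- function(data, relations = mv_relations(), config = bmvc_config(K = 2),
                     base = gaussian_base()) {
  ctx <- build_ctx(data, relations, config, base)
  seeds <- vapply(seq_len(config$restarts), function(r)
    derive_seed(config$seed, r), integer(1))
  best <- NULL
  summaries <- vector("list", config$restarts)
  traces <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    run <- with_seed(seeds[r], run_restart(ctx, seeds[r]))
    traces[[r]] <- run$trace
    summaries[[r]] <- data.frame(restart = r, seed = seeds[r],
                                 objective = run$objective,
                                 converged = run$converged,
                                 iterations = length(run$trace) - 1L)
    if (is.null(best) || run$objective > best$objective) {
      best <- run
      best$restart <- r
    }
  }
  restarts <- do.call(rbind, summaries)
  structure(list(state = best$state, objective = best$objective,
                 trace = best$trace, best_restart = best$restart,
                 restarts = restarts, all_traces = traces, seeds = seeds,
                 converged = best$converged, mode = ctx$mode,
                 config = config, entity_ids = ctx$ids,
                 view_names = ctx$vnames,
                 pair_names = names(ctx$pairs),
                 degenerate = any(ctx$degenerate)),
            class = "bmvc_fit")
}

em_loop <- function(ctx, st, max_iter, obj = objective_full(ctx, st)) {
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- e_step(ctx, st)
    st <- m_theta(ctx, st)
    st <- m_corr(ctx, st)
    st <- m_weights(ctx, st)
    new_obj <- objective_full(ctx, st)
    trace <- c(trace, new_obj)
    if (new_obj - obj < ctx$config$tol * (abs(obj) + 1)) {
      obj <- max(obj, new_obj)
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  list(st = st, obj = trace[length(trace)], trace = trace, converged = converged)
}

# Correspondence matchings are not identifiable from the relation structure
# alone when an alternative permutation carries (almost) the same matched
# edge weight - e.g. when two clusters' cross-view relations are split
# half-and-half. The EM path then commits to whichever branch the
# initialization suggested. At convergence, every near-tied alternative
# matching is evaluated with a short EM re-convergence and adopted if it
# strictly improves the objective.
tied_matching_candidates <- function(ctx, st, weight_tol = 0.9) {
  out <- list()
  for (p in seq_along(ctx$pairs)) {
    pr <- ctx$pairs[[p]]
    if (!length(pr$ti)) next
    K <- ctx$K[pr$v]
    if (K < 2 || factorial(K) > 720) next
    J <- edge_agg(st$z[[pr$v]][pr$ti], st$z[[pr$u]][pr$tj], pr$tw, K, K)
    t0 <- sum(J[cbind(seq_len(K), st$C[[p]])])
    perms <- all_permutations(K)
    for (r in seq_len(nrow(perms))) {
      m <- perms[r, ]
      if (all(m == st$C[[p]])) next
      if (sum(J[cbind(seq_len(K), m)]) >= weight_tol * t0)
        out[[length(out) + 1L]] <- list(p = p, m = m)
    }
  }
  out
}

run_restart <- function(ctx, restart_seed) {
  st <- init_state(ctx, restart_seed)
  run <- em_loop(ctx, st, ctx$config$max_iter)
  st <- run$st
  obj <- run$obj
  trace <- run$trace
  converged <- run$converged
  if (length(ctx$pairs) && !ctx$config$phi_fixed_zero) {
    repeat {
      improved <- FALSE
      for (cand in tied_matching_candidates(ctx, st)) {
        st2 <- st
        st2$C[[cand$p]] <- cand$m
        r2 <- em_loop(ctx, st2, max_iter = 10L)
        if (r2$obj > obj + ctx$config$tol * (abs(obj) + 1)) {
          st <- r2$st
          obj <- r2$obj
          trace <- c(trace, r2$trace[-1])
          converged <- r2$converged
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  names(st$phi) <- names(ctx$pairs)
  names(st$C) <- names(ctx$pairs)
  names(st$z) <- ctx$vnames
  names(st$pi) <- ctx$vnames
  names(st$theta) <- ctx$vnames
  list(state = st[c("z", "pi", "theta", "C", "phi")],
       objective = obj, trace = trace, converged = converged)
}

#' @export
print.bmvc_fit <- function(x, ...) {
  cat("BMVC fit (", x$mode, " mode): ", length(x$state$z), " view(s), ",
      nrow(x$restarts), " restart(s)\n", sep = "")
  cat("  best objective:", format(x$objective, digits = 8),
      "(restart", x$best_restart, ")\n")
  if (length(x$state$phi))
    cat("  coupling strengths:",
        paste(sprintf("%s=%.4g", names(x$state$phi), x$state$phi), collapse = ", "),
        "\n")
  invisible(x)
}

#' Coupling strengths of a fit
#' @param fit a `bmvc_fit`.
#' @return named numeric vector of fitted phi values, one per coupled pair.
#' @export
coupling_strengths <- function(fit) {
  stopifnot(inherits(fit, "bmvc_fit"))
  fit$state$phi
}
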