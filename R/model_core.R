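# Core model quantities: the coupled assignment prior, its exact partition
# function, per-entity full conditionals, the Besag pseudolikelihood of the
# prior, and the joint objective maximized by inference.
#
# The coupled prior over all hard assignments Z is, up to normalization,
#   prod_v prod_i pi_{v, z_vi} * prod_{v<u} prod_{i,j} (1 + C_vu[z_vi, z_uj] R_vu[i,j] phi_vu)
# so a related pair of entities placed in matched clusters multiplies the
# prior mass by (1 + R * phi). All arithmetic is in the log domain with
# log1p for the coupling factor.

# Accept either an mv_relations object (compiled on the fly) or an already
# compiled pair list.
as_pairs <- function(relations, N, vnames = NULL) {
  if (is.null(relations)) return(list())
  if (inherits(relations, "mv_relations")) {
    if (is.null(vnames)) vnames <- paste0("view", seq_along(N))
    return(compile_relations(relations, N, vnames))
  }
  relations
}

resolve_phi <- function(phi, pairs) {
  if (length(pairs) == 0) return(numeric(0))
  if (is.null(phi)) phi <- 0
  if (length(phi) == 1) phi <- rep(phi, length(pairs))
  if (!is.null(names(phi)) && all(names(pairs) %in% names(phi)))
    phi <- phi[names(pairs)]
  if (length(phi) != length(pairs))
    stop("need one coupling strength per coupled view pair")
  if (any(phi < 0)) stop("coupling strengths must be non-negative")
  as.numeric(phi)
}

# Sum edge quantities into an N x K matrix indexed by (own entity, partner's
# cluster label).
edge_agg <- function(idx, lab, val, N, K) {
  M <- matrix(0, N, K)
  if (length(idx)) {
    lin <- (lab - 1L) * N + idx
    s <- rowsum(val, group = lin, reorder = TRUE)
    M[sort(unique(lin))] <- s
  }
  M
}

# Per-view coupling matrices logW[[v]][i, k] = sum over related entities j in
# other views of log(1 + R_ij * phi) restricted to edges whose partner label
# is matched to k. With grad = TRUE also returns, per pair, the derivative
# of logW with respect to phi for both endpoint views.
coupling_terms <- function(z, pairs, C, phi, K, grad = FALSE) {
  V <- length(z)
  N <- lengths(z)
  logW <- lapply(seq_len(V), function(v) matrix(0, N[v], K[v]))
  pg <- if (grad) vector("list", length(pairs))
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (length(pr$ti) == 0) next
    m <- C[[p]]
    minv <- order(m)
    lw <- log1p(pr$tw * phi[p])
    Lv <- edge_agg(pr$ti, z[[pr$u]][pr$tj], lw, pr$Nv, K[pr$u])
    Lu <- edge_agg(pr$tj, z[[pr$v]][pr$ti], lw, pr$Nu, K[pr$v])
    logW[[pr$v]] <- logW[[pr$v]] + Lv[, m, drop = FALSE]
    logW[[pr$u]] <- logW[[pr$u]] + Lu[, minv, drop = FALSE]
    if (grad) {
      dw <- pr$tw / (1 + pr$tw * phi[p])
      Dv <- edge_agg(pr$ti, z[[pr$u]][pr$tj], dw, pr$Nv, K[pr$u])
      Du <- edge_agg(pr$tj, z[[pr$v]][pr$ti], dw, pr$Nu, K[pr$v])
      pg[[p]] <- list(Dv = Dv[, m, drop = FALSE], Du = Du[, minv, drop = FALSE])
    }
  }
  list(logW = logW, grad = pg)
}

#' Unnormalized log-prior of a joint cluster assignment
#'
#' Evaluates the log of the coupled assignment prior (up to its partition
#' function): the sum of per-entity `log pi` terms plus, for every related
#' entity pair placed in matched clusters, `log(1 + R * phi)`. Pairs with no
#' relation contribute nothing, and the coupling term vanishes when all
#' `phi = 0`.
#'
#' @param z list of integer cluster-label vectors, one per view.
#' @param pi list of mixture-weight vectors, one per view.
#' @param relations an [mv_relations] object (or `NULL` for independent
#'   views).
#' @param C list of correspondence matchings, one integer permutation per
#'   coupled view pair in compiled order (`NULL` for identity).
#' @param phi coupling strengths, one per coupled pair (scalar recycled).
#' @return a single numeric value.
#' @export
assignment_log_prior <- function(z, pi, relations = NULL, C = NULL, phi = NULL) {
  K <- lengths(pi)
  N <- lengths(z)
  z <- check_assignments(z, N, K)
  pairs <- as_pairs(relations, N, names(pi) %||% names(z))
  phi <- resolve_phi(phi, pairs)
  C <- check_matching(C, pairs, K)
  out <- sum(vapply(seq_along(z), function(v) sum(log(pi[[v]][z[[v]]])), numeric(1)))
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (length(pr$ti) == 0) next
    matched <- C[[p]][z[[pr$v]][pr$ti]] == z[[pr$u]][pr$tj]
    out <- out + sum(log1p(pr$tw[matched] * phi[p]))
  }
  out
}

#' Exact log partition function of the coupled assignment prior
#'
#' The log of the sum of the unnormalized prior over every joint cluster
#' assignment of every entity in every view. The sum factorizes exactly over
#' the connected components of the relationship graph (entities with no
#' relations contribute a normalized multinomial, i.e. a factor of one), so
#' it is computed component by component: single-edge components in closed
#' form, larger components by exhaustive enumeration of their joint
#' assignments, refused above `enum_cap` states per component. When all
#' `phi = 0` the prior is a product of normalized multinomials and the log
#' partition function is exactly 0.
#'
#' @inheritParams assignment_log_prior
#' @param N integer vector of entity counts per view.
#' @param enum_cap maximum number of joint assignments enumerated within one
#'   connected component of the relationship graph.
#' @return the log partition function (a single numeric value).
#' @export
assignment_log_partition <- function(pi, relations = NULL, C = NULL, phi = NULL,
                                     N, enum_cap = 1e6) {
  K <- lengths(pi)
  if (length(N) != length(K)) stop("`N` must give one entity count per view")
  pairs <- as_pairs(relations, N, names(pi))
  phi <- resolve_phi(phi, pairs)
  C <- check_matching(C, pairs, K)
  exact_log_partition_engine(pi, pairs, C, phi, N, enum_cap)
}

# Component-wise partition function. Assumes validated inputs.
exact_log_partition_engine <- function(pi, pairs, C, phi, N, enum_cap = 1e6) {
  K <- lengths(pi)
  n_tot <- sum(N)
  offs <- cumsum(c(0L, N))
  gi <- gj <- integer(0); ew <- numeric(0); ep <- integer(0)
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (!length(pr$ti)) next
    gi <- c(gi, offs[pr$v] + pr$ti)
    gj <- c(gj, offs[pr$u] + pr$tj)
    ew <- c(ew, pr$tw)
    ep <- c(ep, rep.int(p, length(pr$ti)))
  }
  if (!length(gi)) return(0)
  deg <- tabulate(c(gi, gj), n_tot)
  if (all(deg <= 1L)) {
    # every component is a single edge: sum_{k,l} pi_vk pi_ul (1 + C[k,l] w phi)
    # = 1 + w * phi * sum_k pi_vk pi_u,m(k)
    out <- 0
    for (p in seq_along(pairs)) {
      pr <- pairs[[p]]
      if (!length(pr$ti)) next
      s <- sum(pi[[pr$v]] * pi[[pr$u]][C[[p]]])
      out <- out + sum(log1p(pr$tw * phi[p] * s))
    }
    return(out)
  }
  # generic path: union-find components, exhaustive enumeration per component
  parent <- seq_len(n_tot)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(gi)) {
    a <- find(gi[e]); b <- find(gj[e])
    if (a != b) parent[a] <- b
  }
  rel_nodes <- sort(unique(c(gi, gj)))
  comp_of <- vapply(rel_nodes, find, integer(1))
  node_view <- rep.int(seq_along(N), N)
  out <- 0
  for (cp in unique(comp_of)) {
    nodes <- rel_nodes[comp_of == cp]
    ks <- K[node_view[nodes]]
    if (prod(ks) > enum_cap)
      stop("a connected component of the relationship graph exceeds the ",
           "enumeration cap; the exact partition function is intractable ",
           "here - use the pseudolikelihood")
    in_comp <- gi %in% nodes
    ei <- match(gi[in_comp], nodes)
    ej <- match(gj[in_comp], nodes)
    cw <- ew[in_comp]
    cp_pair <- ep[in_comp]
    grid <- as.matrix(do.call(expand.grid,
                              c(lapply(ks, seq_len), list(KEEP.OUT.ATTRS = FALSE))))
    logpi_node <- lapply(seq_along(nodes),
                         function(t) log(pi[[node_view[nodes[t]]]]))
    lp <- vapply(seq_len(nrow(grid)), function(r) {
      zz <- grid[r, ]
      val <- 0
      for (t in seq_along(nodes)) val <- val + logpi_node[[t]][zz[t]]
      for (e in seq_along(ei)) {
        if (C[[cp_pair[e]]][zz[ei[e]]] == zz[ej[e]])
          val <- val + log1p(cw[e] * phi[cp_pair[e]])
      }
      val
    }, numeric(1))
    out <- out + logsumexp(lp)
  }
  out
}

#' Full conditional distribution of one entity's cluster assignment
#'
#' Holding every other assignment fixed, the conditional probability that
#' entity `i` of view `v` belongs to cluster `k` is proportional to
#' `exp(data_loglik[k]) * pi_vk * prod_j (1 + C[k, z_uj] R[i,j] phi)` over the
#' entities `j` related to `i` in the other views. Supplying a zero data term
#' gives the prior full conditional used by the pseudolikelihood.
#'
#' @inheritParams assignment_log_prior
#' @param v,i view and entity index of the assignment being resampled.
#' @param data_loglik numeric vector of per-cluster data log-likelihoods for
#'   entity `i` (defaults to zeros).
#' @return a probability vector over the `K_v` clusters (sums to 1).
#' @export
assignment_conditional <- function(v, i, z, pi, relations = NULL, C = NULL,
                                   phi = NULL, data_loglik = NULL) {
  K <- lengths(pi)
  N <- lengths(z)
  z <- check_assignments(z, N, K)
  if (v < 1 || v > length(z) || i < 1 || i > N[v]) stop("entity index out of range")
  if (is.null(data_loglik)) data_loglik <- rep(0, K[v])
  if (length(data_loglik) != K[v] || any(!is.finite(data_loglik)))
    stop("`data_loglik` must be a finite vector of length K_v")
  pairs <- as_pairs(relations, N, names(pi) %||% names(z))
  phi <- resolve_phi(phi, pairs)
  C <- check_matching(C, pairs, K)
  score <- data_loglik + log(pi[[v]])
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (length(pr$ti) == 0) next
    if (pr$v == v) {
      sel <- pr$ti == i
      if (!any(sel)) next
      labs <- z[[pr$u]][pr$tj[sel]]
      w <- pr$tw[sel]
      for (k in seq_len(K[v]))
        score[k] <- score[k] + sum(log1p(w[labs == C[[p]][k]] * phi[p]))
    } else if (pr$u == v) {
      sel <- pr$tj == i
      if (!any(sel)) next
      labs <- z[[pr$v]][pr$ti[sel]]
      w <- pr$tw[sel]
      minv <- order(C[[p]])
      for (k in seq_len(K[v]))
        score[k] <- score[k] + sum(log1p(w[labs == minv[k]] * phi[p]))
    }
  }
  p_out <- exp(score - logsumexp(score))
  p_out / sum(p_out)
}

#' Besag pseudolikelihood of the coupled assignment prior
#'
#' The sum over all entities of the log full-conditional probability of their
#' current assignment (with a zero data term). This is the tractable
#' surrogate for the normalized log-prior when the partition function cannot
#' be enumerated; the two agree exactly whenever no relations are present.
#'
#' @inheritParams assignment_log_prior
#' @return a single numeric value.
#' @export
pseudo_log_prior <- function(z, pi, relations = NULL, C = NULL, phi = NULL) {
  K <- lengths(pi)
  N <- lengths(z)
  z <- check_assignments(z, N, K)
  pairs <- as_pairs(relations, N, names(pi) %||% names(z))
  phi <- resolve_phi(phi, pairs)
  C <- check_matching(C, pairs, K)
  pseudo_log_prior_engine(z, pi, pairs, C, phi, K)
}

# Engine shared with inference: assumes validated inputs.
pseudo_log_prior_engine <- function(z, pi, pairs, C, phi, K) {
  ct <- coupling_terms(z, pairs, C, phi, K)
  out <- 0
  for (v in seq_along(z)) {
    S <- ct$logW[[v]] + matrix(log(pi[[v]]), length(z[[v]]), K[v], byrow = TRUE)
    out <- out + sum(S[cbind(seq_along(z[[v]]), z[[v]])] - row_logsumexp(S))
  }
  out
}

# Normalized log-prior of the assignments in the requested mode.
assignment_log_prior_normalized <- function(z, pi, pairs, C, phi, K,
                                            mode = c("pseudo", "exact"),
                                            enum_cap = 1e6) {
  mode <- match.arg(mode)
  if (mode == "pseudo") return(pseudo_log_prior_engine(z, pi, pairs, C, phi, K))
  lp <- 0
  for (v in seq_along(z)) lp <- lp + sum(log(pi[[v]][z[[v]]]))
  for (p in seq_along(pairs)) {
    pr <- pairs[[p]]
    if (length(pr$ti) == 0) next
    matched <- C[[p]][z[[pr$v]][pr$ti]] == z[[pr$u]][pr$tj]
    lp <- lp + sum(log1p(pr$tw[matched] * phi[p]))
  }
  lp - exact_log_partition_engine(pi, pairs, C, phi, N = lengths(z), enum_cap = enum_cap)
}

#' Joint objective of the coupled mixture model
#'
#' The scalar maximized by inference: the data log-likelihood under the hard
#' assignments, plus the assignment log-prior (exact, or its pseudolikelihood
#' approximation), plus the log hyperprior densities of the mixture weights
#' and the coupling strengths. With all `phi = 0` and flat hyperpriors this
#' is exactly the sum of independent hard-assignment mixture objectives.
#'
#' @inheritParams assignment_log_prior
#' @param data an [mv_dataset].
#' @param theta list (per view) of lists (per cluster) of component
#'   parameters for `base`.
#' @param priors a [bmvc_priors] object.
#' @param mode `"pseudo"` or `"exact"`; exact mode requires a tractable
#'   partition function.
#' @param base component distribution, see [gaussian_base()].
#' @param enum_cap enumeration cap for exact mode.
#' @return a single numeric value.
#' @export
joint_objective <- function(data, z, pi, theta, relations = NULL, C = NULL,
                            phi = NULL, priors = bmvc_priors(),
                            mode = c("pseudo", "exact"),
                            base = gaussian_base(), enum_cap = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "mv_dataset"))
  N <- view_sizes(data)
  K <- lengths(pi)
  z <- check_assignments(z, N, K)
  pairs <- as_pairs(relations, N, view_names(data))
  phi <- resolve_phi(phi, pairs)
  C <- check_matching(C, pairs, K)
  ll <- 0
  for (v in seq_along(z)) {
    L <- component_loglik(data$views[[v]]$X, theta[[v]], base)
    ll <- ll + sum(L[cbind(seq_len(N[v]), z[[v]])])
  }
  lp <- assignment_log_prior_normalized(z, pi, pairs, C, phi, K, mode, enum_cap)
  lh <- sum(vapply(pi, function(p) ldirichlet(p, priors$alpha), numeric(1)))
  if (length(phi)) lh <- lh + phi_log_prior(phi, priors)
  ll + lp + lh
}
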