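# Brute-force oracles written independently of the package's computation
# paths: direct substitution in the linear domain, exhaustive enumeration,
# and explicit pair counting.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unnormalized coupled-prior probability of one joint assignment, by direct
# substitution. `edges` is a data.frame with columns p (pair index), v, u
# (view indices), i, j (entity indices) and w (weight); C is a list of
# matching vectors, phi a vector per pair.
oracle_unnorm <- function(z, pi, edges, C, phi) {
  val <- 1
  for (v in seq_along(z)) val <- val * prod(pi[[v]][z[[v]]])
  if (!is.null(edges) && nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ed <- edges[e, ]
      if (C[[ed$p]][z[[ed$v]][ed$i]] == z[[ed$u]][ed$j])
        val <- val * (1 + ed$w * phi[ed$p])
    }
  }
  val
}

# Exhaustive enumeration of the partition function over every joint
# assignment of every entity.
oracle_partition <- function(pi, edges, C, phi, N) {
  K <- lengths(pi)
  slot_view <- rep.int(seq_along(N), N)
  grid <- do.call(expand.grid, lapply(slot_view, function(v) seq_len(K[v])))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    row <- as.integer(grid[r, ])
    z <- split(row, slot_view)
    total <- total + oracle_unnorm(z, pi, edges, C, phi)
  }
  total
}

# Random small coupled instance: V views with equal K (required by the
# correspondence matching), a handful of entities, Bernoulli edges with unit
# or continuous weights, random mixture weights, matchings and coupling
# strengths. Returns both the package-facing objects and the raw pieces the
# oracles consume.
random_instance <- function(seed, V = NULL, max_total_n = 6, K = NULL,
                            weighted = NULL) {
  set.seed(seed)
  V <- V %||% sample(2:3, 1)
  K <- K %||% sample(2:3, 1)
  repeat {
    N <- sample(1:3, V, replace = TRUE)
    if (sum(N) <= max_total_n) break
  }
  weighted <- weighted %||% (runif(1) < 0.5)
  pi <- lapply(seq_len(V), function(v) {
    w <- rgamma(K, 1) + 0.05
    w / sum(w)
  })
  vn <- paste0("view", seq_len(V))
  pair_idx <- utils::combn(V, 2)
  blocks <- list()
  edges <- NULL
  C <- list()
  phi <- numeric(0)
  p <- 0
  for (c_i in seq_len(ncol(pair_idx))) {
    v <- pair_idx[1, c_i]; u <- pair_idx[2, c_i]
    R <- matrix(0, N[v], N[u])
    mask <- matrix(runif(N[v] * N[u]) < 0.5, N[v], N[u])
    R[mask] <- if (weighted) round(runif(sum(mask), 0.2, 2), 2) else 1
    p <- p + 1
    blocks[[p]] <- relation_block(vn[v], vn[u], R)
    C[[p]] <- sample(K)
    phi[p] <- round(runif(1, 0, 3), 3)
    idx <- which(R > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- rbind(edges, data.frame(p = p, v = v, u = u,
                                       i = idx[, 1], j = idx[, 2],
                                       w = R[idx]))
    }
  }
  z <- lapply(seq_len(V), function(v) sample.int(K, N[v], replace = TRUE))
  names(z) <- names(pi) <- vn
  list(V = V, N = N, K = rep(K, V), pi = pi, z = z,
       relations = mv_relations(blocks), edges = edges, C = C, phi = phi)
}

# Chance-corrected Rand agreement by explicit pair counting.
oracle_ari <- function(a, b) {
  n <- length(a)
  if (n < 2) return(1)
  s_ab <- s_a <- s_b <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s_ab <- s_ab + 1
      if (sa) s_a <- s_a + 1
      if (sb) s_b <- s_b + 1
    }
  }
  tot <- choose(n, 2)
  expected <- s_a * s_b / tot
  max_idx <- (s_a + s_b) / 2
  if (abs(max_idx - expected) < 1e-12) {
    same <- identical(as.integer(factor(a)), as.integer(factor(b)))
    return(if (same) 1 else 0)
  }
  (s_ab - expected) / (max_idx - expected)
}

# Two views, one entity each, K = 2, uniform weights, a single unit edge.
tiny_two_view <- function(phi = 1) {
  list(z = list(v1 = 1L, v2 = 1L),
       pi = list(v1 = c(0.5, 0.5), v2 = c(0.5, 0.5)),
       relations = mv_relations(list(relation_block("v1", "v2", matrix(1, 1, 1)))),
       phi = phi)
}

# Well-separated Gaussian blobs with labels.
make_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_along(centers), each = n_per)
  X <- t(vapply(lab, function(k) centers[[k]] + rnorm(length(centers[[k]]), 0, sd),
                numeric(length(centers[[1]]))))
  rownames(X) <- sprintf("e%d", seq_along(lab))
  list(X = X, labels = lab)
}
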