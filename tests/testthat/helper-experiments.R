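# Shared pieces for the experiment-level checks.

# Fraction of clusters whose C-matched partner attains the row maximum of
# the structural affinity map (ties count as attained).
matched_row_max_fraction <- function(z_v, z_u, R, matching, K) {
  am <- affinity_map(z_v, z_u, R, K_v = K, K_u = K, matching = matching)
  hits <- vapply(seq_len(K), function(k) {
    row <- am$scores[k, ]
    if (all(is.na(row))) return(NA)
    row[matching[k]] >= max(row, na.rm = TRUE) - 1e-9
  }, logical(1))
  mean(hits, na.rm = TRUE)
}

# Best-case matching for an independent clustering pair: the permutation
# maximizing the matched relation weight (exhaustive, small K).
best_weight_matching <- function(z_v, z_u, R, K) {
  perms <- bmvc:::all_permutations(K)
  J <- bmvc:::affinity_components(z_v, z_u, R, K, K)
  w <- apply(perms, 1, function(m) sum(J[cbind(seq_len(K), m)]))
  perms[which.max(w), ]
}

# Weak four-cluster structure in three dimensions; the base matrix for the
# replicate-views affinity experiment.
weak_cluster_matrix <- function(n_per = 50, seed = 1) {
  set.seed(seed)
  lab <- rep(1:4, each = n_per)
  mu <- list(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  X <- t(vapply(lab, function(k) mu[[k]] + rnorm(3), numeric(3)))
  rownames(X) <- sprintf("g%d", seq_along(lab))
  X
}
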