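# Synthetic-data generators for benchmarking the coupled model: two-cluster
# shift simulations under three relationship topologies, a binomial
# randomization mechanism that degrades inter-view dependence, a four-cluster
# simulation with two kinds of confounding, and a pseudo-omics generator that
# derives two noisy, partially duplicated views from a single data matrix.

#' Configuration of the two-cluster shift simulation
#'
#' Two Gaussian clusters A and B in each of two views; related samples are
#' generated by the same cluster in both views, and in the second view half
#' of the cluster-A samples are shifted along the axis between the cluster
#' means by a random fraction `s_i ~ N(mu_s, sigma_s)`.
#'
#' @param mu_a,mu_b cluster mean vectors.
#' @param sigma_a,sigma_b isotropic cluster standard deviations.
#' @param mu_s,sigma_s mean and standard deviation of the shift fraction.
#' @param n samples per cluster per view.
#' @param dims data dimensionality (defaults to `length(mu_a)`).
#' @param clamp clamp sampled shift fractions to `[0, 1]`.
#' @return an object of class `shift_config`.
#' @export
shift_config <- function(mu_a = c(0, 0), mu_b = c(4, 0), sigma_a = 0.5,
                         sigma_b = 0.5, mu_s = 0.5, sigma_s = 0.05, n = 100L,
                         dims = length(mu_a), clamp = FALSE) {
  stopifnot(sigma_a > 0, sigma_b > 0, sigma_s > 0, n >= 1, dims >= 1,
            length(mu_a) == dims, length(mu_b) == dims)
  structure(list(mu_a = mu_a, mu_b = mu_b, sigma_a = sigma_a, sigma_b = sigma_b,
                 mu_s = mu_s, sigma_s = sigma_s, n = as.integer(n),
                 dims = as.integer(dims), clamp = clamp),
            class = "shift_config")
}

#' Shift a sample toward the opposite cluster mean
#'
#' Applies `x + s * (mu_b - mu_a)`: a fraction `s` of the displacement from
#' the cluster-A mean to the cluster-B mean.
#'
#' @param x sample vector (or matrix of samples in rows).
#' @param s shift fraction(s); recycled over rows when `x` is a matrix.
#' @param mu_a,mu_b the two cluster means.
#' @return the shifted sample(s).
#' @export
apply_shift <- function(x, s, mu_a, mu_b) {
  delta <- mu_b - mu_a
  if (is.matrix(x)) {
    x + outer(rep_len(s, nrow(x)), delta)
  } else {
    x + s * delta
  }
}

#' Binomial randomization of view-2 generating labels
#'
#' Degrades the dependence between the views by resampling which cluster
#' generates each view-2 sample, given its baseline (related) cluster.
#' As printed rule (`complement = FALSE`): a baseline cluster-A sample is
#' generated by A with probability `p` and by B otherwise; a baseline
#' cluster-B sample is generated by B with probability `1 - p`. With
#' `complement = TRUE` the A rule is flipped (A with probability `1 - p`),
#' which makes dependence decay monotonically from complete at `p = 0` to
#' none at `p = 0.5`.
#'
#' @param labels integer baseline labels (1 = A, 2 = B).
#' @param p randomization probability in `[0, 0.5]`.
#' @param seed integer seed.
#' @param complement use the dependence-decreasing variant of the A rule.
#' @return a list with `baseline` and `realized` label vectors.
#' @export
apply_binomial_randomization <- function(labels, p, seed = 1L, complement = FALSE) {
  if (p < 0 || p > 0.5) stop("`p` must lie in [0, 0.5]")
  labels <- as.integer(labels)
  if (any(!labels %in% c(1L, 2L))) stop("binary baseline labels (1/2) required")
  with_seed(seed, {
    u <- stats::runif(length(labels))
    p_a <- if (complement) 1 - p else p
    realized <- ifelse(labels == 1L, ifelse(u < p_a, 1L, 2L),
                       ifelse(u < 1 - p, 2L, 1L))
    list(baseline = labels, realized = as.integer(realized))
  })
}

draw_gauss <- function(n, mu, sigma) {
  d <- length(mu)
  matrix(stats::rnorm(n * d), n, d) * sigma + matrix(mu, n, d, byrow = TRUE)
}

draw_components <- function(labels, means, sigmas) {
  d <- length(means[[1]])
  X <- matrix(0, length(labels), d)
  for (k in seq_along(means)) {
    idx <- which(labels == k)
    if (length(idx)) X[idx, ] <- draw_gauss(length(idx), means[[k]], sigmas[[k]])
  }
  X
}

sim_output <- function(data, relations, truth, meta) {
  structure(list(data = data, relations = relations, truth = truth, meta = meta),
            class = "bmvc_sim")
}

#' @export
print.bmvc_sim <- function(x, ...) {
  cat("Simulated multi-view dataset (", x$meta$design, ")\n", sep = "")
  print(x$data)
  print(x$relations)
  invisible(x)
}

# Draw the shifted half of the view-2 cluster-A samples and apply the shift.
shift_half_a <- function(X2, realized, config) {
  ia <- which(realized == 1L)
  shifted <- integer(0)
  if (length(ia) >= 2) {
    shifted <- sort(sample(ia, floor(length(ia) / 2)))
    s <- stats::rnorm(length(shifted), config$mu_s, config$sigma_s)
    if (config$clamp) s <- pmin(pmax(s, 0), 1)
    X2[shifted, ] <- apply_shift(X2[shifted, , drop = FALSE], s,
                                 config$mu_a, config$mu_b)
  }
  list(X2 = X2, shifted = shifted)
}

#' Two-view, two-cluster shift simulation
#'
#' Generates the two-cluster confounding benchmark: related samples come
#' from the same cluster in both views and half of the view-2 cluster-A
#' samples are shifted toward cluster B (see [shift_config()]). The
#' relationship topology is one of: `half_one_to_one` (one-to-one edges for
#' a random half of the view-2 entities), `complete_one_to_one` (a full
#' bijection), or `two_to_one` (view 2 has twice as many samples, mapping in
#' pairs to single view-1 samples). Optionally the view-2 generating labels
#' are degraded by [apply_binomial_randomization()] with probability `p`.
#'
#' @param config a [shift_config].
#' @param topology relationship structure between the views.
#' @param seed integer seed; the output is reproducible from
#'   `(config, topology, seed)`.
#' @param p optional binomial randomization probability.
#' @param complement passed to [apply_binomial_randomization()].
#' @return a `bmvc_sim`: `data` ([mv_dataset]), `relations`
#'   ([mv_relations]), `truth` (per-view generating labels) and `meta`.
#' @export
gen_two_view_shift <- function(config = shift_config(),
                               topology = c("complete_one_to_one",
                                            "half_one_to_one", "two_to_one"),
                               seed = 1L, p = NULL, complement = FALSE) {
  topology <- match.arg(topology)
  stopifnot(inherits(config, "shift_config"))
  with_seed(seed, {
    n <- config$n
    N1 <- 2L * n
    lab1 <- rep(1:2, each = n)
    means <- list(config$mu_a, config$mu_b)
    sigmas <- list(config$sigma_a, config$sigma_b)
    X1 <- draw_components(lab1, means, sigmas)
    N2 <- if (topology == "two_to_one") 2L * N1 else N1
    partner <- if (topology == "two_to_one") rep(seq_len(N1), each = 2L) else seq_len(N2)
    baseline2 <- lab1[partner]
    realized2 <- if (!is.null(p)) {
      apply_binomial_randomization(baseline2, p, seed = derive_seed(seed, 17L),
                                   complement = complement)$realized
    } else baseline2
    X2 <- draw_components(realized2, means, sigmas)
    sh <- shift_half_a(X2, realized2, config)
    edges <- switch(topology,
      complete_one_to_one = cbind(seq_len(N1), seq_len(N1)),
      two_to_one = cbind(partner, seq_len(N2)),
      half_one_to_one = {
        related <- sort(sample(N2, floor(N2 / 2)))
        cbind(partner[related], related)
      })
    rownames(X1) <- sprintf("v1_e%d", seq_len(N1))
    rownames(sh$X2) <- sprintf("v2_e%d", seq_len(N2))
    data <- mv_dataset(list(view1 = X1, view2 = sh$X2))
    R <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                              dims = c(N1, N2))
    relations <- mv_relations(list(relation_block("view1", "view2", R)))
    sim_output(data, relations,
               truth = list(view1 = lab1, view2 = realized2),
               meta = list(design = paste0("two_cluster_shift/", topology),
                           config = config, topology = topology, seed = seed,
                           p = p, complement = complement,
                           baseline2 = baseline2, shifted = sh$shifted))
  })
}

#' Configuration of the four-cluster confounded simulation
#'
#' @param mu list of four cluster mean vectors (A, B, C, D).
#' @param sigma isotropic cluster standard deviation.
#' @param n samples per cluster per view.
#' @param mu_s,sigma_s shift-fraction distribution (applied between A and B
#'   in view 2, as in [shift_config()]).
#' @param clamp clamp shift fractions to `[0, 1]`.
#' @return an object of class `four_cluster_config`.
#' @export
four_cluster_config <- function(mu = list(A = c(0, 0), B = c(4, 0),
                                          C = c(0, 4), D = c(4, 4)),
                                sigma = 0.5, n = 100L, mu_s = 0.5,
                                sigma_s = 0.05, clamp = FALSE) {
  stopifnot(length(mu) == 4, sigma > 0, n >= 2, sigma_s > 0)
  d <- length(mu[[1]])
  stopifnot(all(lengths(mu) == d))
  structure(list(mu = mu, sigma = sigma, n = as.integer(n), mu_s = mu_s,
                 sigma_s = sigma_s, dims = d, clamp = clamp),
            class = "four_cluster_config")
}

#' Four-cluster simulation with shift and relation-scrambling confounding
#'
#' One-to-one related views with four Gaussian clusters. Two kinds of
#' confounding are introduced in view 2: half of the cluster-A samples are
#' shifted toward cluster B exactly as in [gen_two_view_shift()], and the
#' C/D relations are scrambled so that half of the view-2 cluster-C samples
#' are related to view-1 cluster-D samples (and symmetrically for D). This
#' is the design on which the naive consensus baseline fails: the two views
#' genuinely disagree about part of the structure.
#'
#' @param config a [four_cluster_config].
#' @param seed integer seed.
#' @param scramble apply the C/D relation scrambling.
#' @param shift apply the A-to-B shift confounding.
#' @return a `bmvc_sim`, as for [gen_two_view_shift()].
#' @export
gen_four_cluster <- function(config = four_cluster_config(), seed = 1L,
                             scramble = TRUE, shift = TRUE) {
  stopifnot(inherits(config, "four_cluster_config"))
  with_seed(seed, {
    n <- config$n
    N <- 4L * n
    lab1 <- rep(1:4, each = n)
    sigmas <- rep(list(config$sigma), 4)
    X1 <- draw_components(lab1, config$mu, sigmas)
    realized2 <- lab1
    if (scramble) {
      iC <- which(lab1 == 3L)
      iD <- which(lab1 == 4L)
      swapC <- sample(iC, floor(n / 2))  # partners of these view-1 C entities come from D
      swapD <- sample(iD, floor(n / 2))
      realized2[swapC] <- 4L
      realized2[swapD] <- 3L
    }
    X2 <- draw_components(realized2, config$mu, sigmas)
    shifted <- integer(0)
    if (shift) {
      scfg <- shift_config(mu_a = config$mu[[1]], mu_b = config$mu[[2]],
                           sigma_a = config$sigma, sigma_b = config$sigma,
                           mu_s = config$mu_s, sigma_s = config$sigma_s,
                           n = n, clamp = config$clamp)
      sh <- shift_half_a(X2, realized2, scfg)
      X2 <- sh$X2
      shifted <- sh$shifted
    }
    rownames(X1) <- sprintf("v1_e%d", seq_len(N))
    rownames(X2) <- sprintf("v2_e%d", seq_len(N))
    data <- mv_dataset(list(view1 = X1, view2 = X2))
    R <- Matrix::sparseMatrix(i = seq_len(N), j = seq_len(N), x = 1,
                              dims = c(N, N))
    relations <- mv_relations(list(relation_block("view1", "view2", R)))
    sim_output(data, relations,
               truth = list(view1 = lab1, view2 = realized2),
               meta = list(design = "four_cluster_confounded", config = config,
                           seed = seed, scramble = scramble, shift = shift,
                           shifted = shifted))
  })
}

#' Pseudo-omics simulation: two dependent views from one matrix
#'
#' Produces two pseudo-simulated views from a single data matrix by adding
#' independent Gaussian noise in each view, duplicating a random fraction of
#' the entities in the second view (simulating many-to-one relationships;
#' duplicates receive fresh entity ids suffixed `_dup` and independent
#' noise), and removing a random fraction of the edges of the resulting
#' identity relationship graph (simulating entities with no known
#' relationships).
#'
#' @param X numeric matrix (entities in rows, with row names).
#' @param noise_scale standard deviation of the added Gaussian noise.
#' @param dup_frac fraction of entities duplicated in view 2, in `[0, 1)`.
#' @param edge_drop_frac fraction of relationship edges removed, in `[0, 1)`.
#' @param seed integer seed.
#' @return a `bmvc_sim`; `truth` is `NULL` (this design has no generating
#'   cluster labels - a reference clustering of the noiseless `X` plays that
#'   role downstream) and `meta$provenance` maps every view-2 row to its
#'   source row of `X`.
#' @export
gen_pseudo_omics <- function(X, noise_scale = 1, dup_frac = 0.25,
                             edge_drop_frac = 0.25, seed = 1L) {
  if (is.data.frame(X)) X <- as.matrix(X)
  stopifnot(is.matrix(X), is.numeric(X))
  if (dup_frac < 0 || dup_frac >= 1 || edge_drop_frac < 0 || edge_drop_frac >= 1)
    stop("`dup_frac` and `edge_drop_frac` must lie in [0, 1)")
  N <- nrow(X)
  ids <- rownames(X) %||% sprintf("e%d", seq_len(N))
  with_seed(seed, {
    X1 <- X + noise_scale * matrix(stats::rnorm(length(X)), N, ncol(X))
    ndup <- floor(dup_frac * N)
    dup_idx <- if (ndup > 0) sort(sample(N, ndup)) else integer(0)
    src <- c(seq_len(N), dup_idx)
    X2 <- X[src, , drop = FALSE] +
      noise_scale * matrix(stats::rnorm(length(src) * ncol(X)), length(src), ncol(X))
    ids2 <- c(ids, if (ndup > 0) paste0(ids[dup_idx], "_dup"))
    rownames(X1) <- ids
    rownames(X2) <- ids2
    edges <- cbind(src, seq_along(src))  # view-2 row -> its source view-1 row
    n_keep <- round((1 - edge_drop_frac) * nrow(edges))
    keep <- sort(sample(nrow(edges), n_keep))
    edges <- edges[keep, , drop = FALSE]
    data <- mv_dataset(list(view1 = X1, view2 = X2))
    R <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1,
                              dims = c(N, length(src)))
    relations <- mv_relations(list(relation_block("view1", "view2", R)))
    sim_output(data, relations, truth = NULL,
               meta = list(design = "pseudo_omics", seed = seed,
                           noise_scale = noise_scale, dup_frac = dup_frac,
                           edge_drop_frac = edge_drop_frac,
                           provenance = stats::setNames(ids[src], ids2)))
  })
}
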