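# Domain containers: multi-view datasets, cross-view relationship graphs,
# cluster-correspondence matchings, and the model hyperpriors.

#' Construct a multi-view dataset
#'
#' A multi-view dataset holds one entities-by-features numeric matrix per
#' view. Row names are used as entity identifiers; when absent they are
#' generated as `<view>_e<i>`. Entity order defines the index order used by
#' relationship matrices.
#'
#' @param views named list of numeric matrices (entities in rows). Unnamed
#'   lists are named `view1`, `view2`, ...
#' @return an object of class `mv_dataset`.
#' @examples
#' d <- mv_dataset(list(expr = matrix(rnorm(20), 10, 2)))
#' view_sizes(d)
#' @export
mv_dataset <- function(views) {
  if (!is.list(views) || length(views) < 1)
    stop("`views` must be a non-empty list of matrices")
  nm <- names(views)
  if (is.null(nm)) nm <- rep("", length(views))
  nm[!nzchar(nm)] <- paste0("view", which(!nzchar(nm)))
  if (anyDuplicated(nm)) stop("view names must be unique")
  out <- vector("list", length(views))
  for (v in seq_along(views)) {
    X <- views[[v]]
    if (is.data.frame(X)) X <- as.matrix(X)
    if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1)
    if (!is.matrix(X) || !is.numeric(X))
      stop(sprintf("view '%s' is not a numeric matrix", nm[v]))
    if (nrow(X) < 1) stop(sprintf("view '%s' has no entities", nm[v]))
    if (any(!is.finite(X)))
      stop(sprintf("view '%s' contains non-finite values", nm[v]))
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("%s_e%d", nm[v], seq_len(nrow(X)))
    if (anyDuplicated(ids))
      stop(sprintf("duplicate entity ids in view '%s'", nm[v]))
    rownames(X) <- ids
    out[[v]] <- list(ids = ids, X = X)
  }
  names(out) <- nm
  structure(list(views = out), class = "mv_dataset")
}

#' @export
print.mv_dataset <- function(x, ...) {
  cat("Multi-view dataset with", length(x$views), "view(s):\n")
  for (nm in names(x$views)) {
    cat(sprintf("  %s: %d entities x %d features\n",
                nm, nrow(x$views[[nm]]$X), ncol(x$views[[nm]]$X)))
  }
  invisible(x)
}

#' @rdname mv_dataset
#' @param data an `mv_dataset`.
#' @export
view_sizes <- function(data) {
  stopifnot(inherits(data, "mv_dataset"))
  vapply(data$views, function(v) nrow(v$X), integer(1))
}

#' @rdname mv_dataset
#' @export
view_names <- function(data) {
  stopifnot(inherits(data, "mv_dataset"))
  names(data$views)
}

#' Cross-view relationship graph
#'
#' Holds, for each pair of views, a sparse non-negative matrix `R` whose
#' entry `[i, j]` is positive when entity `i` of the first view is related to
#' entity `j` of the second. Relationships may be one-to-one, many-to-one,
#' many-to-many, or absent for some entities; continuous positive weights
#' describe known relationship strengths.
#'
#' @param blocks list of blocks built with [relation_block()].
#' @return an object of class `mv_relations`.
#' @seealso [relation_block()]
#' @export
mv_relations <- function(blocks = list()) {
  if (inherits(blocks, "bmvc_relation_block")) blocks <- list(blocks)
  stopifnot(is.list(blocks))
  for (b in blocks) {
    if (!inherits(b, "bmvc_relation_block"))
      stop("all elements must be created by relation_block()")
  }
  structure(list(blocks = blocks), class = "mv_relations")
}

#' @rdname mv_relations
#' @param v,u view names (matching the dataset) of the two related views.
#' @param R matrix (dense or sparse) of non-negative relation weights,
#'   entities of view `v` in rows and of view `u` in columns. Explicit zeros
#'   are dropped.
#' @export
relation_block <- function(v, u, R) {
  stopifnot(is.character(v), is.character(u), length(v) == 1, length(u) == 1)
  if (identical(v, u)) stop("a relation block must link two distinct views")
  R <- Matrix::Matrix(R, sparse = TRUE)
  # force a general (non-symmetric, non-triangular) column-sparse layout so
  # triplet extraction sees every stored edge
  R <- Matrix::drop0(methods::as(methods::as(R, "generalMatrix"), "CsparseMatrix"))
  if (any(R@x < 0)) stop("relationship weights must be non-negative")
  structure(list(v = v, u = u, R = R), class = "bmvc_relation_block")
}

#' @export
print.mv_relations <- function(x, ...) {
  cat("Relationship graph with", length(x$blocks), "view pair(s):\n")
  for (b in x$blocks) {
    cat(sprintf("  %s -- %s: %d edge(s) (%d x %d)\n", b$v, b$u,
                length(b$R@x), nrow(b$R), ncol(b$R)))
  }
  invisible(x)
}

# Compile an mv_relations object against a dataset (or view sizes) into the
# canonical internal form: one record per unordered view pair with v < u in
# dataset order, edges stored as triplets. Blocks for the same pair are
# summed. Returns a list of pair records sorted by (v, u).
compile_relations <- function(relations, N, vnames, ids = NULL) {
  if (is.null(relations)) relations <- mv_relations()
  stopifnot(inherits(relations, "mv_relations"))
  acc <- list()
  for (b in relations$blocks) {
    vi <- match(b$v, vnames)
    ui <- match(b$u, vnames)
    if (is.na(vi) || is.na(ui))
      stop(sprintf("relation block references unknown view '%s'",
                   if (is.na(vi)) b$v else b$u))
    R <- b$R
    if (vi > ui) {
      tmp <- vi; vi <- ui; ui <- tmp
      R <- Matrix::t(R)
    }
    if (nrow(R) != N[vi] || ncol(R) != N[ui])
      stop(sprintf("relation block %s--%s has dimensions %d x %d; expected %d x %d",
                   vnames[vi], vnames[ui], nrow(R), ncol(R), N[vi], N[ui]))
    if (!is.null(ids)) {
      dn <- dimnames(R)
      if (!is.null(dn[[1]]) && !identical(dn[[1]], ids[[vi]]))
        stop("relation block row names do not match the entity order of view ",
             vnames[vi])
      if (!is.null(dn[[2]]) && !identical(dn[[2]], ids[[ui]]))
        stop("relation block column names do not match the entity order of view ",
             vnames[ui])
    }
    key <- paste0(vi, ":", ui)
    acc[[key]] <- if (is.null(acc[[key]])) R else acc[[key]] + R
  }
  if (length(acc) == 0) return(stats::setNames(list(), character(0)))
  keys <- names(acc)
  ord <- order(vapply(strsplit(keys, ":"), function(s) as.integer(s[1]), integer(1)) * 1e6 +
               vapply(strsplit(keys, ":"), function(s) as.integer(s[2]), integer(1)))
  pairs <- lapply(keys[ord], function(key) {
    idx <- as.integer(strsplit(key, ":")[[1]])
    R <- Matrix::drop0(acc[[key]])
    tr <- Matrix::mat2triplet(R)
    list(v = idx[1], u = idx[2],
         name = paste0(vnames[idx[1]], ":", vnames[idx[2]]),
         ti = as.integer(tr$i), tj = as.integer(tr$j), tw = as.numeric(tr$x),
         Nv = N[idx[1]], Nu = N[idx[2]])
  })
  names(pairs) <- vapply(pairs, `[[`, character(1), "name")
  pairs
}

total_edges <- function(pairs) sum(vapply(pairs, function(p) length(p$ti), integer(1)))

# Identity correspondence matchings for a set of compiled pairs; requires the
# coupled views to share a cluster count so that C is a permutation matrix.
# A pair without stored edges needs no matching.
default_matching <- function(pairs, K) {
  out <- lapply(pairs, function(p) {
    if (length(p$ti) == 0) return(seq_len(min(K[p$v], K[p$u])))
    if (K[p$v] != K[p$u])
      stop(sprintf(paste0("views %d and %d are coupled through relations but have ",
                          "different cluster counts (%d vs %d); a correspondence ",
                          "matching requires equal K"),
                   p$v, p$u, K[p$v], K[p$u]))
    seq_len(K[p$v])
  })
  names(out) <- names(pairs)
  out
}

check_matching <- function(C, pairs, K) {
  if (is.null(C)) return(default_matching(pairs, K))
  if (length(C) != length(pairs))
    stop("need one correspondence matching per coupled view pair")
  if (!is.null(names(C)) && !is.null(names(pairs)) &&
      all(names(pairs) %in% names(C))) {
    C <- C[names(pairs)]
  }
  for (p in seq_along(pairs)) {
    if (length(pairs[[p]]$ti) == 0) next
    m <- as.integer(C[[p]])
    Kv <- K[pairs[[p]]$v]; Ku <- K[pairs[[p]]$u]
    if (Kv != Ku)
      stop("coupled view pairs must have equal cluster counts")
    if (length(m) != Kv || !setequal(m, seq_len(Ku)))
      stop(sprintf("matching for pair %s is not a permutation of 1..%d",
                   names(pairs)[p] %||% p, Ku))
    C[[p]] <- m
  }
  names(C) <- names(pairs)
  C
}

#' Convert a correspondence matching to its indicator matrix
#'
#' @param m integer vector; `m[k]` is the cluster of the second view matched
#'   to cluster `k` of the first.
#' @return a binary matrix with exactly one indicator per row and column.
#' @export
matching_matrix <- function(m) {
  K <- length(m)
  M <- matrix(0L, K, K)
  M[cbind(seq_len(K), m)] <- 1L
  M
}

#' Hyperpriors for the coupled mixture model
#'
#' @param alpha Dirichlet concentration for the mixture weights (scalar or
#'   per-cluster; must be >= 1 so the MAP stays well defined on the simplex
#'   boundary). `alpha = 1` is flat.
#' @param phi_prior prior family for the coupling strengths:
#'   `"halfnormal"` (default; a weakly-informative guard appropriate for a
#'   parameter whose effect on the assignment odds saturates),
#'   `"lognormal"`, or `"flat"` (improper, constant on the non-negative
#'   reals).
#' @param phi_scale half-normal scale.
#' @param phi_meanlog,phi_sdlog log-normal location and scale (mode
#'   `exp(phi_meanlog - phi_sdlog^2)`).
#' @return an object of class `bmvc_priors`.
#' @export
bmvc_priors <- function(alpha = 1, phi_prior = c("halfnormal", "lognormal", "flat"),
                        phi_scale = 5, phi_meanlog = 0, phi_sdlog = 1) {
  phi_prior <- match.arg(phi_prior)
  stopifnot(all(alpha >= 1), phi_scale > 0, phi_sdlog > 0)
  structure(list(alpha = alpha, phi_prior = phi_prior, phi_scale = phi_scale,
                 phi_meanlog = phi_meanlog, phi_sdlog = phi_sdlog),
            class = "bmvc_priors")
}

# Priors are evaluated on the phi >= 0 domain; log-normal entries frozen at
# the phi = 0 boundary contribute nothing.
phi_log_prior <- function(phi, priors) {
  switch(priors$phi_prior,
    flat = 0,
    halfnormal = sum(log(2) + stats::dnorm(phi, 0, priors$phi_scale, log = TRUE)),
    lognormal = {
      pos <- phi > 0
      if (!any(pos)) 0
      else sum(stats::dlnorm(phi[pos], priors$phi_meanlog, priors$phi_sdlog,
                             log = TRUE))
    })
}

phi_log_prior_grad <- function(phi, priors) {
  switch(priors$phi_prior,
    flat = rep(0, length(phi)),
    halfnormal = -phi / priors$phi_scale^2,
    lognormal = (-1 - (log(phi) - priors$phi_meanlog) / priors$phi_sdlog^2) / phi)
}

phi_prior_mode <- function(priors) {
  switch(priors$phi_prior,
    flat = 0.5,
    halfnormal = 0,
    lognormal = exp(priors$phi_meanlog - priors$phi_sdlog^2))
}

# Validate an assignment state against view sizes and cluster counts.
check_assignments <- function(z, N, K) {
  if (length(z) != length(N)) stop("assignment state has the wrong number of views")
  for (v in seq_along(z)) {
    zv <- z[[v]]
    if (length(zv) != N[v])
      stop(sprintf("view %d: %d assignments for %d entities", v, length(zv), N[v]))
    if (any(zv < 1L | zv > K[v]) || any(zv != as.integer(zv)))
      stop(sprintf("view %d: cluster labels must be integers in 1..%d", v, K[v]))
  }
  lapply(z, as.integer)
}
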