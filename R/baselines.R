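# Comparison methods: independent hard-assignment Gaussian mixtures (H-GMM)
# per view, and the naive consensus clustering obtained by concatenating two
# one-to-one related views and fitting a single mixture (M-GMM).

#' Independent hard-assignment Gaussian mixture (H-GMM)
#'
#' Hard-EM Gaussian mixture on a single view; by construction identical to
#' [fit_bmvc()] with every coupling strength frozen at zero, which is the
#' baseline the coupled model reduces to.
#'
#' @param X numeric matrix (entities in rows) or a one-view [mv_dataset].
#' @param K number of clusters.
#' @param init `"kmeans"` or `"random"` initialization.
#' @param seed integer seed.
#' @param restarts number of restarts.
#' @param max_iter,tol EM iteration cap and relative tolerance.
#' @param init_labels optional integer label vector used as the initial
#'   assignment of every restart.
#' @param priors a [bmvc_priors] object (only the Dirichlet part is used).
#' @return a list with `labels`, `pi`, `theta`, `objective`, `trace`,
#'   `degenerate` flag, and the underlying `bmvc_fit` as `fit`.
#' @export
hgmm_fit <- function(X, K, init = c("kmeans", "random"), seed = 1L,
                     restarts = 1L, max_iter = 50L, tol = 1e-8,
                     init_labels = NULL, priors = bmvc_priors()) {
  init <- match.arg(init)
  data <- if (inherits(X, "mv_dataset")) {
    if (length(X$views) != 1) stop("hgmm_fit clusters a single view")
    X
  } else {
    mv_dataset(list(view1 = X))
  }
  cfg <- bmvc_config(K = K, mode = "pseudo", max_iter = max_iter, tol = tol,
                     restarts = restarts, init = init, seed = seed,
                     phi_fixed_zero = TRUE, priors = priors,
                     init_labels = if (!is.null(init_labels)) list(init_labels))
  fit <- fit_bmvc(data, mv_relations(), cfg)
  list(labels = fit$state$z[[1]], pi = fit$state$pi[[1]],
       theta = fit$state$theta[[1]], objective = fit$objective,
       trace = fit$trace, degenerate = fit$degenerate, fit = fit)
}

#' Naive consensus clustering of two one-to-one related views (M-GMM)
#'
#' Concatenates the features of two views along the entity dimension,
#' following the complete one-to-one correspondence encoded by `relations`,
#' fits one hard-EM Gaussian mixture to the concatenated matrix, and applies
#' the single resulting labeling to both views. The baseline is undefined
#' for any other relationship structure and such input is rejected.
#'
#' @param data a two-view [mv_dataset].
#' @param relations an [mv_relations] encoding a complete one-to-one
#'   correspondence between the views.
#' @param K number of clusters.
#' @inheritParams hgmm_fit
#' @return a list with `labels` (per-view list; the shared labeling indexed
#'   in each view's entity order), `objective`, and the underlying consensus
#'   `hgmm` result.
#' @export
consensus_fit <- function(data, relations, K, init = c("kmeans", "random"),
                          seed = 1L, restarts = 1L, max_iter = 50L, tol = 1e-8,
                          priors = bmvc_priors()) {
  init <- match.arg(init)
  stopifnot(inherits(data, "mv_dataset"))
  if (length(data$views) != 2)
    stop("the consensus baseline is defined for exactly two views")
  N <- view_sizes(data)
  pairs <- compile_relations(relations, N, view_names(data),
                             lapply(data$views, `[[`, "ids"))
  if (length(pairs) != 1)
    stop("the consensus baseline needs relations between the two views")
  pr <- pairs[[1]]
  deg_v <- tabulate(pr$ti, pr$Nv)
  deg_u <- tabulate(pr$tj, pr$Nu)
  if (pr$Nv != pr$Nu || any(deg_v != 1L) || any(deg_u != 1L))
    stop("the consensus baseline requires a complete one-to-one ",
         "correspondence between the views; the supplied relationships are not")
  partner <- integer(pr$Nv)
  partner[pr$ti] <- pr$tj  # view-1 entity i is paired with view-2 entity partner[i]
  Xc <- cbind(data$views[[1]]$X, data$views[[2]]$X[partner, , drop = FALSE])
  rownames(Xc) <- data$views[[1]]$ids
  hg <- hgmm_fit(Xc, K, init = init, seed = seed, restarts = restarts,
                 max_iter = max_iter, tol = tol, priors = priors)
  lab2 <- integer(pr$Nu)
  lab2[partner] <- hg$labels
  list(labels = stats::setNames(list(hg$labels, lab2), view_names(data)),
       objective = hg$objective, consensus = hg)
}
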