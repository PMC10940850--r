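# Evaluation statistics and experiment harnesses: adjusted Rand index,
# structural affinity of a clustering pair with respect to the relationship
# graph, the convergence-rate experiment (random vs k-means++ initialization)
# and the coupling-strength recovery experiment.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same entities.
#' Degenerate cases where the expected index equals the maximum index (e.g.
#' one labeling puts everything in a single cluster) return 1 for identical
#' partitions and 0 otherwise.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return a single numeric value (1 for identical partitions).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  out <- suppressWarnings(mclust::adjustedRandIndex(labels_a, labels_b))
  if (!is.finite(out)) {
    same <- identical(as.integer(factor(labels_a)), as.integer(factor(labels_b)))
    out <- if (same) 1 else 0
  }
  out
}

#' Mean adjusted Rand index of a fit against ground truth
#'
#' @param fit a `bmvc_fit`, or a list of per-view label vectors.
#' @param truth list of per-view ground-truth label vectors; views with
#'   `NULL` truth are skipped only when listed in `exclude` (e.g. a
#'   duplicated pseudo-omics view, where truth is undefined).
#' @param exclude character or integer vector of views to exclude.
#' @return unweighted mean of the per-view ARIs.
#' @export
mean_ari <- function(fit, truth, exclude = NULL) {
  labels <- if (inherits(fit, "bmvc_fit")) fit$state$z else fit
  if (!is.null(exclude)) {
    keep <- if (is.character(exclude)) !(names(labels) %in% exclude)
            else !(seq_along(labels) %in% exclude)
    labels <- labels[keep]
    truth <- truth[keep]
  }
  for (v in seq_along(labels)) {
    if (is.null(truth[[v]]))
      stop("missing ground truth for a view that was not excluded")
  }
  mean(vapply(seq_along(labels), function(v)
    adjusted_rand_index(labels[[v]], truth[[v]]), numeric(1)))
}

affinity_components <- function(z_v, z_u, R, K_v = max(z_v), K_u = max(z_u)) {
  R <- Matrix::drop0(methods::as(methods::as(Matrix::Matrix(R, sparse = TRUE),
                                             "generalMatrix"), "CsparseMatrix"))
  tr <- Matrix::mat2triplet(R)
  J <- matrix(0, K_v, K_u)
  if (length(tr$i)) {
    lin <- (z_u[tr$j] - 1L) * K_v + z_v[tr$i]
    s <- rowsum(tr$x, lin)
    J[as.integer(rownames(s))] <- s
  }
  J
}

#' Structural affinity of a cross-view cluster pair
#'
#' For clusters `k` (view v) and `l` (view u): the average of the two
#' directed proportions of related entity pairs falling into the partner
#' cluster - the weight of relations leaving cluster `k` that land in `l`,
#' and of relations leaving `l` that land in `k`. Measures how strongly a
#' clustering pair adheres to the structure encoded by the relationship
#' matrix. Continuous relation weights enter both numerator and denominator.
#'
#' @param z_v,z_u cluster labels of the two views.
#' @param R relationship matrix (entities of view v in rows).
#' @param k,l cluster indices in views v and u.
#' @return a value in `[0, 1]`, or `NA` when neither cluster has any related
#'   entity (the statistic is undefined there, not zero).
#' @export
structural_affinity <- function(z_v, z_u, R, k, l) {
  J <- affinity_components(z_v, z_u, R)
  row_tot <- sum(J[k, ])
  col_tot <- sum(J[, l])
  if (row_tot == 0 && col_tot == 0) return(NA_real_)
  p1 <- if (row_tot > 0) J[k, l] / row_tot else NA_real_
  p2 <- if (col_tot > 0) J[k, l] / col_tot else NA_real_
  mean(c(p1, p2), na.rm = TRUE)
}

#' Structural affinity map of a view pair
#'
#' The full matrix of [structural_affinity()] scores for every cross-view
#' cluster pair, together with the mask of matched pairs from a
#' correspondence matching (the starred cells of an affinity heat map).
#'
#' @inheritParams structural_affinity
#' @param K_v,K_u cluster counts (default: maximum observed label).
#' @param matching optional correspondence matching (integer vector,
#'   `matching[k]` = view-u cluster matched to view-v cluster `k`).
#' @return a list with `scores` (`K_v` x `K_u` matrix, `NA` where undefined)
#'   and `matched` (logical mask, or `NULL` when no matching is supplied).
#' @export
affinity_map <- function(z_v, z_u, R, K_v = max(z_v), K_u = max(z_u),
                         matching = NULL) {
  J <- affinity_components(z_v, z_u, R, K_v, K_u)
  row_tot <- rowSums(J)
  col_tot <- colSums(J)
  P1 <- J / ifelse(row_tot > 0, row_tot, NA)[row(J)]
  P2 <- J / ifelse(col_tot > 0, col_tot, NA)[col(J)]
  scores <- matrix(rowMeans(cbind(as.vector(P1), as.vector(P2)), na.rm = TRUE),
                   K_v, K_u)
  scores[is.nan(scores)] <- NA_real_
  matched <- NULL
  if (!is.null(matching)) {
    matched <- matrix(FALSE, K_v, K_u)
    matched[cbind(seq_len(K_v), matching)] <- TRUE
  }
  list(scores = scores, matched = matched)
}

#' Convergence-rate experiment on the four-cluster simulation
#'
#' For each shift value, data is generated once from a shift-specific seed;
#' the clustering is then run `trials_per_shift` times per initialization
#' mode. A run "attains the best objective" when its final objective lies
#' within a relative tolerance of the per-shift best over all runs (pooled
#' across modes by default). Reports the attainment fraction per mode and
#' shift, and pooled over shifts.
#'
#' @param shifts numeric vector of shift-fraction means.
#' @param trials_per_shift runs per shift and mode.
#' @param init_modes subset of `c("kmeans", "random")`.
#' @param seed master seed; per-shift data seeds and per-run seeds derive
#'   from it.
#' @param method `"bmvc"` (the coupled model) or `"hgmm"` (independent
#'   per-view hard-EM mixtures, whose objective is the sum over views).
#' @param sim_config a [four_cluster_config].
#' @param K clusters per view.
#' @param fit_config optional named list of [bmvc_config()] overrides for
#'   the BMVC runs.
#' @param pool_modes compute the per-shift best over all modes jointly
#'   (otherwise within each mode).
#' @param tol_rel relative objective tolerance defining attainment.
#' @return a list with `runs` (one row per run), `fractions` (per mode and
#'   shift) and `pooled` (named fraction per mode, in `[0, 1]`).
#' @export
convergence_experiment <- function(shifts, trials_per_shift = 10L,
                                   init_modes = c("kmeans", "random"),
                                   seed = 1L, method = c("bmvc", "hgmm"),
                                   sim_config = four_cluster_config(),
                                   K = 4L, fit_config = NULL,
                                   pool_modes = TRUE, tol_rel = 1e-4) {
  method <- match.arg(method)
  init_modes <- match.arg(init_modes, c("kmeans", "random"), several.ok = TRUE)
  rows <- list()
  for (si in seq_along(shifts)) {
    data_seed <- derive_seed(seed, 1000L + si)
    cfg <- sim_config
    cfg$mu_s <- shifts[si]
    sim <- gen_four_cluster(cfg, seed = data_seed)
    for (mi in seq_along(init_modes)) {
      mode <- init_modes[mi]
      for (t in seq_len(trials_per_shift)) {
        run_seed <- derive_seed(seed, si, mi, t)
        if (method == "bmvc") {
          args <- list(K = K, init = mode, seed = run_seed, restarts = 1L,
                       mode = "auto")
          if (!is.null(fit_config)) args[names(fit_config)] <- fit_config
          fit <- fit_bmvc(sim$data, sim$relations, do.call(bmvc_config, args))
          rows[[length(rows) + 1L]] <- data.frame(
            shift = shifts[si], mode = mode, trial = t, seed = run_seed,
            view = NA_integer_, objective = fit$objective)
        } else {
          # one baseline run fits the phi = 0 model to every view; its
          # objective is the sum of the per-view mixture objectives
          obj <- sum(vapply(seq_along(sim$data$views), function(v)
            hgmm_fit(sim$data$views[[v]]$X, K, init = mode,
                     seed = derive_seed(run_seed, v))$objective, numeric(1)))
          rows[[length(rows) + 1L]] <- data.frame(
            shift = shifts[si], mode = mode, trial = t, seed = run_seed,
            view = NA_integer_, objective = obj)
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  runs$hit <- NA
  views <- unique(runs$view)
  for (si in seq_along(shifts)) {
    for (vv in views) {
      sel_sv <- runs$shift == shifts[si] &
        (if (is.na(vv)) is.na(runs$view) else !is.na(runs$view) & runs$view == vv)
      for (mode in init_modes) {
        sel <- sel_sv & (if (pool_modes) TRUE else runs$mode == mode)
        best <- max(runs$objective[sel])
        here <- sel_sv & runs$mode == mode
        runs$hit[here] <- runs$objective[here] >= best - tol_rel * abs(best)
      }
    }
  }
  fractions <- stats::aggregate(hit ~ mode + shift, data = runs, FUN = mean)
  pooled <- vapply(init_modes, function(m) mean(runs$hit[runs$mode == m]),
                   numeric(1))
  list(runs = runs, fractions = fractions, pooled = pooled)
}

#' Coupling-strength recovery over a grid of dependence levels
#'
#' Generates two-view shift simulations whose inter-view dependence is
#' degraded by binomial randomization at probability `p`, fits the coupled
#' model, and records the fitted coupling strength. The dependence-decreasing
#' randomization variant is used so that `p = 0` means complete dependence
#' and `p = 0.5` none; the fitted strength should then decrease in `p`.
#'
#' @param p_grid randomization probabilities in `[0, 0.5]`.
#' @param shift_grid shift-fraction means.
#' @param topology relationship topology, see [gen_two_view_shift()].
#' @param seeds integer vector of replicate seeds.
#' @param config a [shift_config] (its `mu_s` is overridden by `shift_grid`).
#' @param fit_config optional named list of [bmvc_config()] overrides.
#' @return a list with `results` (one row per `(p, shift, seed)`, with the
#'   fitted `phi`) and `medians` (median `phi` per `(p, shift)`).
#' @export
phi_recovery_experiment <- function(p_grid = seq(0, 0.5, by = 0.1),
                                    shift_grid = 0.3,
                                    topology = "complete_one_to_one",
                                    seeds = 1:3, config = shift_config(),
                                    fit_config = NULL) {
  rows <- list()
  for (p in p_grid) {
    for (s in shift_grid) {
      cfg <- config
      cfg$mu_s <- s
      for (sd in seeds) {
        sim <- gen_two_view_shift(cfg, topology, seed = derive_seed(sd, round(100 * p), round(100 * s)),
                                  p = p, complement = TRUE)
        args <- list(K = 2L, init = "kmeans", seed = sd, restarts = 1L,
                     mode = "pseudo")
        if (!is.null(fit_config)) args[names(fit_config)] <- fit_config
        fit <- fit_bmvc(sim$data, sim$relations, do.call(bmvc_config, args))
        rows[[length(rows) + 1L]] <- data.frame(p = p, shift = s, seed = sd,
                                                phi = unname(fit$state$phi[1]),
                                                objective = fit$objective)
      }
    }
  }
  results <- do.call(rbind, rows)
  medians <- stats::aggregate(phi ~ p + shift, data = results, FUN = stats::median)
  list(results = results, medians = medians)
}
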