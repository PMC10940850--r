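# The hard-EM engine: initialization, E-step, M sub-steps and the full fit.

test_that("kmeans_init is deterministic and recovers separated blobs", {
  blobs <- make_blobs(20, list(c(0, 0), c(10, 10)), sd = 1, seed = 3)
  l1 <- kmeans_init(blobs$X, 2, seed = 11)
  l2 <- kmeans_init(blobs$X, 2, seed = 11)
  expect_identical(l1, l2)
  expect_equal(adjusted_rand_index(l1, blobs$labels), 1)
  # K = N: every entity its own cluster
  small <- blobs$X[1:5, ]
  expect_equal(adjusted_rand_index(kmeans_init(small, 5, seed = 1), 1:5), 1)
  expect_error(kmeans_init(small, 6, seed = 1), "exceeds")
})

test_that("E-step decouples at phi = 0 and fixes coordinate-wise optima", {
  blobs <- make_blobs(10, list(c(0, 0), c(8, 8)), seed = 5)
  X2 <- blobs$X + 0.05
  rownames(X2) <- paste0("b", 1:20)
  data <- mv_dataset(list(v1 = blobs$X, v2 = X2))
  rel <- mv_relations(list(relation_block("v1", "v2", diag(20))))
  cfg <- bmvc_config(K = 2, phi_fixed_zero = TRUE, restarts = 1, seed = 2)
  ctx <- bmvc:::build_ctx(data, rel, cfg)
  st <- bmvc:::with_seed(1, bmvc:::init_state(ctx, 42))
  st1 <- bmvc:::e_step(ctx, st)
  # phi = 0: each entity gets argmax of log pi + component log-density
  for (v in 1:2) {
    S <- st$loglik[[v]] + matrix(log(st$pi[[v]]), 20, 2, byrow = TRUE)
    expect_identical(st1$z[[v]], max.col(S, ties.method = "first"))
  }
  # a coordinate-wise optimum is returned unchanged
  st2 <- bmvc:::e_step(ctx, st1)
  expect_identical(st2$z, st1$z)
})

test_that("E-step ascends and stays below the enumerated optimum on tiny instances", {
  for (s in 1:5) {
    inst <- random_instance(7000 + s, V = 2, K = 2)
    set.seed(s)
    X <- lapply(inst$N, function(n) {
      m <- matrix(rnorm(n * 2, sd = 1), n, 2)
      rownames(m) <- paste0("x", seq_len(n), "_", sample(1e6, 1))
      m
    })
    data <- mv_dataset(setNames(X, names(inst$z)))
    il <- lapply(inst$N, function(n) sample.int(2, n, replace = TRUE))
    cfg <- bmvc_config(K = 2, mode = "exact", restarts = 1, seed = s,
                       priors = bmvc_priors(phi_prior = "flat"),
                       init_labels = il)
    ctx <- bmvc:::build_ctx(data, inst$relations, cfg)
    st <- bmvc:::with_seed(s, bmvc:::init_state(ctx, 100 + s))
    st$phi <- rep(1.3, length(ctx$pairs))
    obj0 <- bmvc:::objective_full(ctx, st)
    st1 <- bmvc:::e_step(ctx, st)
    obj1 <- bmvc:::objective_full(ctx, st1)
    expect_gte(obj1, obj0 - 1e-10)
    # exhaustive maximum over all joint assignments with the same
    # parameters bounds the E-step result
    slot_view <- rep.int(1:2, inst$N)
    grid <- do.call(expand.grid, lapply(slot_view, function(v) 1:2))
    best <- max(apply(grid, 1, function(row) {
      zz <- split(as.integer(row), slot_view)
      st2 <- st
      st2$z <- zz
      bmvc:::objective_full(ctx, st2)
    }))
    expect_lte(obj1, best + 1e-9)
  }
})

test_that("component MLE uses sample mean, 1/n covariance and the floor", {
  g <- gaussian_base()
  th <- g$mle(matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE), eps = 1e-8)
  expect_equal(th$mean, c(1, 1))
  # biased (divide by n) convention in 1-D: points {0, 2} give variance 1
  th1 <- g$mle(matrix(c(0, 2), 2, 1), eps = 1e-8)
  expect_equal(th1$cov[1, 1], 1)
  # singleton: mean at the point, floor covariance
  th2 <- g$mle(matrix(c(3, -1), 1, 2), eps = 1e-4)
  expect_equal(th2$mean, c(3, -1))
  expect_equal(th2$cov, diag(1e-4, 2))
})

test_that("correspondence search recovers the generating permutation", {
  # identical 3-cluster labelings in both views under identity relations
  lab <- rep(1:3, each = 8)
  blobs <- make_blobs(8, list(c(0, 0), c(6, 0), c(0, 6)), seed = 9)
  X2 <- blobs$X + 0.05
  rownames(X2) <- paste0("b", seq_len(nrow(X2)))
  data <- mv_dataset(list(v1 = blobs$X, v2 = X2))
  rel <- mv_relations(list(relation_block("v1", "v2", diag(24))))
  cfg <- bmvc_config(K = 3, restarts = 1, seed = 1, mode = "pseudo")
  ctx <- bmvc:::build_ctx(data, rel, cfg)
  st <- bmvc:::with_seed(1, bmvc:::init_state(ctx, 5))
  st$z <- list(lab, lab)
  st$pi <- list(rep(1 / 3, 3), rep(1 / 3, 3))
  st$phi <- 1.5
  st$C <- list(c(2L, 3L, 1L))  # start from a scrambled matching
  out <- bmvc:::m_corr(ctx, st)
  expect_identical(out$C[[1]], 1:3)
  # view-2 labels a fixed permutation of view-1 labels: the search attains
  # the brute-force maximum over all 6 permutations
  sigma <- c(3L, 1L, 2L)
  st$z <- list(lab, sigma[lab])
  out2 <- bmvc:::m_corr(ctx, st)
  perms <- bmvc:::all_permutations(3)
  vals <- apply(perms, 1, function(m) {
    st2 <- st
    st2$C[[1]] <- as.integer(m)
    bmvc:::prior_objective(ctx, st2)
  })
  got <- bmvc:::prior_objective(ctx, out2)
  expect_equal(got, max(vals), tolerance = 1e-10)
  expect_identical(out2$C[[1]], sigma)
  # flat objective in C at phi = 0: matching unchanged
  st$phi <- 0
  st$C <- list(c(2L, 3L, 1L))
  expect_identical(bmvc:::m_corr(ctx, st)$C[[1]], c(2L, 3L, 1L))
})

test_that("weight/coupling update returns valid parameters and occupancies", {
  blobs <- make_blobs(15, list(c(0, 0), c(8, 8)), seed = 4)
  data <- mv_dataset(list(v1 = blobs$X))
  cfg <- bmvc_config(K = 2, restarts = 1, seed = 1)
  ctx <- bmvc:::build_ctx(data, mv_relations(), cfg)
  st <- bmvc:::with_seed(1, bmvc:::init_state(ctx, 3))
  st$z <- list(blobs$labels)
  out <- bmvc:::m_weights(ctx, st)
  # no relations: pi at the cluster occupancy proportions
  expect_equal(out$pi[[1]], c(0.5, 0.5))
  expect_equal(sum(out$pi[[1]]), 1, tolerance = 1e-10)
  expect_true(all(out$phi >= 0))
})

test_that("analytic gradients match numeric differences in both engines", {
  sim <- gen_four_cluster(four_cluster_config(n = 15), seed = 8)
  num_grad <- function(fn, par, h = 1e-6) {
    vapply(seq_along(par), function(j) {
      pp <- par; pm <- par
      pp[j] <- pp[j] + h
      pm[j] <- pm[j] - h
      (fn(pp) - fn(pm)) / (2 * h)
    }, numeric(1))
  }
  par <- c(rnorm(8, sd = 0.4), 0.3)
  # pseudolikelihood engine
  ctxp <- bmvc:::build_ctx(sim$data, sim$relations, bmvc_config(K = 4, mode = "pseudo"))
  st <- bmvc:::with_seed(2, bmvc:::init_state(ctxp, 9))
  cnt <- bmvc:::precompute_coupling_counts(ctxp, st$z, st$C)
  g <- bmvc:::weights_fg_grouped(par, ctxp, st$z, cnt, TRUE)$grad
  gn <- num_grad(function(p) bmvc:::weights_fg_grouped(p, ctxp, st$z, cnt, FALSE)$obj, par)
  expect_equal(g, gn, tolerance = 1e-5)
  # per-edge fallback agrees with the grouped engine
  g2 <- bmvc:::weights_obj_grad(par, ctxp, st$z, st$C, TRUE)
  expect_equal(g2$grad, g, tolerance = 1e-9)
  # exact edge-decomposable engine
  ctxe <- bmvc:::build_ctx(sim$data, sim$relations, bmvc_config(K = 4, mode = "exact"))
  pre <- bmvc:::precompute_exact_edge_stats(ctxe, st$z, st$C)
  ge <- bmvc:::weights_fg_exact_edges(par, ctxe, pre, TRUE)$grad
  gne <- num_grad(function(p) bmvc:::weights_fg_exact_edges(p, ctxe, pre, FALSE)$obj, par)
  expect_equal(ge, gne, tolerance = 1e-5)
})

test_that("aligned labels earn a larger fitted coupling than shuffled labels", {
  sim <- gen_two_view_shift(shift_config(mu_s = 0.2, n = 60),
                            "complete_one_to_one", seed = 21)
  f_aligned <- fit_bmvc(sim$data, sim$relations,
                        bmvc_config(K = 2, restarts = 1, seed = 1))
  # destroy the correspondence by shuffling view-2 rows
  set.seed(99)
  perm <- sample(nrow(sim$data$views[[2]]$X))
  X2 <- sim$data$views[[2]]$X[perm, ]
  rownames(X2) <- sim$data$views[[2]]$ids
  data_shuf <- mv_dataset(list(view1 = sim$data$views[[1]]$X, view2 = X2))
  f_shuf <- fit_bmvc(data_shuf, sim$relations,
                     bmvc_config(K = 2, restarts = 1, seed = 1))
  expect_gt(f_aligned$state$phi[1], f_shuf$state$phi[1])
})

test_that("fit is reproducible and reports the best restart", {
  sim <- gen_two_view_shift(shift_config(n = 30), "complete_one_to_one", seed = 2)
  cfg <- bmvc_config(K = 2, restarts = 3, seed = 7)
  f1 <- fit_bmvc(sim$data, sim$relations, cfg)
  f2 <- fit_bmvc(sim$data, sim$relations, cfg)
  expect_identical(f1$state, f2$state)
  expect_identical(f1$trace, f2$trace)
  expect_equal(f1$objective, max(f1$restarts$objective))
})

test_that("freezing phi at zero reproduces per-view independent mixtures", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:40, 1)
    K <- sample(2:3, 1)
    ctrs <- lapply(seq_len(K), function(k) rnorm(2, sd = 4))
    b1 <- make_blobs(n, ctrs, sd = 0.8, seed = s)
    b2 <- make_blobs(n, ctrs, sd = 0.8, seed = s + 500)
    rownames(b2$X) <- paste0("w", seq_len(nrow(b2$X)))
    data <- mv_dataset(list(v1 = b1$X, v2 = b2$X))
    rel <- mv_relations(list(relation_block("v1", "v2", diag(nrow(b1$X)))))
    il <- list(kmeans_init(b1$X, K, seed = s),
               kmeans_init(b2$X, K, seed = s + 1))
    f <- fit_bmvc(data, rel, bmvc_config(K = K, restarts = 1, seed = s,
                                         phi_fixed_zero = TRUE,
                                         init_labels = il))
    h1 <- hgmm_fit(b1$X, K, seed = s, init_labels = il[[1]])
    h2 <- hgmm_fit(b2$X, K, seed = s, init_labels = il[[2]])
    expect_identical(f$state$z[[1]], h1$labels)
    expect_identical(f$state$z[[2]], h2$labels)
  }
})

test_that("two coupled copies of one dataset agree across views through C", {
  blobs <- make_blobs(25, list(c(0, 0), c(7, 7)), seed = 12)
  X2 <- blobs$X
  rownames(X2) <- paste0("c", seq_len(nrow(X2)))
  data <- mv_dataset(list(v1 = blobs$X, v2 = X2))
  rel <- mv_relations(list(relation_block("v1", "v2", diag(50))))
  f <- fit_bmvc(data, rel, bmvc_config(K = 2, restarts = 2, seed = 3))
  m <- f$state$C[[1]]
  expect_equal(adjusted_rand_index(m[f$state$z[[1]]], f$state$z[[2]]), 1)
  expect_identical(m[f$state$z[[1]]], f$state$z[[2]])
})

test_that("objective trace is non-decreasing within a restart", {
  sim <- gen_two_view_shift(shift_config(n = 40), "complete_one_to_one", seed = 6)
  f <- fit_bmvc(sim$data, sim$relations, bmvc_config(K = 2, restarts = 2, seed = 9))
  for (tr in f$all_traces) {
    expect_true(all(diff(tr) > -1e-6 * (abs(tr[-length(tr)]) + 1)))
  }
})

test_that("BBVI mode returns valid parameters and a usable fit", {
  sim <- gen_two_view_shift(shift_config(n = 30), "complete_one_to_one", seed = 13)
  f <- fit_bmvc(sim$data, sim$relations,
                bmvc_config(K = 2, restarts = 1, seed = 2, optimizer = "bbvi",
                            opt_steps = 60, max_iter = 15))
  expect_true(all(f$state$phi >= 0))
  expect_equal(sum(f$state$pi[[1]]), 1, tolerance = 1e-10)
  expect_gt(mean_ari(f, sim$truth), 0.8)
})

test_that("small coupled instances end at a coordinate-wise local optimum", {
  for (s in 1:4) {
    inst <- random_instance(8000 + s, V = 2, K = 2)
    set.seed(s + 60)
    X <- lapply(seq_along(inst$N), function(v) {
      m <- matrix(rnorm(inst$N[v] * 2, mean = 2 * (v - 1)), inst$N[v], 2)
      rownames(m) <- paste0("v", v, "_", seq_len(inst$N[v]))
      m
    })
    data <- mv_dataset(setNames(X, names(inst$z)))
    il <- lapply(inst$N, function(n) sample.int(2, n, replace = TRUE))
    f <- fit_bmvc(data, inst$relations,
                  bmvc_config(K = 2, restarts = 2, seed = s, mode = "exact",
                              init_labels = il))
    ctx <- bmvc:::build_ctx(data, inst$relations,
                            bmvc_config(K = 2, mode = "exact"))
    st <- f$state
    st$loglik <- lapply(seq_along(X), function(v)
      bmvc:::component_loglik(ctx$X[[v]], st$theta[[v]], ctx$base))
    base_obj <- bmvc:::objective_full(ctx, st)
    # no single-entity move improves the exhaustively computed objective
    for (v in 1:2) {
      for (i in seq_len(inst$N[v])) {
        for (k in 1:2) {
          if (k == st$z[[v]][i]) next
          st2 <- st
          st2$z[[v]][i] <- k
          expect_lte(bmvc:::objective_full(ctx, st2), base_obj + 1e-9)
        }
      }
    }
  }
})
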