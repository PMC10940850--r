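# The coupled assignment prior, its partition function, full conditionals,
# pseudolikelihood and joint objective.

test_that("unnormalized assignment prior matches direct substitution", {
  tiny <- tiny_two_view(phi = 1)
  # pi terms 0.5 * 0.5, one matched unit edge doubles the mass
  expect_equal(assignment_log_prior(tiny$z, tiny$pi, tiny$relations, phi = 1),
               log(0.5))
  # coupling term vanishes at phi = 0
  expect_equal(assignment_log_prior(tiny$z, tiny$pi, tiny$relations, phi = 0),
               log(0.25))
  # no relations: independent-mixture prior regardless of phi
  z <- list(a = c(1L, 2L), b = c(2L, 1L, 1L))
  pi <- list(a = c(0.3, 0.7), b = c(0.2, 0.5, 0.3))
  expect_equal(assignment_log_prior(z, pi, NULL, phi = NULL),
               sum(log(pi$a[z$a])) + sum(log(pi$b[z$b])))
  empty <- mv_relations(list(relation_block("a", "b", matrix(0, 2, 3))))
  expect_equal(assignment_log_prior(z, pi, empty, phi = 5),
               assignment_log_prior(z, pi, NULL))
})

test_that("prior evaluation matches the substitution oracle on random instances", {
  for (s in 1:25) {
    inst <- random_instance(1000 + s)
    got <- assignment_log_prior(inst$z, inst$pi, inst$relations,
                                C = inst$C, phi = inst$phi)
    want <- log(oracle_unnorm(inst$z, inst$pi, inst$edges, inst$C, inst$phi))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("exact partition function equals exhaustive enumeration", {
  tiny <- tiny_two_view(phi = 1)
  # four joint assignments with masses 0.5, 0.25, 0.25, 0.5
  expect_equal(assignment_log_partition(tiny$pi, tiny$relations, phi = 1,
                                        N = c(1L, 1L)),
               log(1.5))
  # normalized prior when phi = 0 or when there are no pairs
  expect_equal(assignment_log_partition(tiny$pi, tiny$relations, phi = 0,
                                        N = c(1L, 1L)), 0)
  expect_equal(assignment_log_partition(list(v = c(0.4, 0.6)), NULL, N = 3L), 0)
  for (s in 1:30) {
    inst <- random_instance(2000 + s)
    got <- assignment_log_partition(inst$pi, inst$relations, C = inst$C,
                                    phi = inst$phi, N = inst$N)
    want <- log(oracle_partition(inst$pi, inst$edges, inst$C, inst$phi, inst$N))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("partition enumeration is refused above the per-component cap", {
  # a single fully connected component of 8 + 8 entities at K = 3
  R <- matrix(1, 8, 8)
  rel <- mv_relations(list(relation_block("a", "b", R)))
  pi <- list(a = rep(1 / 3, 3), b = rep(1 / 3, 3))
  expect_error(assignment_log_partition(pi, rel, phi = 1, N = c(8L, 8L),
                                        enum_cap = 1e4),
               "pseudolikelihood")
})

test_that("full conditional reduces to pi, saturates with phi, sums to one", {
  tiny <- tiny_two_view()
  pi <- list(v1 = c(0.3, 0.7), v2 = c(0.5, 0.5))
  # phi = 0 and a constant data term return the mixture weights
  expect_equal(assignment_conditional(1, 1, tiny$z, pi, tiny$relations, phi = 0,
                                      data_loglik = c(2, 2)),
               pi$v1)
  # one matched unit-weight neighbor at phi = 1: proportional to (2, 1)
  expect_equal(assignment_conditional(1, 1, tiny$z, tiny$pi, tiny$relations,
                                      phi = 1),
               c(2 / 3, 1 / 3))
  # large phi concentrates all mass on the matched cluster
  p_sat <- assignment_conditional(1, 1, tiny$z, tiny$pi, tiny$relations,
                                  phi = 1e8)
  expect_gt(p_sat[1], 1 - 1e-6)
  for (s in 1:10) {
    inst <- random_instance(3000 + s)
    for (v in seq_len(inst$V)) {
      for (i in seq_len(inst$N[v])) {
        p <- assignment_conditional(v, i, inst$z, inst$pi, inst$relations,
                                    C = inst$C, phi = inst$phi)
        expect_equal(sum(p), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("pseudolikelihood equals the sum of enumerated full conditionals", {
  for (s in 1:15) {
    inst <- random_instance(4000 + s)
    want <- 0
    for (v in seq_len(inst$V)) {
      for (i in seq_len(inst$N[v])) {
        p <- assignment_conditional(v, i, inst$z, inst$pi, inst$relations,
                                    C = inst$C, phi = inst$phi)
        want <- want + log(p[inst$z[[v]][i]])
      }
    }
    got <- pseudo_log_prior(inst$z, inst$pi, inst$relations, inst$C, inst$phi)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("zero coupling reduces every quantity to the independent mixture", {
  for (s in 1:8) {
    inst <- random_instance(5000 + s)
    base <- sum(vapply(seq_len(inst$V), function(v)
      sum(log(inst$pi[[v]][inst$z[[v]]])), numeric(1)))
    zero <- rep(0, length(inst$phi))
    expect_equal(assignment_log_prior(inst$z, inst$pi, inst$relations,
                                      inst$C, zero), base)
    expect_equal(assignment_log_partition(inst$pi, inst$relations, inst$C,
                                          zero, N = inst$N), 0)
    expect_equal(pseudo_log_prior(inst$z, inst$pi, inst$relations, inst$C,
                                  zero), base)
  }
})

test_that("prior is strictly increasing in phi when a matched pair exists", {
  tiny <- tiny_two_view()
  vals <- vapply(c(0, 0.5, 1, 2, 5), function(ph)
    assignment_log_prior(tiny$z, tiny$pi, tiny$relations, phi = ph), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("pseudolikelihood equals the exact normalized prior when R is empty", {
  z <- list(a = c(1L, 2L, 2L), b = 1L)
  pi <- list(a = c(0.2, 0.8), b = c(0.6, 0.4))
  rel <- mv_relations(list(relation_block("a", "b", matrix(0, 3, 1))))
  exact <- assignment_log_prior(z, pi, rel, phi = 2) -
    assignment_log_partition(pi, rel, phi = 2, N = c(3L, 1L))
  expect_equal(pseudo_log_prior(z, pi, rel, phi = 2), exact, tolerance = 1e-12)
})

test_that("gaussian component log-density matches closed forms", {
  g <- gaussian_base()
  expect_equal(g$loglik(matrix(0, 1, 1), list(mean = 0, cov = diag(1))),
               -0.5 * log(2 * pi))
  th <- list(mean = c(1, -1), cov = diag(c(2, 0.5)))
  x <- c(0.3, 0.4)
  expect_equal(g$loglik(matrix(x, 1), th),
               dnorm(x[1], 1, sqrt(2), log = TRUE) +
                 dnorm(x[2], -1, sqrt(0.5), log = TRUE))
  # symmetry about the mean
  expect_equal(g$loglik(matrix(c(2, 0), 1), th), g$loglik(matrix(c(0, -2), 1), th))
  expect_error(g$loglik(matrix(x, 1), list(mean = c(0, 0),
                                           cov = matrix(c(1, 2, 2, 1), 2))),
               "positive definite")
})

test_that("joint objective composes data, prior and hyperprior terms", {
  blobs <- make_blobs(4, list(c(0, 0), c(5, 5)), seed = 7)
  X1 <- blobs$X
  X2 <- blobs$X + 0.1
  rownames(X2) <- paste0("b", seq_len(nrow(X2)))
  data <- mv_dataset(list(v1 = X1, v2 = X2))
  rel <- mv_relations(list(relation_block("v1", "v2", diag(nrow(X1)))))
  g <- gaussian_base()
  z <- list(v1 = blobs$labels, v2 = blobs$labels)
  pi <- list(v1 = c(0.5, 0.5), v2 = c(0.5, 0.5))
  theta <- lapply(list(X1, X2), function(X)
    lapply(1:2, function(k) g$mle(X[z[[1]] == k, , drop = FALSE], eps = 1e-8)))
  flat <- bmvc_priors(phi_prior = "flat")
  # factorizes at phi = 0 into per-view hard-assignment mixture objectives
  per_view <- vapply(1:2, function(v) {
    X <- list(X1, X2)[[v]]
    ll <- 0
    for (k in 1:2) {
      rows <- which(z[[v]] == k)
      ll <- ll + sum(g$loglik(X[rows, , drop = FALSE], theta[[v]][[k]])) +
        length(rows) * log(0.5)
    }
    ll
  }, numeric(1))
  expect_equal(joint_objective(data, z, pi, theta, rel, phi = 0, priors = flat,
                               mode = "pseudo"),
               sum(per_view), tolerance = 1e-10)
  # exact and pseudo agree without relations
  norel <- mv_relations()
  expect_equal(joint_objective(data, z, pi, theta, norel, priors = flat,
                               mode = "exact"),
               joint_objective(data, z, pi, theta, norel, priors = flat,
                               mode = "pseudo"))
  # exact mode equals data term + unnormalized prior - partition function
  obj <- joint_objective(data, z, pi, theta, rel, phi = 1.5, priors = flat,
                         mode = "exact")
  dat <- sum(vapply(1:2, function(v) {
    X <- list(X1, X2)[[v]]
    sum(vapply(seq_len(nrow(X)), function(i)
      g$loglik(X[i, , drop = FALSE], theta[[v]][[z[[v]][i]]]), numeric(1)))
  }, numeric(1)))
  comp <- dat + assignment_log_prior(z, pi, rel, phi = 1.5) -
    assignment_log_partition(pi, rel, phi = 1.5, N = view_sizes(data))
  expect_equal(obj, comp, tolerance = 1e-8)
})

test_that("dimension and label errors are caught", {
  tiny <- tiny_two_view()
  expect_error(assignment_log_prior(list(v1 = 3L, v2 = 1L), tiny$pi,
                                    tiny$relations, phi = 1), "labels")
  expect_error(assignment_log_prior(list(v1 = c(1L, 1L), v2 = 1L), tiny$pi,
                                    tiny$relations, phi = 1), "dimensions")
  bad_rel <- mv_relations(list(relation_block("v1", "v2", matrix(1, 2, 2))))
  expect_error(assignment_log_prior(tiny$z, tiny$pi, bad_rel, phi = 1),
               "dimensions")
  # coupled views must share the cluster count
  pi_uneven <- list(v1 = c(0.5, 0.5), v2 = c(0.2, 0.3, 0.5))
  expect_error(assignment_log_prior(list(v1 = 1L, v2 = 1L), pi_uneven,
                                    tiny$relations, phi = 1),
               "equal K|cluster counts")
  expect_error(relation_block("a", "b", matrix(-1, 1, 1)), "non-negative")
})
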