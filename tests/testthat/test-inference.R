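make_fit <- function(beta, var_beta, N = 10) {
  structure(list(beta_hat = matrix(beta, 1), var_beta = var_beta,
                 psi = psi_model("scaled_identity", 0), N = N,
                 E = length(beta), n_iterations = 2L, converged = TRUE),
            class = "group_fit")
}

test_that("network statistic is the quadratic form it claims to be", {
  set.seed(41)
  E <- 10
  v <- diag(E) / 2
  b <- rnorm(E)
  expect_equal(network_statistic(make_fit(b, v), make_fit(b, v)), 0)
  d <- rnorm(E)
  expect_equal(network_statistic(make_fit(b + d, diag(E) / 2),
                                 make_fit(b, diag(E) / 2)),
               sum(d^2))
  # random instance vs an independent dense solver
  map <- edge_index_map(5)
  st1 <- random_valid_state(5, map)
  st2 <- random_valid_state(5, map)
  f1 <- make_fit(rnorm(map$E), st1$Lambda / 7)
  f2 <- make_fit(rnorm(map$E), st2$Lambda / 9)
  dd <- as.numeric(f1$beta_hat - f2$beta_hat)
  M <- f1$var_beta + f2$var_beta
  oracle <- drop(t(dd) %*% qr.solve(M, dd))
  expect_equal(network_statistic(f1, f2), oracle, tolerance = 1e-8)
})

test_that("edge statistic is the squared plug-in z-score", {
  f1 <- make_fit(c(3, 1), diag(c(1, 2)))
  f2 <- make_fit(c(1, 1), diag(c(3, 2)))
  expect_equal(edge_statistic(f1, f2, 1), 4 / 4)
  expect_equal(edge_statistic(f1, f2, 2), 0)
  expect_error(edge_statistic(make_fit(1, matrix(0, 1, 1)),
                              make_fit(0, matrix(0, 1, 1)), 1),
               "degenerate edge")
  # with diagonal variance matrices the edge statistics sum to the
  # network statistic
  set.seed(42)
  E <- 8
  v1 <- diag(runif(E, 0.5, 2))
  v2 <- diag(runif(E, 0.5, 2))
  f1 <- make_fit(rnorm(E), v1)
  f2 <- make_fit(rnorm(E), v2)
  per_edge <- vapply(1:E, function(e) edge_statistic(f1, f2, e), numeric(1))
  expect_equal(sum(per_edge), network_statistic(f1, f2))
})

test_that("BH adjustment matches the hand-rolled step-up on random input", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (rep in 1:10) {
    p <- runif(25)^2
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_manual(p))
    expect_true(all(adj >= p))
    # rejection set preserved at every alpha
    for (alpha in c(0.05, 0.2)) {
      m <- length(p)
      thresh <- max(c(0, which(sort(p) <= seq_len(m) / m * alpha)))
      stepup <- if (thresh == 0) rep(FALSE, m) else p <= sort(p)[thresh]
      expect_identical(adj <= alpha, stepup)
    }
  }
})

sim_two_group <- function(N1, N2, E = 10, shift = 0, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm((N1 + N2) * E), N1 + N2)
  Y[seq_len(N1), ] <- Y[seq_len(N1), ] + shift
  connectivity_dataset(Y, rep(c("g1", "g2"), c(N1, N2)),
                       edge_index_map(5))
}

test_that("exhaustive permutation p equals the explicit enumeration", {
  ds <- sim_two_group(3, 3, shift = 0.8, seed = 7)
  Sig <- list(g1 = diag(10), g2 = diag(10))
  res <- permutation_test(ds, Sig, "scaled_identity",
                          permutation_plan(exhaustive = TRUE))
  expect_identical(res$network$B, as.integer(choose(6, 3)))
  # oracle: recompute every assignment from scratch with fit_group +
  # network_statistic
  combos <- combn(6, 3)
  stats <- apply(combos, 2, function(rows) {
    f1 <- fit_group(ds$Y[rows, ], NULL, diag(10), "scaled_identity")
    f2 <- fit_group(ds$Y[-rows, ], NULL, diag(10), "scaled_identity")
    network_statistic(f1, f2)
  })
  obs <- stats[1] # first combination is 1,2,3 = the observed labels
  expect_equal(res$network$statistic, obs, tolerance = 1e-10)
  expect_equal(res$network$p_perm, mean(stats >= obs - 1e-12))
})

test_that("the fast permutation path agrees with the full iterative fit", {
  set.seed(44)
  map <- edge_index_map(6)
  st <- random_valid_state(6, map)
  Y <- matrix(rnorm(16 * map$E), 16)
  ds <- connectivity_dataset(Y, rep(c("a", "b"), each = 8), map)
  for (structure in c("scaled_identity", "compound_symmetry")) {
    res <- permutation_test(ds, list(a = st$Lambda, b = st$Lambda),
                            structure, permutation_plan(B = 5, seed = 2))
    f1 <- fit_group(Y[1:8, ], NULL, st$Lambda, structure)
    f2 <- fit_group(Y[9:16, ], NULL, st$Lambda, structure)
    expect_equal(res$network$statistic, network_statistic(f1, f2),
                 tolerance = 1e-8)
    per_edge <- vapply(seq_len(map$E),
                       function(e) edge_statistic(f1, f2, e), numeric(1))
    expect_equal(res$edges$statistic, per_edge, tolerance = 1e-8)
  }
})

test_that("permutation p-values respect their contracts", {
  ds <- sim_two_group(6, 6, shift = 0, seed = 9)
  Sig <- list(g1 = diag(10), g2 = diag(10))
  plan <- permutation_plan(B = 99, seed = 31)
  res <- permutation_test(ds, Sig, "scaled_identity", plan)
  expect_gte(res$network$p_perm, 1 / 100)
  expect_lte(res$network$p_perm, 1)
  expect_true(all(res$edges$p_fdr >= res$edges$p_perm))
  # relabeling which group is which leaves the p-value unchanged
  ds_swap <- connectivity_dataset(ds$Y,
                                  factor(ds$groups,
                                         levels = rev(levels(ds$groups))),
                                  ds$map)
  res_swap <- permutation_test(ds_swap, Sig, "scaled_identity", plan)
  expect_equal(res_swap$network$statistic, res$network$statistic)
  expect_equal(res_swap$network$p_perm, res$network$p_perm)
  # duplicated groups: observed sits at the center of its null
  Yd <- rbind(ds$Y[1:6, ], ds$Y[1:6, ])
  dsd <- connectivity_dataset(Yd, rep(c("g1", "g2"), each = 6),
                              edge_index_map(5))
  resd <- permutation_test(dsd, Sig, "scaled_identity",
                           permutation_plan(B = 199, seed = 8))
  expect_gt(resd$network$p_perm, 0.5)
})

test_that("null permutation p-values are super-uniform", {
  # exchangeable subjects, no group difference: P(p <= a) <= a + MC error
  set.seed(46)
  pvals <- vapply(1:60, function(r) {
    ds <- sim_two_group(5, 5, shift = 0, seed = 1000 + r)
    res <- permutation_test(ds, list(g1 = diag(10), g2 = diag(10)),
                            "scaled_identity",
                            permutation_plan(B = 60, seed = r))
    res$network$p_perm
  }, numeric(1))
  for (a in c(0.05, 0.1)) {
    expect_lte(mean(pvals <= a), a + 2.5 * sqrt(a * (1 - a) / 60))
  }
})
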