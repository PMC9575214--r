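test_that("the true model realizes the scenario structure", {
  cfg <- scenario_config(V = 20, rho_within = 0.3, seed = 3)
  model <- make_true_model(cfg)
  expect_equal(dim(model$Lambda_true), c(190, 190))
  expect_setequal(unique(as.numeric(model$Lambda_true)), c(1, 0.3, 0))
  expect_true(min(model$eigen$values) > 0)
  expect_equal(model$Lambda_true,
               brute_lambda(rep(1:2, each = 10), 0, c(0.3, 0.3),
                            model$map))
  # sparse shift: 5% of 190 edges at 0.8 each
  expect_equal(sum(model$d_vector != 0), 10)
  expect_equal(sum(model$d_vector), 8.0)
  # odd V splits ceiling/floor
  model21 <- make_true_model(scenario_config(V = 21, seed = 3))
  expect_equal(tabulate(model21$omega_true), c(11, 10))
  # rho 0 collapses to the identity
  m0 <- make_true_model(scenario_config(V = 8, rho_within = 0, seed = 1))
  expect_equal(m0$Lambda_true, diag(28))
  # null configuration shares the code path: same support, zero shift
  m_null <- make_true_model(scenario_config(V = 20, rho_within = 0.3,
                                            effect_size = 0, seed = 3))
  expect_identical(m_null$support, model$support)
  expect_equal(sum(m_null$d_vector != 0), 0)
})

test_that("simulated datasets have the configured moments", {
  cfg <- scenario_config(V = 20, rho_within = 0.5, delta = 0, N = 500,
                         seed = 8)
  model <- make_true_model(cfg)
  ds <- simulate_dataset(model, cfg, rep_seed = 42)
  expect_s3_class(ds, "connectivity_dataset")
  expect_equal(nrow(ds$Y), 1000)
  # with delta = 0 all subjects share Lambda_true: pooled covariance close
  Yc <- ds$Y
  Yc[ds$groups == "control", ] <-
    sweep(Yc[ds$groups == "control", , drop = FALSE], 2, model$d_vector)
  S <- crossprod(sweep(Yc, 2, colMeans(Yc))) / (nrow(Yc) - 1)
  # per-entry sampling sd is about sqrt((1 + rho^2) / 1000) ~ 0.035; bound
  # the worst of the 190^2 entries at ~5 sd and the average much tighter
  expect_lt(max(abs(S - model$Lambda_true)), 0.2)
  expect_lt(mean(abs(S - model$Lambda_true)), 0.05)
  # group mean difference recovers the sparse shift (per-edge sd ~ 0.063)
  dhat <- colMeans(ds$Y[ds$groups == "control", ]) -
    colMeans(ds$Y[ds$groups == "case", ])
  expect_lt(max(abs(dhat - model$d_vector)), 0.25)
  expect_lt(mean(abs(dhat - model$d_vector)), 0.08)
  # determinism in the replicate seed
  ds2 <- simulate_dataset(model, cfg, rep_seed = 42)
  expect_identical(ds$Y, ds2$Y)
  ds3 <- simulate_dataset(model, cfg, rep_seed = 43)
  expect_false(identical(ds$Y, ds3$Y))
})

test_that("experiments are pure functions of the scenario seed", {
  cfg <- scenario_config(V = 8, rho_within = 0.5, N = 6, n_reps = 3,
                         B = 30, sigma_method = "oracle", seed = 21)
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(a$replicates, b$replicates)
  expect_true(a$rejection_rate %in% c(0, 1 / 3, 2 / 3, 1))
  one <- run_experiment(scenario_config(V = 8, N = 6, n_reps = 1, B = 30,
                                        sigma_method = "oracle", seed = 4))
  expect_true(one$rejection_rate %in% c(0, 1))
  # different seed, different replicate statistics
  c2 <- run_experiment(scenario_config(V = 8, rho_within = 0.5, N = 6,
                                       n_reps = 3, B = 30,
                                       sigma_method = "oracle", seed = 22))
  expect_false(identical(a$replicates$statistic, c2$replicates$statistic))
})

test_that("power does not fall off with more subjects (oracle mode)", {
  base <- list(V = 10, rho_within = 0.5, delta = 0.15, n_reps = 30, B = 60,
               sigma_method = "oracle", seed = 17)
  p10 <- run_experiment(do.call(scenario_config, c(base, N = 10)))
  p25 <- run_experiment(do.call(scenario_config, c(base, N = 25)))
  expect_gte(p25$rejection_rate, p10$rejection_rate - 0.1)
})
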