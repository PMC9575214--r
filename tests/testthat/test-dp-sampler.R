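# Correctness checks for the partition Gibbs sweep and the random-walk
# factor updates, against enumeration / grid / prior oracles. The
# full-length versions of these checks live in the acceptance suite; here
# the chains are kept short enough for routine runs.

partition_key <- function(omega) paste(omega, collapse = ".")

test_that("Gibbs sweep targets the enumerated partition posterior (V = 3)", {
  rho_w <- 0.45
  fx <- make_H_fixture(3, c(1, 1, 1), 0, rho_w, N = 25, seed = 101)
  map <- fx$map
  # near-degenerate factor priors pin every rho_k at rho_w
  hyper <- dp_hyperparameters(alpha = 1, muk = rho_w, tauk_sq = 1e-18,
                              mu0 = 0, tau0_sq = 1e-18)
  parts <- all_set_partitions(3)
  logw <- vapply(parts, function(p) {
    dense_loglik(fx$H$H, fx$H$N, p, 0, rep(rho_w, max(p)), map) +
      log(crp_probability(p, 1))
  }, numeric(1))
  probs <- exp(logw - max(logw))
  probs <- probs / sum(probs)
  set.seed(202)
  state <- list(omega = c(1L, 1L, 1L), rho0 = 0, rho_k = rho_w)
  n_sweep <- 6000
  keys <- character(n_sweep)
  for (s in seq_len(n_sweep)) {
    state <- gibbs_update_omega(state, fx$H, hyper, map)
    keys[s] <- partition_key(state$omega)
  }
  keep <- keys[seq(10, n_sweep, by = 5)]
  obs <- table(factor(keep, levels = vapply(parts, partition_key, "")))
  expected <- probs * length(keep)
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  p <- pchisq(chi2, df = length(parts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("with a flat likelihood the sweep samples the CRP prior", {
  # rho_k forced equal to rho0: the structure, hence the likelihood, is
  # the same for every partition
  rho <- 0.2
  fx <- make_H_fixture(3, c(1, 1, 1), 0, 0.4, N = 25, seed = 55)
  hyper <- dp_hyperparameters(alpha = 1.5, mu0 = rho, tau0_sq = 1e-18,
                              muk = rho, tauk_sq = 1e-18)
  parts <- all_set_partitions(3)
  probs <- vapply(parts, crp_probability, numeric(1), alpha = 1.5)
  set.seed(77)
  state <- list(omega = c(1L, 1L, 1L), rho0 = rho, rho_k = rho)
  n_sweep <- 6000
  keys <- character(n_sweep)
  for (s in seq_len(n_sweep)) {
    state <- gibbs_update_omega(state, fx$H, hyper, map = fx$map)
    keys[s] <- partition_key(state$omega)
  }
  keep <- keys[seq(10, n_sweep, by = 5)]
  obs <- table(factor(keep, levels = vapply(parts, partition_key, "")))
  expected <- probs * length(keep)
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_gt(pchisq(chi2, df = 4, lower.tail = FALSE), 0.01)
})

test_that("factor updates sample the grid-evaluated conditional (V = 4)", {
  fx <- make_H_fixture(4, rep(1, 4), 0, 0.5, N = 25, seed = 303)
  map <- fx$map
  hyper <- dp_hyperparameters(proposal_sd = 0.1)
  E <- map$E
  grid <- seq(-1 / (E - 1) + 1e-4, 1 - 1e-4, length.out = 2001)
  logd <- vapply(grid, function(r) {
    dense_loglik(fx$H$H, fx$H$N, rep(1, 4), 0, r, map) +
      dnorm(r, hyper$muk, sqrt(hyper$tauk_sq), log = TRUE)
  }, numeric(1))
  dens <- exp(logd - max(logd))
  cdf <- cumsum(dens) / sum(dens)
  set.seed(404)
  state <- list(omega = rep(1L, 4), rho0 = 0, rho_k = 0.3)
  n_draw <- 20000
  draws <- numeric(n_draw)
  acc <- 0L
  prop <- 0L
  for (s in seq_len(n_draw)) {
    state <- mh_update_rho(state, fx$H, hyper, map)
    draws[s] <- state$rho_k[1]
    acc <- acc + attr(state, "n_accept")
    prop <- prop + attr(state, "n_propose")
  }
  # acceptance fraction strictly inside (0, 1)
  expect_gt(acc / prop, 0)
  expect_lt(acc / prop, 1)
  emp <- ecdf(draws)
  ks <- max(abs(emp(grid) - cdf))
  expect_lt(ks, 0.05)
})

test_that("with the likelihood suppressed the factors recover their prior", {
  # prior kept tight relative to the positive definite region (rho0 in
  # (-1/5, 1) for the all-singleton partition) so truncation is negligible
  fx <- make_H_fixture(4, rep(1, 4), 0, 0.5, N = 25, seed = 9)
  hyper <- dp_hyperparameters(mu0 = 0.1, tau0_sq = 0.01, proposal_sd = 0.1)
  set.seed(11)
  state <- list(omega = 1:4, rho0 = 0.1, rho_k = rep(0, 4))
  n_draw <- 20000
  draws <- numeric(n_draw)
  for (s in seq_len(n_draw)) {
    state <- mh_update_rho(state, fx$H, hyper, map = fx$map,
                           likelihood_weight = 0)
    draws[s] <- state$rho0
  }
  se <- batch_se(draws)
  expect_lt(abs(mean(draws) - 0.1), 3 * se + 1e-3)
  expect_lt(abs(sd(draws) - 0.1), 0.01)
})

test_that("edge covariance estimation is deterministic given a seed and
           invariant to cluster relabeling", {
  set.seed(61)
  fx <- make_H_fixture(8, rep(1:2, each = 4), 0, c(0.6, 0.6), N = 25,
                       seed = 61)
  Yres <- matrix(rnorm(25 * fx$map$E), 25) # raw residual input
  L <- fx$Lambda
  eg <- eigen(L, symmetric = TRUE)
  R <- t(eg$vectors %*% (sqrt(eg$values) * t(Yres)))
  hyper <- dp_hyperparameters(n_iter = 300, n_burn = 150, seed = 99)
  a <- estimate_edge_covariance(R, 1, hyper, fx$map)
  b <- estimate_edge_covariance(R, 1, hyper, fx$map)
  expect_identical(a$Sigma_hat, b$Sigma_hat)
  expect_identical(a$omega_hat, b$omega_hat)
  # point estimate reported in canonical labels; relabeling the same
  # partition leaves the structure unchanged
  perm <- max(a$omega_hat) + 1 - a$omega_hat
  la <- build_lambda(a$omega_hat, a$rho_hat, fx$map)
  lb <- build_lambda(perm, correlation_factors(a$rho_hat$rho0,
                                               rev(a$rho_hat$rho_k)),
                     fx$map)
  expect_equal(la$Lambda, lb$Lambda)
})

test_that("the sampler recovers block structure and the independence null", {
  # two well-separated clusters: structure recovered, moderate error
  set.seed(71)
  map <- edge_index_map(12)
  omega_true <- rep(1:2, each = 6)
  L <- brute_lambda(omega_true, 0, c(0.7, 0.7), map)
  eg <- eigen(L, symmetric = TRUE)
  R <- t(eg$vectors %*% (sqrt(eg$values) * t(matrix(rnorm(25 * map$E),
                                                    25))))
  R <- sweep(R, 2, colMeans(R))
  est <- estimate_edge_covariance(R, 1,
                                  dp_hyperparameters(n_iter = 300,
                                                     n_burn = 150,
                                                     seed = 5), map)
  expect_equal(adjusted_rand(est$omega_hat, omega_true), 1)
  expect_lt(max(abs(est$Lambda_hat - L)), 0.2)
  # independent edges: off-diagonal estimates stay near zero
  set.seed(72)
  R0 <- matrix(rnorm(200 * map$E), 200)
  R0 <- sweep(R0, 2, colMeans(R0))
  est0 <- estimate_edge_covariance(R0, 1,
                                   dp_hyperparameters(n_iter = 300,
                                                      n_burn = 150,
                                                      seed = 6), map)
  off <- est0$Lambda_hat[upper.tri(est0$Lambda_hat)]
  expect_lt(mean(abs(off)), 0.05)
})
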