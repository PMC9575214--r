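#' Scenario configuration for the power / type-I-error experiments
#'
#' Defaults follow the study design: two equal latent clusters of regions,
#' within-cluster edge correlation `rho_within`, between-structure
#' correlation 0, per-subject Uniform(-delta, delta) diagonal perturbation,
#' and a sparse mean shift of `effect_size = 0.8` at `effect_fraction = 5%`
#' of the edges in one group; 100 replicates of 500 permutations at
#' `alpha = 0.05`. Setting `effect_size = 0` turns the same pipeline into a
#' type-I-error run.
#'
#' @param V Number of regions (>= 6).
#' @param rho_within Within-cluster edge correlation (`rho_1 = rho_2`).
#' @param rho_between Between-structure correlation `rho_0` (default 0).
#' @param delta Half-width of the Uniform(-delta, delta) subject effect.
#' @param N Per-group sample size.
#' @param effect_size Mean shift `d` applied at the chosen edges of the
#'   control group (0 for null runs).
#' @param effect_fraction Fraction of edges carrying the shift.
#' @param psi_structure Heterogeneity structure used at estimation time.
#' @param n_reps Number of simulation replicates.
#' @param B Permutations per replicate.
#' @param alpha Significance level.
#' @param sigma_method `"dp"` runs the Dirichlet-process covariance
#'   estimator per group; `"oracle"` injects the true edge correlation
#'   structure as `Sigma_hat` (isolates the inference layer from MCMC
#'   noise in calibration checks).
#' @param mcmc [dp_hyperparameters()] used when `sigma_method = "dp"`.
#'   The scenario default runs 400 sweeps with 200 burn-in: replicated
#'   experiments use shorter chains than one-off estimation because the
#'   block partition at these dimensions is typically identified within
#'   tens of sweeps.
#' @param seed Scenario seed; the full experiment is a pure function of it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(V = 20L, rho_within = 0.3, rho_between = 0,
                            delta = 0.15, N = 25L,
                            effect_size = 0.8, effect_fraction = 0.05,
                            psi_structure = c("scaled_identity",
                                              "compound_symmetry"),
                            n_reps = 100L, B = 500L, alpha = 0.05,
                            sigma_method = c("dp", "oracle"),
                            mcmc = dp_hyperparameters(n_iter = 400L,
                                                      n_burn = 200L),
                            seed = 1L) {
  psi_structure <- match.arg(psi_structure)
  sigma_method <- match.arg(sigma_method)
  stopifnot(V >= 6, rho_between >= 0, rho_between < 1,
            effect_fraction > 0, effect_fraction < 1,
            delta >= 0, N >= 2, n_reps >= 1, B >= 1)
  structure(
    list(V = as.integer(V), n_clusters = 2L, rho_within = rho_within,
         rho_between = rho_between, delta = delta, N = as.integer(N),
         effect_size = effect_size, effect_fraction = effect_fraction,
         psi_structure = psi_structure, n_reps = as.integer(n_reps),
         B = as.integer(B), alpha = alpha, sigma_method = sigma_method,
         mcmc = mcmc, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' True data-generating model of a scenario
#'
#' Assigns the first half of the regions to cluster 1 and the rest to
#' cluster 2 (sizes `ceiling(V/2)`, `floor(V/2)` for odd V), builds the true
#' edge correlation structure, and draws the support of the sparse mean
#' shift: `round(effect_fraction * E)` edges chosen uniformly without
#' replacement under the scenario seed. The support is fixed across
#' replicates, so a power estimate refers to one alternative.
#'
#' @param config A [scenario_config()].
#' @return An object of class `true_model` with `omega_true`,
#'   `Lambda_true`, its eigendecomposition, `d_vector`, and the map.
#' @export
make_true_model <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  V <- config$V
  map <- edge_index_map(V)
  omega_true <- rep(c(1L, 2L), c(ceiling(V / 2), floor(V / 2)))
  rho <- correlation_factors(config$rho_between,
                             rep(config$rho_within, 2L))
  lambda <- build_lambda(omega_true, rho, map)
  eg <- eigen(lambda$Lambda, symmetric = TRUE)
  if (min(eg$values) <= 0) {
    stop("scenario correlations do not give a positive definite structure",
         call. = FALSE)
  }
  set.seed(config$seed)
  n_shift <- round(config$effect_fraction * map$E)
  support <- sort(sample.int(map$E, n_shift))
  d_vector <- numeric(map$E)
  d_vector[support] <- config$effect_size
  structure(
    list(omega_true = omega_true, Lambda_true = lambda$Lambda,
         eigen = eg, d_vector = d_vector, support = support, map = map,
         config = config),
    class = "true_model"
  )
}

#' Simulate one two-group connectivity dataset
#'
#' Each subject gets a scalar perturbation `u ~ Uniform(-delta, delta)`
#' added to every diagonal entry of the edge covariance, then an edge vector
#' `Y ~ MVN(0, Lambda_true + u I)`; the control group's mean is shifted by
#' the sparse `d` vector. Groups are labelled `"case"` and `"control"`,
#' `N` subjects each.
#'
#' @param model A [make_true_model()] object.
#' @param config The [scenario_config()] (sample size, delta).
#' @param rep_seed Optional seed for this replicate; `NULL` continues the
#'   current RNG stream.
#' @return A [connectivity_dataset()].
#' @export
simulate_dataset <- function(model, config, rep_seed = NULL) {
  stopifnot(inherits(model, "true_model"))
  if (!is.null(rep_seed)) set.seed(rep_seed)
  N <- config$N
  Ntot <- 2L * N
  E <- model$map$E
  u <- stats::runif(Ntot, -config$delta, config$delta)
  lam_pert <- outer(model$eigen$values, u, "+") # E x Ntot
  if (any(lam_pert <= 0)) {
    stop("perturbed covariance not positive definite (delta too large)",
         call. = FALSE)
  }
  Z <- matrix(stats::rnorm(Ntot * E), E, Ntot)
  Y <- t(model$eigen$vectors %*% (sqrt(lam_pert) * Z))
  groups <- rep(c("case", "control"), each = N)
  Y[groups == "control", ] <-
    sweep(Y[groups == "control", , drop = FALSE], 2L, model$d_vector, "+")
  connectivity_dataset(Y, groups, model$map)
}

#' Run a power or type-I-error experiment
#'
#' For each replicate: simulate a dataset, estimate the edge covariance per
#' group (Dirichlet-process sampler or oracle injection of the truth), and
#' run the permutation test of the whole-network difference. The rejection
#' proportion at `alpha` is the power when `effect_size != 0` and the
#' type-I error when `effect_size = 0`; both use the identical code path.
#' Per-replicate seeds are derived deterministically from the scenario
#' seed, so replicates can be distributed without changing results.
#'
#' @param config A [scenario_config()].
#' @param progress Print a dot per replicate.
#' @return An object of class `experiment_result` with `rejection_rate`,
#'   per-replicate records, the failed-replicate count, and the scenario
#'   echo.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  model <- make_true_model(config) # consumes the scenario seed stream
  rep_seeds <- sample.int(2147483646L, config$n_reps)
  stats <- rep(NA_real_, config$n_reps)
  pvals <- rep(NA_real_, config$n_reps)
  failed <- character(0)
  for (r in seq_len(config$n_reps)) {
    res <- tryCatch(
      run_one_replicate(model, config, rep_seeds[r]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("rep %d: %s", r, conditionMessage(res)))
    } else {
      stats[r] <- res$statistic
      pvals[r] <- res$p
    }
    if (progress) {
      cat(".")
      if (r %% 50 == 0) cat(" ", r, "\n")
    }
  }
  if (progress) cat("\n")
  ok <- !is.na(pvals)
  structure(
    list(
      rejection_rate = mean(pvals[ok] <= config$alpha),
      replicates = data.frame(rep = seq_len(config$n_reps),
                              seed = rep_seeds,
                              statistic = stats, p = pvals),
      n_failed = sum(!ok),
      failures = failed,
      config = config
    ),
    class = "experiment_result"
  )
}

run_one_replicate <- function(model, config, rep_seed) {
  set.seed(rep_seed)
  ds <- simulate_dataset(model, config, rep_seed = NULL)
  lv <- levels(ds$groups)
  sigma_by_group <- lapply(lv, function(g) {
    if (config$sigma_method == "oracle") {
      return(model$Lambda_true)
    }
    Yg <- ds$Y[ds$groups == g, , drop = FALSE]
    Rg <- sweep(Yg, 2L, colMeans(Yg), check.margin = FALSE)
    est <- estimate_edge_covariance(Rg, p = 1L, hyper = config$mcmc,
                                    map = ds$map)
    est$Sigma_hat
  })
  names(sigma_by_group) <- lv
  tst <- permutation_test(ds, sigma_by_group, config$psi_structure,
                          permutation_plan(B = config$B, seed = NULL,
                                           alpha = config$alpha))
  list(statistic = tst$network$statistic, p = tst$network$p_perm)
}

#' @export
print.experiment_result <- function(x, ...) {
  kind <- if (x$config$effect_size == 0) "type-I error" else "power"
  cat("<experiment_result>", kind, "=", round(x$rejection_rate, 3),
      "over", sum(!is.na(x$replicates$p)), "replicates",
      sprintf("(V = %d, N = %d, rho = %.2f, delta = %.2f, %s)\n",
              x$config$V, x$config$N, x$config$rho_within, x$config$delta,
              x$config$psi_structure))
  if (x$n_failed > 0) cat("  failed replicates:", x$n_failed, "\n")
  invisible(x)
}
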