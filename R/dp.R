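#' Hyperparameters of the Dirichlet-process edge covariance model
#'
#' @param alpha Dirichlet-process concentration (> 0). Larger values favour
#'   more clusters a priori.
#' @param mu0,tau0_sq Normal prior mean and variance of the between-structure
#'   correlation `rho0`.
#' @param muk,tauk_sq Normal prior mean and variance of each within-cluster
#'   correlation `rho_k`.
#' @param n_iter,n_burn Total MCMC sweeps and burn-in discarded from the
#'   front (`n_iter > n_burn >= 0`).
#' @param proposal_sd Standard deviation of the Gaussian random-walk proposal
#'   used in the Metropolis-Hastings updates of the correlation factors.
#' @param seed Optional integer seed; when given, estimation is a
#'   deterministic function of its inputs.
#' @return An object of class `dp_hyperparameters`.
#' @export
dp_hyperparameters <- function(alpha = 1, mu0 = 0, tau0_sq = 0.25,
                               muk = 0, tauk_sq = 0.25,
                               n_iter = 2000L, n_burn = 1000L,
                               proposal_sd = 0.05, seed = NULL) {
  stopifnot(alpha > 0, tau0_sq > 0, tauk_sq > 0, proposal_sd > 0,
            n_iter > n_burn, n_burn >= 0)
  structure(
    list(alpha = alpha, mu0 = mu0, tau0_sq = tau0_sq,
         muk = muk, tauk_sq = tauk_sq,
         n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
         proposal_sd = proposal_sd, seed = seed),
    class = "dp_hyperparameters"
  )
}

# Chinese-restaurant-process log prior of a partition.
crp_log_prior <- function(omega, alpha) {
  omega <- canonical_partition(omega)
  m <- tabulate(omega)
  K <- length(m)
  V <- length(omega)
  K * log(alpha) + sum(lgamma(m)) - sum(log(alpha + seq_len(V) - 1))
}

#' Log posterior kernel of a partition and correlation-factor state
#'
#' Gaussian likelihood term `-N/2 (log|Lambda| + tr(H Lambda^{-1}))` plus the
#' Chinese-restaurant-process log prior of the partition and the normal log
#' priors of `rho0` and each occupied cluster's `rho_k`. Returns `-Inf` for
#' states whose Lambda is not positive definite.
#'
#' @param H A [compute_residual_summary()] object.
#' @param omega Integer cluster labels, one per region.
#' @param rho A [correlation_factors()] object.
#' @param hyper A [dp_hyperparameters()] object.
#' @param map An [edge_index_map()].
#' @param likelihood_weight Scalar in `[0, 1]` multiplying the likelihood
#'   term; 0 reduces the kernel to the prior (used in prior-recovery checks).
#' @return Log kernel value (finite or `-Inf`).
#' @export
log_posterior_kernel <- function(H, omega, rho, hyper, map,
                                 likelihood_weight = 1) {
  stopifnot(inherits(H, "residual_summary"))
  omega <- canonical_partition(omega)
  K <- max(omega)
  ll <- if (likelihood_weight > 0) {
    lambda_loglik_term(H$H, H$N, omega, rho, map) * likelihood_weight
  } else {
    spec <- lambda_spectrum(omega, rho, map)
    if (!spec$pd) -Inf else 0
  }
  if (!is.finite(ll)) {
    return(-Inf)
  }
  ll + crp_log_prior(omega, hyper$alpha) +
    stats::dnorm(rho$rho0, hyper$mu0, sqrt(hyper$tau0_sq), log = TRUE) +
    sum(stats::dnorm(rho$rho_k[seq_len(K)], hyper$muk, sqrt(hyper$tauk_sq),
                     log = TRUE))
}

# Normalize a sampler state: canonical labels, rho_k aligned and trimmed.
normalize_dp_state <- function(state) {
  old <- state$omega
  new <- canonical_partition(old)
  K <- max(new)
  rho_k <- numeric(K)
  for (k in seq_len(K)) {
    rho_k[k] <- state$rho_k[old[match(k, new)]]
  }
  list(omega = new, rho0 = state$rho0, rho_k = rho_k)
}

#' One Gibbs sweep over the node cluster assignments
#'
#' Visits each region in ascending index order. A region may join any
#' existing cluster (weight proportional to the cluster size excluding the
#' region, times the likelihood of the resulting structure) or open a new
#' cluster (weight proportional to `alpha`, with the new cluster's
#' correlation drawn from its normal prior; a region currently alone keeps
#' its own factor as the new-cluster candidate). Candidates whose structure
#' is not positive definite receive zero weight; if every candidate is
#' invalid the region keeps its assignment and a warning is counted.
#'
#' @param state List with `omega` (cluster labels), `rho0`, `rho_k`.
#' @param H A [compute_residual_summary()] object.
#' @param hyper A [dp_hyperparameters()] object.
#' @param map An [edge_index_map()].
#' @param likelihood_weight See [log_posterior_kernel()].
#' @return Updated state (canonical labels, `rho_k` aligned), with attribute
#'   `n_stuck` counting regions whose candidates were all invalid.
#' @export
gibbs_update_omega <- function(state, H, hyper, map, likelihood_weight = 1) {
  omega <- canonical_partition(state$omega)
  rho_k <- state$rho_k[seq_len(max(omega))]
  rho0 <- state$rho0
  V <- map$V
  n_stuck <- 0L
  for (i in seq_len(V)) {
    m <- tabulate(omega[-i], nbins = max(omega))
    existing <- which(m > 0L)
    singleton <- m[omega[i]] == 0L
    if (singleton) {
      rho_new <- rho_k[omega[i]]
    } else {
      rho_new <- stats::rnorm(1, hyper$muk, sqrt(hyper$tauk_sq))
    }
    cand_labels <- c(existing, max(omega) + 1L)
    logw <- vapply(seq_along(cand_labels), function(ci) {
      lab <- cand_labels[ci]
      om <- omega
      om[i] <- lab
      rk <- c(rho_k, rho_new)[seq_len(max(om))]
      if (lab > length(rho_k)) rk[lab] <- rho_new
      ll <- lambda_loglik_term(H$H, H$N, canonical_partition(om),
                               correlation_factors(rho0, align_rho(om, rk)),
                               map)
      if (!is.finite(ll)) {
        return(-Inf)
      }
      ll * likelihood_weight +
        if (ci <= length(existing)) log(m[lab]) else log(hyper$alpha)
    }, numeric(1))
    if (all(!is.finite(logw))) {
      n_stuck <- n_stuck + 1L
      next
    }
    w <- exp(logw - max(logw[is.finite(logw)]))
    w[!is.finite(logw)] <- 0
    pick <- cand_labels[sample.int(length(w), 1L, prob = w)]
    if (pick > length(rho_k)) {
      rho_k <- c(rho_k, rho_new)
    }
    omega[i] <- pick
    # drop emptied clusters, keep labels contiguous
    occ <- sort(unique(omega))
    if (length(occ) < length(rho_k)) {
      rho_k <- rho_k[occ]
      omega <- match(omega, occ)
    }
  }
  st <- normalize_dp_state(list(omega = omega, rho0 = rho0, rho_k = rho_k))
  attr(st, "n_stuck") <- n_stuck
  st
}

# rho_k vector aligned to the canonical relabeling of omega.
align_rho <- function(omega, rho_k) {
  new <- canonical_partition(omega)
  K <- max(new)
  out <- numeric(K)
  for (k in seq_len(K)) out[k] <- rho_k[omega[match(k, new)]]
  out
}

#' One Metropolis-Hastings sweep over the correlation factors
#'
#' Updates `rho0` and each occupied cluster's `rho_k` in turn with a Gaussian
#' random-walk proposal; acceptance uses the likelihood term plus the factor's
#' normal prior. Proposals yielding a non-positive-definite structure are
#' rejected outright.
#'
#' @inheritParams gibbs_update_omega
#' @return Updated state with attributes `n_accept` and `n_propose`.
#' @export
mh_update_rho <- function(state, H, hyper, map, likelihood_weight = 1) {
  omega <- canonical_partition(state$omega)
  K <- max(omega)
  rho_k <- state$rho_k[seq_len(K)]
  rho0 <- state$rho0
  ll_cur <- if (likelihood_weight > 0) {
    lambda_loglik_term(H$H, H$N, omega, correlation_factors(rho0, rho_k), map)
  } else {
    0
  }
  n_accept <- 0L
  n_propose <- 0L
  eval_ll <- function(r0, rk) {
    if (likelihood_weight > 0) {
      lambda_loglik_term(H$H, H$N, omega, correlation_factors(r0, rk), map)
    } else {
      spec <- lambda_spectrum(omega, correlation_factors(r0, rk), map)
      if (!spec$pd) -Inf else 0
    }
  }
  # rho0
  n_propose <- n_propose + 1L
  prop <- rho0 + stats::rnorm(1, 0, hyper$proposal_sd)
  ll_prop <- eval_ll(prop, rho_k)
  if (is.finite(ll_prop)) {
    log_r <- likelihood_weight * (ll_prop - ll_cur) +
      stats::dnorm(prop, hyper$mu0, sqrt(hyper$tau0_sq), log = TRUE) -
      stats::dnorm(rho0, hyper$mu0, sqrt(hyper$tau0_sq), log = TRUE)
    if (log(stats::runif(1)) < log_r) {
      rho0 <- prop
      ll_cur <- ll_prop
      n_accept <- n_accept + 1L
    }
  }
  for (k in seq_len(K)) {
    n_propose <- n_propose + 1L
    prop_k <- rho_k
    prop_k[k] <- rho_k[k] + stats::rnorm(1, 0, hyper$proposal_sd)
    ll_prop <- eval_ll(rho0, prop_k)
    if (is.finite(ll_prop)) {
      log_r <- likelihood_weight * (ll_prop - ll_cur) +
        stats::dnorm(prop_k[k], hyper$muk, sqrt(hyper$tauk_sq), log = TRUE) -
        stats::dnorm(rho_k[k], hyper$muk, sqrt(hyper$tauk_sq), log = TRUE)
      if (log(stats::runif(1)) < log_r) {
        rho_k <- prop_k
        ll_cur <- ll_prop
        n_accept <- n_accept + 1L
      }
    }
  }
  st <- list(omega = omega, rho0 = rho0, rho_k = rho_k)
  attr(st, "n_accept") <- n_accept
  attr(st, "n_propose") <- n_propose
  st
}

#' Estimate the edge covariance by Dirichlet-process clustering of regions
#'
#' Runs the MCMC (Gibbs sweep over cluster assignments, then
#' Metropolis-Hastings updates of the correlation factors, per sweep) on the
#' residual summary of `R`, discards the burn-in, and forms a plug-in point
#' estimate: the retained draw maximizing the log posterior kernel gives the
#' partition `omega_hat` (earliest draw on ties); `rho_hat` averages the
#' retained factor draws whose partition equals `omega_hat`. The covariance
#' estimate is `Sigma_hat = D^{1/2} Lambda(omega_hat, rho_hat) D^{1/2}` with
#' `D = Diag(H0)`.
#'
#' @param R Numeric `N x E` residual matrix.
#' @param p Number of design columns used to form the residuals (default 1).
#' @param hyper A [dp_hyperparameters()] object; when `hyper$seed` is set the
#'   result is deterministic.
#' @param map Optional [edge_index_map()]; inferred from `ncol(R)` when
#'   missing.
#' @return An object of class `posterior_covariance` with fields
#'   `omega_hat`, `rho_hat`, `Lambda_hat`, `Sigma_hat`, `samples`
#'   (retained draws) and `diagnostics` (per-sweep log posterior, cluster
#'   count, acceptance rates).
#' @export
estimate_edge_covariance <- function(R, p = 1L, hyper = dp_hyperparameters(),
                                     map = NULL) {
  R <- as.matrix(R)
  if (nrow(R) <= p) {
    stop("insufficient data: need N > p", call. = FALSE)
  }
  if (is.null(map)) {
    map <- edge_index_map(v_from_edge_count(ncol(R)))
  }
  stopifnot(map$E == ncol(R))
  H <- compute_residual_summary(R, p)
  if (!is.null(hyper$seed)) set.seed(hyper$seed)
  fit <- run_dp_chain_cpp(
    H$H, map$pairs - 1L, H$N,
    hyper$alpha, hyper$mu0, hyper$tau0_sq, hyper$muk, hyper$tauk_sq,
    hyper$proposal_sd, hyper$n_iter, hyper$n_burn,
    rep(0L, map$V), 0, 0
  )
  lp <- fit$logpost
  if (all(!is.finite(lp))) {
    stop("estimation failure: chain produced no positive definite state",
         call. = FALSE)
  }
  omega_draws <- fit$omega # n_keep x V, canonical 1-based labels
  part_key <- apply(omega_draws, 1L, paste, collapse = ".")
  best <- which.max(lp)
  omega_hat <- as.integer(omega_draws[best, ])
  K_hat <- max(omega_hat)
  same <- which(part_key == part_key[best])
  rho0_hat <- mean(fit$rho0[same])
  rho_k_hat <- colMeans(fit$rho_k[same, seq_len(K_hat), drop = FALSE])
  Lambda_hat <- build_lambda(omega_hat,
                             correlation_factors(rho0_hat, rho_k_hat), map)
  d <- diag(H$H0)
  Sigma_hat <- Lambda_hat$Lambda * tcrossprod(sqrt(d))
  structure(
    list(
      omega_hat = omega_hat,
      rho_hat = correlation_factors(rho0_hat, rho_k_hat),
      Lambda_hat = Lambda_hat$Lambda,
      Sigma_hat = Sigma_hat,
      map = map,
      H = H,
      samples = list(omega = omega_draws, rho0 = fit$rho0,
                     rho_k = fit$rho_k, logpost = lp),
      diagnostics = data.frame(
        sweep = seq_len(hyper$n_iter),
        K = as.integer(fit$K_traj),
        logpost = fit$logpost_traj
      ),
      acceptance_rate = fit$acc_rate,
      n_stuck = fit$n_stuck,
      hyper = hyper,
      seed = hyper$seed
    ),
    class = "posterior_covariance"
  )
}

#' @export
print.posterior_covariance <- function(x, ...) {
  cat("<posterior_covariance> E =", nrow(x$Sigma_hat),
      " K_hat =", max(x$omega_hat),
      " rho0_hat =", round(x$rho_hat$rho0, 3), "\n")
  cat("  rho_k_hat:", paste(round(x$rho_hat$rho_k, 3), collapse = ", "), "\n")
  invisible(x)
}
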