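#' Whole-network two-sample statistic
#'
#' Hotelling-type quadratic form
#' `(b1 - b2)' (var(b1) + var(b2))^{-1} (b1 - b2)` comparing the full edge
#' effect vectors of the two groups (identity contrast over all E edges).
#' A singular variance sum is ridged once by `1e-8 * trace / E` with a
#' warning.
#'
#' @param fit1,fit2 [fit_group()] objects for the two groups (intercept-only
#'   designs).
#' @return Non-negative scalar; 0 iff the effect vectors coincide.
#' @export
network_statistic <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "group_fit"), inherits(fit2, "group_fit"))
  if (fit1$E != fit2$E) stop("fits disagree on edge count", call. = FALSE)
  d <- as.numeric(fit1$beta_hat) - as.numeric(fit2$beta_hat)
  M <- fit1$var_beta + fit2$var_beta
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    warning("variance sum numerically singular; adding ridge")
    M <- M + diag(1e-8 * sum(diag(M)) / ncol(M), ncol(M))
    ch <- chol(M)
  }
  z <- backsolve(ch, forwardsolve(t(ch), d))
  max(0, sum(d * z))
}

#' Edge-wise two-sample statistic
#'
#' Squared two-sample z-score of a single edge's effect difference with
#' plug-in variances:
#' `(b1(e) - b2(e))^2 / (var(b1)(e,e) + var(b2)(e,e))`.
#'
#' @inheritParams network_statistic
#' @param e Edge position in 1..E.
#' @return Non-negative scalar.
#' @export
edge_statistic <- function(fit1, fit2, e) {
  stopifnot(e >= 1, e <= fit1$E)
  v <- fit1$var_beta[e, e] + fit2$var_beta[e, e]
  if (v <= 0) stop("degenerate edge ", e, ": zero variance", call. = FALSE)
  (as.numeric(fit1$beta_hat)[e] - as.numeric(fit2$beta_hat)[e])^2 / v
}

#' Benjamini-Hochberg adjustment of edge-wise p-values
#'
#' Step-up adjusted p-values: sort ascending, take running minima of
#' `p_(j) * m / j` from the largest rank down, cap at 1, restore the input
#' order. Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, never smaller than the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Permutation plan for the group comparison
#'
#' @param B Number of label permutations (>= 1).
#' @param seed Optional seed; with a seed the test is deterministic.
#' @param alpha Significance level (default 0.05).
#' @param exhaustive Enumerate every assignment of subjects to the two
#'   groups (sizes preserved) instead of sampling `B` of them; p-values are
#'   then exact.
#' @return An object of class `permutation_plan`.
#' @export
permutation_plan <- function(B = 500L, seed = NULL, alpha = 0.05,
                             exhaustive = FALSE) {
  if (!exhaustive && B < 1) stop("need B >= 1 permutations", call. = FALSE)
  structure(list(B = as.integer(B), seed = seed, alpha = alpha,
                 exhaustive = exhaustive),
            class = "permutation_plan")
}

# Moment fit of one pseudo-group against a fixed Sigma summary; returns the
# pieces the permutation statistics need. Mirrors fit_group for the
# intercept-only design (equality is asserted in the tests).
fast_group_fit <- function(Y, mean_diag_sigma, mean_off_sigma, structure) {
  N <- nrow(Y)
  beta <- colMeans(Y)
  R <- sweep(Y, 2L, beta, check.margin = FALSE)
  E <- ncol(Y)
  diag_omega_mean <- sum(R^2) / (N * E)
  sigma_sq <- max(0, diag_omega_mean - mean_diag_sigma)
  b <- 0
  if (structure == "compound_symmetry" && E > 1L) {
    sum_omega <- sum(rowSums(R)^2) / N
    off_omega <- (sum_omega - sum(R^2) / N) / (E * (E - 1))
    b <- off_omega - mean_off_sigma
    b <- min(max(b, -sigma_sq / (E - 1) + 1e-10), sigma_sq)
  }
  list(beta = beta, sigma_sq = sigma_sq, b = b, N = N)
}

#' Permutation test of whole-network and edge-wise group differences
#'
#' Computes the observed whole-network statistic and all edge-wise
#' statistics, then rebuilds their null distributions by re-randomizing the
#' group labels (group sizes preserved). For every permutation the edge
#' effects and the heterogeneity component are re-estimated by the iterative
#' moment fit; the edge covariance estimates `Sigma_hat` are held fixed at
#' their observed-label values, pseudo-group 1 paired with the first group's
#' estimate and pseudo-group 2 with the second's. p-values use the add-one
#' convention `(1 + #\{perm >= obs\}) / (B + 1)`; with
#' `plan$exhaustive = TRUE` they are exact enumeration proportions.
#' Edge-wise p-values use each edge's own permutation distribution and are
#' FDR-adjusted with [fdr_adjust()].
#'
#' @param dataset A [connectivity_dataset()].
#' @param Sigma_hat_by_group List of two `E x E` covariance estimates, named
#'   by (or ordered as) the group levels.
#' @param structure Heterogeneity structure for all fits.
#' @param plan A [permutation_plan()].
#' @return An object of class `fc_test`: `network` (statistic, `p_perm`,
#'   `B`, `alpha`), `edges` (per-edge table with permutation and
#'   FDR-adjusted p-values), the two observed `fits`, and metadata recording
#'   that `Sigma_hat` was frozen under permutation.
#' @export
permutation_test <- function(dataset, Sigma_hat_by_group,
                             structure = c("scaled_identity",
                                           "compound_symmetry"),
                             plan = permutation_plan()) {
  structure <- match.arg(structure)
  stopifnot(inherits(dataset, "connectivity_dataset"),
            inherits(plan, "permutation_plan"))
  lv <- levels(dataset$groups)
  if (!is.null(names(Sigma_hat_by_group))) {
    Sigma_hat_by_group <- Sigma_hat_by_group[lv]
  }
  Sig1 <- as.matrix(Sigma_hat_by_group[[1L]])
  Sig2 <- as.matrix(Sigma_hat_by_group[[2L]])
  Y <- dataset$Y
  E <- ncol(Y)
  idx1 <- which(dataset$groups == lv[1L])
  idx2 <- which(dataset$groups == lv[2L])
  N1 <- length(idx1)
  N2 <- length(idx2)
  Ntot <- N1 + N2

  # observed fits via the full iterative algorithm
  fit1 <- fit_group(Y[idx1, , drop = FALSE], NULL, Sig1, structure,
                    store_omega = FALSE)
  fit2 <- fit_group(Y[idx2, , drop = FALSE], NULL, Sig2, structure,
                    store_omega = FALSE)

  # eigendecomposition of the psi-free part of the variance sum, fixed
  # across permutations because Sigma_hat and the group sizes are
  C0 <- Sig1 / N1 + Sig2 / N2
  eg <- eigen(C0, symmetric = TRUE)
  Q <- eg$vectors
  lam <- pmax(eg$values, 0)
  one_q <- colSums(Q)
  diag_c0 <- diag(Sig1) / N1 + diag(Sig2) / N2
  md1 <- mean(diag(Sig1))
  md2 <- mean(diag(Sig2))
  mo1 <- if (E > 1) (sum(Sig1) - sum(diag(Sig1))) / (E * (E - 1)) else 0
  mo2 <- if (E > 1) (sum(Sig2) - sum(diag(Sig2))) / (E * (E - 1)) else 0

  stat_for <- function(rows1) {
    g1 <- fast_group_fit(Y[rows1, , drop = FALSE], md1, mo1, structure)
    g2 <- fast_group_fit(Y[-rows1, , drop = FALSE], md2, mo2, structure)
    d <- g1$beta - g2$beta
    tt <- g1$sigma_sq / N1 + g2$sigma_sq / N2
    dq <- drop(crossprod(Q, d))
    w <- 1 / (lam + tt)
    net <- sum(dq^2 * w)
    if (structure == "compound_symmetry") {
      s <- g1$b / N1 + g2$b / N2
      if (s != 0) {
        a11 <- sum(one_q^2 * w)
        a1d <- sum(one_q * dq * w)
        net <- net - s * a1d^2 / (1 + s * a11)
      }
    }
    list(net = net, edge = d^2 / (diag_c0 + tt))
  }

  obs <- stat_for(idx1)
  if (plan$exhaustive) {
    combos <- utils::combn(Ntot, N1)
    B <- ncol(combos)
    perm_sets <- lapply(seq_len(B), function(c) combos[, c])
  } else {
    B <- plan$B
    if (!is.null(plan$seed)) set.seed(plan$seed)
    perm_sets <- lapply(seq_len(B), function(c) sample.int(Ntot, N1))
  }
  perm_net <- numeric(B)
  perm_edge_ge <- numeric(E)
  for (bb in seq_len(B)) {
    st <- stat_for(perm_sets[[bb]])
    perm_net[bb] <- st$net
    perm_edge_ge <- perm_edge_ge + (st$edge >= obs$edge)
  }
  if (plan$exhaustive) {
    p_net <- mean(perm_net >= obs$net)
    p_edge <- perm_edge_ge / B
  } else {
    p_net <- (1 + sum(perm_net >= obs$net)) / (B + 1)
    p_edge <- (1 + perm_edge_ge) / (B + 1)
  }
  pairs <- dataset$map$pairs
  edges <- data.frame(
    edge = seq_len(E),
    region_i = dataset$map$labels[pairs[, 1L]],
    region_j = dataset$map$labels[pairs[, 2L]],
    beta1 = as.numeric(fit1$beta_hat),
    beta2 = as.numeric(fit2$beta_hat),
    statistic = obs$edge,
    p_perm = p_edge,
    p_fdr = fdr_adjust(p_edge)
  )
  structure(
    list(
      network = list(statistic = obs$net, p_perm = p_net, B = B,
                     alpha = plan$alpha,
                     significant = p_net <= plan$alpha),
      edges = edges,
      fits = list(fit1, fit2),
      groups = lv,
      plan = plan,
      meta = list(
        psi_structure = structure,
        sigma_fixed_under_permutation = TRUE,
        exhaustive = plan$exhaustive,
        seed = plan$seed
      )
    ),
    class = "fc_test"
  )
}

#' @export
print.fc_test <- function(x, ...) {
  cat("<fc_test> network statistic =", signif(x$network$statistic, 5),
      " p_perm =", signif(x$network$p_perm, 4),
      " (B =", x$network$B, ")\n")
  n_sig <- sum(x$edges$p_perm <= x$network$alpha)
  n_fdr <- sum(x$edges$p_fdr <= x$network$alpha)
  cat("  edges with p_perm <=", x$network$alpha, ":", n_sig,
      "; after FDR:", n_fdr, "\n")
  invisible(x)
}
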