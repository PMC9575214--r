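#' Between-subject heterogeneity component
#'
#' The per-subject covariance deviation `psi` is either a scaled identity
#' (`sigma_sq * I`) or compound symmetry (diagonal `sigma_sq`, common
#' off-diagonal `b`). `b` is clamped so that `psi` stays positive
#' semidefinite.
#'
#' @param structure `"scaled_identity"` or `"compound_symmetry"`.
#' @param sigma_sq Diagonal component (>= 0).
#' @param b Off-diagonal component (0 for scaled identity).
#' @return An object of class `psi_model`.
#' @export
psi_model <- function(structure = c("scaled_identity", "compound_symmetry"),
                      sigma_sq = 0, b = 0) {
  structure <- match.arg(structure)
  stopifnot(sigma_sq >= 0)
  if (structure == "scaled_identity") b <- 0
  structure(list(structure = structure, sigma_sq = sigma_sq, b = b),
            class = "psi_model")
}

#' Realize a heterogeneity component as a dense matrix
#'
#' @param psi A [psi_model()].
#' @param E Edge count.
#' @return `E x E` matrix with diagonal `sigma_sq` and off-diagonal `b`.
#' @export
psi_matrix <- function(psi, E) {
  m <- matrix(psi$b, E, E)
  diag(m) <- psi$sigma_sq
  m
}

#' Generalized least squares estimate of the edge effects
#'
#' Under the subject-wise model `Y_n ~ MVN(X_n' beta, Sigma + psi)` with
#' independent subjects, the common edge-covariance weight cancels across
#' subjects and GLS reduces to `beta_hat = (X'X)^{-1} X' Y`, with
#' `var(vec beta_hat) = (X'X)^{-1} (x) (Sigma + psi)`. With the default
#' intercept-only design `beta_hat` is the vector of per-edge means and
#' `var_beta = (Sigma_hat + psi) / N`.
#'
#' @param Y `N x E` matrix of edge vectors for one group.
#' @param X Design matrix (`N x p`); `NULL` means intercept only.
#' @param Sigma_hat `E x E` edge covariance estimate.
#' @param psi A [psi_model()].
#' @return List with `beta_hat` (`p x E`), `var_beta` (`E x E`, returned for
#'   `p = 1`), `xtx_inv` (`p x p`).
#' @export
estimate_beta <- function(Y, X = NULL, Sigma_hat, psi) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (is.null(X)) X <- matrix(1, N, 1L)
  X <- as.matrix(X)
  stopifnot(nrow(X) == N)
  xtx <- crossprod(X)
  if (rcond(xtx) < 1e-12) {
    stop("singular design: X'X is not invertible", call. = FALSE)
  }
  xtx_inv <- solve(xtx)
  beta_hat <- xtx_inv %*% crossprod(X, Y)
  var_beta <- NULL
  if (ncol(X) == 1L) {
    var_beta <- (Sigma_hat + psi_matrix(psi, ncol(Y))) * drop(xtx_inv)
  }
  list(beta_hat = beta_hat, var_beta = var_beta, xtx_inv = xtx_inv)
}

#' Moment estimate of the heterogeneity component
#'
#' Forms the average residual outer product `Omega_hat = t(R) R / N` and
#' sets `sigma_sq` to the mean diagonal of `Omega_hat - Sigma_hat` (floored
#' at 0) and, for compound symmetry, `b` to the mean off-diagonal of the
#' same difference, clipped to keep `psi` positive semidefinite
#' (`-sigma_sq/(E-1) + eps <= b <= sigma_sq`).
#'
#' @param residuals `N x E` residual matrix of one group.
#' @param Sigma_hat `E x E` edge covariance estimate.
#' @param structure `"scaled_identity"` or `"compound_symmetry"`.
#' @return A [psi_model()].
#' @export
estimate_psi <- function(residuals,
                         Sigma_hat,
                         structure = c("scaled_identity",
                                       "compound_symmetry")) {
  structure <- match.arg(structure)
  R <- as.matrix(residuals)
  N <- nrow(R)
  if (N < 2L) stop("need at least 2 subjects to estimate psi", call. = FALSE)
  E <- ncol(R)
  diag_omega <- colSums(R^2) / N
  sigma_sq <- max(0, mean(diag_omega) - mean(diag(Sigma_hat)))
  b <- 0
  if (structure == "compound_symmetry" && E > 1L) {
    sum_omega <- sum(rowSums(R)^2) / N
    off_omega <- (sum_omega - sum(diag_omega)) / (E * (E - 1))
    off_sigma <- (sum(Sigma_hat) - sum(diag(Sigma_hat))) / (E * (E - 1))
    b <- off_omega - off_sigma
    b <- min(max(b, -sigma_sq / (E - 1) + 1e-10), sigma_sq)
  }
  psi_model(structure, sigma_sq, b)
}

#' Iterative fit of edge effects and heterogeneity for one group
#'
#' Starts from `psi = 0`, alternates the GLS effect estimate, residual
#' formation, and the moment update of `psi` until the maximum absolute
#' change in `(sigma_sq, b)` falls below `tol` or `max_iter` is reached.
#' With an intercept-only design `beta_hat` does not depend on `psi`, so the
#' iteration reaches a fixed point on the second pass.
#'
#' @param Y `N x E` matrix of edge vectors for the group.
#' @param X Design matrix or `NULL` (intercept only).
#' @param Sigma_hat `E x E` edge covariance estimate for the group.
#' @param structure Heterogeneity structure.
#' @param tol Convergence tolerance on `(sigma_sq, b)` (default `1e-6`).
#' @param max_iter Iteration cap (default 100).
#' @param store_omega Keep the dense residual covariance `Omega_hat` in the
#'   returned object (set `FALSE` in tight loops).
#' @return An object of class `group_fit` with `beta_hat`, `var_beta`,
#'   `psi`, `n_iterations`, `converged`, `N`, and optionally `Omega_hat`.
#' @export
fit_group <- function(Y, X = NULL, Sigma_hat,
                      structure = c("scaled_identity", "compound_symmetry"),
                      tol = 1e-6, max_iter = 100L, store_omega = TRUE) {
  structure <- match.arg(structure)
  Y <- as.matrix(Y)
  N <- nrow(Y)
  if (N < 2L) stop("need at least 2 subjects per group", call. = FALSE)
  if (is.null(X)) X <- matrix(1, N, 1L)
  psi <- psi_model(structure, 0, 0)
  converged <- FALSE
  n_iterations <- 0L
  fit <- NULL
  resid <- NULL
  for (it in seq_len(max_iter)) {
    n_iterations <- it
    fit <- estimate_beta(Y, X, Sigma_hat, psi)
    resid <- Y - X %*% fit$beta_hat
    psi_new <- estimate_psi(resid, Sigma_hat, structure)
    delta <- max(abs(psi_new$sigma_sq - psi$sigma_sq),
                 abs(psi_new$b - psi$b))
    psi <- psi_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  fit <- estimate_beta(Y, X, Sigma_hat, psi)
  out <- list(
    beta_hat = fit$beta_hat,
    var_beta = fit$var_beta,
    xtx_inv = fit$xtx_inv,
    psi = psi,
    n_iterations = n_iterations,
    converged = converged,
    N = N,
    E = ncol(Y)
  )
  if (store_omega) out$Omega_hat <- crossprod(resid) / N
  structure(out, class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat("<group_fit> N =", x$N, " E =", x$E,
      " psi:", x$psi$structure,
      " sigma_sq =", signif(x$psi$sigma_sq, 4),
      " b =", signif(x$psi$b, 4),
      " iterations =", x$n_iterations,
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}
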