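#' Residual cross-product summary for the edge covariance model
#'
#' From an `N x E` residual matrix computes `H0 = t(R) %*% R / (N - p)` and
#' its correlation standardization `H = D^{-1/2} H0 D^{-1/2}` with
#' `D = Diag(H0)`. `H` is the sufficient statistic consumed by the
#' Dirichlet-process edge covariance sampler.
#'
#' @param R Numeric `N x E` residual matrix (subjects in rows).
#' @param p Number of design columns removed when forming the residuals
#'   (default 1, the intercept).
#' @return An object of class `residual_summary` with fields `H0`, `H`,
#'   `N`, `p`.
#' @export
compute_residual_summary <- function(R, p = 1L) {
  R <- as.matrix(R)
  N <- nrow(R)
  if (N <= p) {
    stop("need more subjects than design columns (N = ", N, ", p = ", p, ")",
         call. = FALSE)
  }
  H0 <- crossprod(R) / (N - p)
  d <- diag(H0)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    stop("degenerate edge ", bad, ": zero residual variance", call. = FALSE)
  }
  inv_sd <- 1 / sqrt(d)
  H <- H0 * tcrossprod(inv_sd)
  diag(H) <- 1
  structure(list(H0 = H0, H = H, N = N, p = as.integer(p)),
            class = "residual_summary")
}

#' @export
print.residual_summary <- function(x, ...) {
  cat("<residual_summary> N =", x$N, " E =", ncol(x$H), " p =", x$p, "\n")
  invisible(x)
}
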