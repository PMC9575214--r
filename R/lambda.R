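#' Correlation factors of the edge correlation structure
#'
#' Bundles the between-structure correlation `rho0` with one within-cluster
#' correlation per occupied cluster.
#'
#' @param rho0 Correlation between edges not sharing a cluster.
#' @param rho_k Numeric vector, within-cluster correlation of each occupied
#'   cluster (k = 1..K).
#' @return An object of class `correlation_factors`.
#' @export
correlation_factors <- function(rho0, rho_k) {
  stopifnot(length(rho0) == 1L, is.numeric(rho0), is.numeric(rho_k))
  structure(list(rho0 = as.numeric(rho0), rho_k = as.numeric(rho_k)),
            class = "correlation_factors")
}

# Relabel a cluster assignment so labels are 1..K in order of first occurrence.
canonical_partition <- function(omega) {
  match(omega, unique(omega))
}

# Canonicalize labels and carry the per-cluster factors along with them.
canonicalize_labels <- function(omega, rho_k) {
  omega_in <- as.integer(omega)
  if (max(omega_in) > length(rho_k)) {
    stop("missing within-cluster correlation: need one rho_k per occupied ",
         "cluster", call. = FALSE)
  }
  canon <- canonical_partition(omega_in)
  K <- max(canon)
  out <- numeric(K)
  for (k in seq_len(K)) out[k] <- rho_k[omega_in[match(k, canon)]]
  list(omega = canon, rho_k = out)
}

# Edge block membership induced by a node partition: for each edge, the
# cluster containing both endpoints, or 0 for a "between" edge.
edge_blocks <- function(omega, map) {
  omega <- as.integer(omega)
  if (length(omega) != map$V) {
    stop("`omega` must assign a cluster to each of the ", map$V, " regions",
         call. = FALSE)
  }
  oi <- omega[map$pairs[, 1L]]
  oj <- omega[map$pairs[, 2L]]
  ifelse(oi == oj, oi, 0L)
}

# Closed-form spectral summary of Lambda = A + rho0 * J with A block
# equicorrelation over within-cluster edge sets. Returns positive
# definiteness, log-determinant, per-block inverse coefficients (a, b),
# the piecewise-constant vector u = A^{-1} 1 and s = sum(u).
# Blocks of a single edge carry no constraint from rho_k (the factor does
# not enter Lambda there) and are treated like between edges.
lambda_spectrum <- function(omega, rho, map) {
  st <- canonicalize_labels(omega, rho$rho_k)
  omega <- st$omega
  rho_k <- st$rho_k
  K <- max(omega)
  rho0 <- rho$rho0
  g <- edge_blocks(omega, map)
  E <- map$E
  n_b <- tabulate(g + 1L, nbins = K + 1L) # n_b[1] = between count
  # single-edge blocks behave like between edges
  single <- which(n_b[-1L] == 1L)
  if (length(single)) {
    g[g %in% single] <- 0L
    n_b <- tabulate(g + 1L, nbins = K + 1L)
  }
  n0 <- n_b[1L]
  pd <- TRUE
  logdetA <- 0
  a <- rep(NA_real_, K)
  b <- rep(NA_real_, K)
  u <- rep(1 / (1 - rho0), E)
  if (n0 > 0L && 1 - rho0 <= 0) pd <- FALSE
  if (pd) {
    logdetA <- if (n0 > 0L) n0 * log(1 - rho0) else 0
    s <- if (n0 > 0L) n0 / (1 - rho0) else 0
    for (k in seq_len(K)) {
      nk <- n_b[k + 1L]
      if (nk == 0L) next
      ck <- rho_k[k] - rho0
      d1 <- 1 - rho_k[k]
      lam2 <- d1 + nk * ck
      if (d1 <= 0 || lam2 <= 0) {
        pd <- FALSE
        break
      }
      logdetA <- logdetA + (nk - 1) * log(d1) + log(lam2)
      a[k] <- 1 / d1
      b[k] <- -ck / (d1 * lam2)
      u[g == k] <- 1 / lam2
      s <- s + nk / lam2
    }
  }
  if (!pd) {
    return(list(pd = FALSE))
  }
  denom <- 1 + rho0 * s
  if (denom <= 0) {
    return(list(pd = FALSE))
  }
  list(pd = TRUE, logdet = logdetA + log(denom), logdetA = logdetA,
       g = g, n_b = n_b, a = a, b = b, u = u, s = s, denom = denom,
       K = K, rho0 = rho0, rho_k = rho_k,
       omega = omega)
}

#' Build the edge correlation structure from a node partition
#'
#' The `E x E` matrix Lambda has unit diagonal; the entry for two distinct
#' edges is the within-cluster correlation `rho_k` when all four incident
#' regions lie in cluster k, and `rho0` otherwise. Positive definiteness is
#' checked in closed form (block equicorrelation eigenvalues plus the
#' rank-one between-structure term).
#'
#' @param omega Integer vector of cluster labels, one per region.
#' @param rho A [correlation_factors()] object (or list with `rho0`,
#'   `rho_k`).
#' @param map An [edge_index_map()].
#' @return An object of class `edge_corr_structure` carrying the dense
#'   matrix `Lambda` together with the generating partition and factors.
#' @export
build_lambda <- function(omega, rho, map) {
  stopifnot(inherits(map, "edge_index_map"))
  spec <- lambda_spectrum(omega, rho, map)
  if (!spec$pd) {
    stop("correlation factors do not yield a positive definite structure",
         call. = FALSE)
  }
  st <- canonicalize_labels(omega, rho$rho_k)
  omega <- st$omega
  rho_k <- st$rho_k
  g <- edge_blocks(omega, map)
  E <- map$E
  Lambda <- matrix(rho$rho0, E, E)
  for (k in seq_len(max(omega))) {
    idx <- which(g == k)
    if (length(idx) > 1L) Lambda[idx, idx] <- rho_k[k]
  }
  diag(Lambda) <- 1
  structure(
    list(Lambda = Lambda, omega = omega,
         rho = correlation_factors(rho$rho0, rho_k),
         map = map),
    class = "edge_corr_structure"
  )
}

#' @export
print.edge_corr_structure <- function(x, ...) {
  cat("<edge_corr_structure> E =", nrow(x$Lambda),
      " clusters =", max(x$omega), " rho0 =", x$rho$rho0, "\n")
  invisible(x)
}

#' Structured inverse and log-determinant of an edge correlation structure
#'
#' Writes Lambda = A + rho0 * 1 1' with A block equicorrelated over the
#' within-cluster edge sets, inverts A in closed form block by block, and
#' applies the Sherman-Morrison identity for the rank-one between-structure
#' term. The log-determinant comes from the same decomposition.
#'
#' @param lambda An `edge_corr_structure` from [build_lambda()].
#' @return A list with elements `inverse` (E x E) and `logdet`.
#' @export
structured_inverse_and_logdet <- function(lambda) {
  stopifnot(inherits(lambda, "edge_corr_structure"))
  spec <- lambda_spectrum(lambda$omega, lambda$rho, lambda$map)
  if (!spec$pd) {
    stop("structure is not positive definite", call. = FALSE)
  }
  E <- lambda$map$E
  rho0 <- spec$rho0
  Ainv <- diag(1 / (1 - rho0), E)
  for (k in seq_len(spec$K)) {
    idx <- which(spec$g == k)
    nk <- length(idx)
    if (nk == 0L) next
    Ainv[idx, idx] <- spec$b[k]
    diag(Ainv)[idx] <- spec$a[k] + spec$b[k]
  }
  inv <- Ainv
  if (rho0 != 0) {
    u <- spec$u # = A^{-1} 1, piecewise constant
    inv <- inv - (rho0 / spec$denom) * tcrossprod(u)
  }
  list(inverse = inv, logdet = spec$logdet)
}

# Gaussian likelihood term -N/2 * (log|Lambda| + tr(H Lambda^{-1})) evaluated
# through the closed-form block structure; -Inf when Lambda is not PD.
lambda_loglik_term <- function(Hmat, N, omega, rho, map) {
  spec <- lambda_spectrum(omega, rho, map)
  if (!spec$pd) {
    return(-Inf)
  }
  dH <- diag(Hmat)
  tr <- sum(dH[spec$g == 0L]) / (1 - spec$rho0)
  for (k in seq_len(spec$K)) {
    idx <- which(spec$g == k)
    if (length(idx) == 0L) next
    tr <- tr + spec$a[k] * sum(dH[idx]) + spec$b[k] * sum(Hmat[idx, idx])
  }
  if (spec$rho0 != 0) {
    q <- drop(crossprod(spec$u, Hmat %*% spec$u))
    tr <- tr - spec$rho0 * q / spec$denom
  }
  -N / 2 * (spec$logdet + tr)
}
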