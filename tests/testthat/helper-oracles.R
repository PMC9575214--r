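# Independent oracles used across the suite. Deliberately naive: literal
# loops, dense linear algebra, hand-rolled formulas — no calls into the
# package's own computational paths.

# Literal four-index builder of the edge correlation structure: entry for
# edges (i,j) and (i',j') is rho_k iff all four regions share cluster k,
# else rho0; diagonal 1.
brute_lambda <- function(omega, rho0, rho_k, map) {
  E <- map$E
  L <- matrix(NA_real_, E, E)
  for (e1 in seq_len(E)) {
    for (e2 in seq_len(E)) {
      if (e1 == e2) {
        L[e1, e2] <- 1
        next
      }
      i <- map$pairs[e1, 1]; j <- map$pairs[e1, 2]
      ip <- map$pairs[e2, 1]; jp <- map$pairs[e2, 2]
      same <- omega[i] == omega[j] && omega[j] == omega[ip] &&
        omega[ip] == omega[jp]
      L[e1, e2] <- if (same) rho_k[omega[i]] else rho0
    }
  }
  L
}

# All set partitions of 1..n as canonical label vectors (Bell(n) of them).
all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    K <- max(p)
    for (k in seq_len(K + 1)) out[[length(out) + 1]] <- c(p, k)
  }
  out
}

# Exact Chinese-restaurant-process probability of a canonical partition.
crp_probability <- function(omega, alpha) {
  m <- tabulate(omega)
  V <- length(omega)
  exp(length(m) * log(alpha) + sum(lgamma(m)) -
        sum(log(alpha + seq_len(V) - 1)))
}

# Dense-algebra likelihood term -N/2 (log|L| + tr(H L^{-1})) from the
# brute-force structure; -Inf when not PD.
dense_loglik <- function(Hmat, N, omega, rho0, rho_k, map) {
  L <- brute_lambda(omega, rho0, rho_k, map)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) return(-Inf)
  -N / 2 * (sum(log(ev)) + sum(diag(Hmat %*% solve(L))))
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}

# Hand-rolled Benjamini-Hochberg step-up adjusted p-values.
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Literal GLS on the stacked NE x pE Kronecker system with subject-wise
# weight W = I_N (x) (Sigma + Psi).
dense_gls <- function(Y, X, Sigma, Psi) {
  N <- nrow(Y); E <- ncol(Y); p <- ncol(X)
  W <- kronecker(diag(N), Sigma + Psi)
  Xfull <- kronecker(X, diag(E))
  y <- as.numeric(t(Y)) # subject-major stacking
  Winv <- solve(W)
  A <- t(Xfull) %*% Winv %*% Xfull
  beta <- solve(A, t(Xfull) %*% Winv %*% y)
  list(beta = matrix(beta, p, E, byrow = TRUE), var = solve(A))
}

# Batch-means standard error for autocorrelated chains.
batch_se <- function(x, n_batch = 40) {
  b <- floor(length(x) / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]),
                  numeric(1))
  sd(means) / sqrt(n_batch)
}

# Random partition of V nodes plus correlation factors kept inside the
# positive definite region (checked with dense eigenvalues of the
# brute-force structure).
random_valid_state <- function(V, map, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    K <- sample(1:min(4, V), 1)
    omega <- sample(K, V, replace = TRUE)
    omega <- match(omega, unique(omega))
    K <- max(omega)
    rho0 <- runif(1, -0.05, 0.15)
    rho_k <- runif(K, -0.1, 0.7)
    L <- brute_lambda(omega, rho0, rho_k, map)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    # validity is defined through the decomposition L = A + rho0 J: both
    # the block part A and the rank-one correction must behave (dense check)
    A <- L - rho0 * matrix(1, nrow(L), ncol(L))
    evA <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    denom <- 1 + rho0 * sum(solve(A, rep(1, nrow(A))))
    if (min(ev) > 1e-6 && min(evA) > 1e-6 && denom > 1e-6) {
      return(list(omega = omega, rho0 = rho0, rho_k = rho_k, Lambda = L))
    }
  }
  stop("could not draw a valid state")
}

# Simulated residual summary with a known block structure.
make_H_fixture <- function(V, omega, rho0, rho_k, N, seed = 1) {
  set.seed(seed)
  map <- edge_index_map(V)
  L <- brute_lambda(omega, rho0, rho_k, map)
  eg <- eigen(L, symmetric = TRUE)
  Z <- matrix(rnorm(N * map$E), map$E, N)
  Y <- t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * Z))
  R <- sweep(Y, 2, colMeans(Y))
  list(H = compute_residual_summary(R, 1), map = map, Lambda = L)
}
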