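#' Number of edges in a fully connected network of V regions
#'
#' Each unordered pair of distinct regions contributes one edge, so a network
#' on `V` nodes has `V * (V - 1) / 2` edges (435 for V = 30, 190 for V = 20).
#'
#' @param V Number of regions (a single integer, at least 2).
#' @return Integer edge count.
#' @examples
#' edge_count(30) # 435
#' edge_count(20) # 190
#' @export
edge_count <- function(V) {
  if (length(V) != 1L || !is.numeric(V) || !is.finite(V) || V != round(V)) {
    stop("`V` must be a single finite integer", call. = FALSE)
  }
  if (V < 2) {
    stop("invalid region count: need V >= 2, got ", V, call. = FALSE)
  }
  as.integer(round(V * (V - 1) / 2))
}

#' Fisher z transform of a correlation
#'
#' Variance-stabilizing transform `atanh(r)` used as the connectivity metric.
#' The inverse is [fisher_z_inv()].
#'
#' @param r Correlation values, all strictly inside (-1, 1).
#' @return `atanh(r)`, same shape as `r`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z is defined only for |r| < 1", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z values.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Edge index map between region pairs and edge positions
#'
#' Fixes the ordering used everywhere in the package: edges are the pairs
#' (i, j), i < j, listed lexicographically — (1,2), (1,3), ..., (1,V),
#' (2,3), ... (row-major reading of the upper triangle). The map is a
#' bijection between pair and position, stable across runs.
#'
#' @param V Number of regions.
#' @param labels Optional character vector of unique region names (length `V`).
#' @return An object of class `edge_index_map` with fields `V`, `E`,
#'   `pairs` (E x 2 integer matrix, 1-based), `labels`, and a `V x V`
#'   lookup matrix `index`.
#' @export
edge_index_map <- function(V, labels = NULL) {
  E <- edge_count(V)
  if (is.null(labels)) {
    labels <- sprintf("R%02d", seq_len(V))
  }
  labels <- as.character(labels)
  if (length(labels) != V || anyDuplicated(labels)) {
    stop("`labels` must be ", V, " unique region names", call. = FALSE)
  }
  i <- rep.int(seq_len(V - 1L), times = (V - 1L):1L)
  j <- sequence((V - 1L):1L) + i
  pairs <- cbind(i = as.integer(i), j = as.integer(j))
  index <- matrix(0L, V, V)
  index[pairs] <- seq_len(E)
  index[pairs[, 2:1, drop = FALSE]] <- seq_len(E)
  structure(
    list(V = as.integer(V), E = E, pairs = pairs, labels = labels,
         index = index),
    class = "edge_index_map"
  )
}

#' @export
print.edge_index_map <- function(x, ...) {
  cat("<edge_index_map> V =", x$V, " E =", x$E, "\n")
  invisible(x)
}

#' Look up the edge position of a region pair
#'
#' @param map An [edge_index_map()].
#' @param i,j Region indices (order irrelevant, `i != j`).
#' @return Edge position in 1..E.
#' @export
edge_index <- function(map, i, j) {
  stopifnot(inherits(map, "edge_index_map"))
  if (any(i == j)) stop("no self edges: i must differ from j", call. = FALSE)
  map$index[cbind(i, j)]
}

#' Region pair of an edge position
#'
#' @param map An [edge_index_map()].
#' @param e Edge positions in 1..E.
#' @return Integer matrix with columns `i`, `j` (i < j).
#' @export
edge_pair <- function(map, e) {
  stopifnot(inherits(map, "edge_index_map"))
  map$pairs[e, , drop = FALSE]
}

#' Vectorize a symmetric connectivity matrix into an edge vector
#'
#' Extracts the off-diagonal entries in the ordering of the supplied
#' [edge_index_map()]. Input asymmetry up to `tol` is repaired by averaging
#' `M` and `t(M)`; larger asymmetry is an error. The diagonal is ignored.
#'
#' @param m Square numeric matrix of Fisher z connectivities.
#' @param map An [edge_index_map()] with `map$V == nrow(m)`.
#' @param tol Asymmetry tolerance (default `1e-8`).
#' @return Numeric vector of length `map$E`.
#' @seealso [devectorize_connectivity()]
#' @export
vectorize_connectivity <- function(m, map, tol = 1e-8) {
  stopifnot(inherits(map, "edge_index_map"))
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || nrow(m) != map$V) {
    stop("matrix must be ", map$V, " x ", map$V, ", got ",
         nrow(m), " x ", ncol(m), call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop("connectivity matrix is asymmetric beyond tolerance (max |M - t(M)| = ",
         format(asym), ")", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  unname(m[map$pairs])
}

#' Rebuild a symmetric connectivity matrix from an edge vector
#'
#' Inverse of [vectorize_connectivity()] on the off-diagonal; the diagonal is
#' set to 0 by convention and never consumed downstream.
#'
#' @param y Numeric edge vector of length `map$E`.
#' @param map An [edge_index_map()].
#' @return A `V x V` symmetric matrix with zero diagonal.
#' @export
devectorize_connectivity <- function(y, map) {
  stopifnot(inherits(map, "edge_index_map"))
  if (length(y) != map$E) {
    stop("edge vector must have length ", map$E, call. = FALSE)
  }
  m <- matrix(0, map$V, map$V, dimnames = list(map$labels, map$labels))
  m[map$pairs] <- y
  m[map$pairs[, 2:1, drop = FALSE]] <- y
  m
}

#' Fisher z connectivity matrix from a region-by-time series table
#'
#' Computes the Pearson correlation between every pair of region time series
#' and applies the Fisher z transform. The diagonal is stored as 0.
#'
#' @param x Numeric matrix, regions in rows and time points in columns.
#' @return A symmetric `V x V` Fisher z connectivity matrix.
#' @export
ts_to_connectivity <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3 || ncol(x) < 3) {
    stop("need at least 3 regions and 3 time points", call. = FALSE)
  }
  r <- stats::cor(t(x))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- 0
  (z + t(z)) / 2
}

#' Assemble a two-group connectivity dataset
#'
#' Bundles the `N x E` matrix of per-subject edge vectors with a two-level
#' group label per subject. Columns of `Y` must follow the ordering of an
#' [edge_index_map()]; an intercept-only design is implied (each group's edge
#' means are fitted separately).
#'
#' @param Y Numeric `N x E` matrix of Fisher z edge vectors, one row per
#'   subject.
#' @param groups Group label per subject; must take exactly two values, each
#'   with at least 2 subjects.
#' @param map Optional [edge_index_map()] consistent with `ncol(Y)`.
#' @param subject_ids Optional subject identifiers (default `S1..SN`).
#' @return An object of class `connectivity_dataset`.
#' @export
connectivity_dataset <- function(Y, groups, map = NULL, subject_ids = NULL) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  if (nrow(Y) != length(groups)) {
    stop("`groups` must have one label per row of Y", call. = FALSE)
  }
  if (nlevels(groups) != 2L) {
    stop("`groups` must have exactly two levels, got ",
         nlevels(groups), call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  if (is.null(map)) {
    V <- v_from_edge_count(ncol(Y))
    map <- edge_index_map(V)
  } else {
    stopifnot(inherits(map, "edge_index_map"))
    if (map$E != ncol(Y)) {
      stop("ncol(Y) = ", ncol(Y), " does not match map$E = ", map$E,
           call. = FALSE)
    }
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%d", seq_len(nrow(Y)))
  structure(
    list(Y = Y, groups = groups, map = map,
         subject_ids = as.character(subject_ids)),
    class = "connectivity_dataset"
  )
}

#' @export
print.connectivity_dataset <- function(x, ...) {
  cat("<connectivity_dataset> N =", nrow(x$Y), " V =", x$map$V,
      " E =", x$map$E, "\n")
  print(table(x$groups))
  invisible(x)
}

# Recover V from an edge count; errors if E is not a triangular number.
v_from_edge_count <- function(E) {
  V <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(V - round(V)) > 1e-9) {
    stop("column count ", E, " is not V*(V-1)/2 for any integer V",
         call. = FALSE)
  }
  as.integer(round(V))
}
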