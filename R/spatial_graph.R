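#' Build the k-nearest-neighbour spatial graph of spots
#'
#' Connects every spot to its `k_neighbors` nearest neighbours by Euclidean
#' distance between spatial coordinates. The directed KNN relation is
#' symmetrized with an elementwise maximum (keeping every KNN edge), and each
#' edge gets weight `exp(-d / dbar)` where `dbar` is the mean KNN edge
#' distance — so weights fall off exponentially with distance but are
#' invariant to the coordinate units (pixels, microns, grid indices).
#'
#' @param coords n x 2 matrix of spot coordinates, or an [st_dataset()].
#' @param k_neighbors Neighbours per spot (default 6, the usual choice for
#'   Visium-style hexagonal packings). Values `>= n` are clipped to `n - 1`
#'   with a warning.
#' @return An object of class `"spatial_graph"`: list with the spot count
#'   `n`, sparse symmetric weight matrix `W` (zero diagonal), degree vector
#'   `degree`, sparse Laplacian `L = D - W`, the distance scale `dbar`, and
#'   `k_neighbors`.
#' @details Ties in neighbour distance are broken by spot index so the graph
#'   is deterministic. Duplicated coordinates are allowed: distance 0 gives
#'   edge weight 1.
#' @examples
#' g <- build_spatial_graph(cbind(rep(1:5, 5), rep(1:5, each = 5)), k_neighbors = 4)
#' range(Matrix::rowSums(g$L)) # rows of a Laplacian sum to zero
#' @export
build_spatial_graph <- function(coords, k_neighbors = 6) {
  if (inherits(coords, "st_dataset")) coords <- coords$coords
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least two spots to build a graph")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k_neighbors < 1) stop("'k_neighbors' must be >= 1")
  if (k_neighbors >= n) {
    warning("k_neighbors >= number of spots; clipped to ", n - 1L)
    k_neighbors <- n - 1L
  }
  d <- as.matrix(stats::dist(coords))
  # k nearest per row, self excluded, distance ties broken by spot index
  nn_i <- integer(n * k_neighbors)
  nn_j <- integer(n * k_neighbors)
  nn_d <- numeric(n * k_neighbors)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n), method = "radix")
    ord <- ord[ord != i][seq_len(k_neighbors)]
    sl <- ((i - 1L) * k_neighbors + 1L):(i * k_neighbors)
    nn_i[sl] <- i
    nn_j[sl] <- ord
    nn_d[sl] <- d[i, ord]
  }
  dbar <- mean(nn_d)
  if (dbar == 0) dbar <- 1 # all spots coincide; weights all exp(0) = 1
  w <- exp(-nn_d / dbar)
  A <- Matrix::sparseMatrix(i = nn_i, j = nn_j, x = w, dims = c(n, n))
  W <- pmax_sparse(A, Matrix::t(A))
  graph_from_weights(W, dbar = dbar, k_neighbors = k_neighbors)
}

# Elementwise max of two nonnegative sparse matrices.
pmax_sparse <- function(a, b) {
  # (a + b + |a - b|) / 2, computed sparsely
  (a + b + abs(a - b)) / 2
}

graph_from_weights <- function(W, dbar = NA_real_, k_neighbors = NA_integer_) {
  W <- methods::as(W, "generalMatrix")
  deg <- Matrix::rowSums(W)
  L <- Matrix::Diagonal(x = deg) - W
  structure(list(n = nrow(W), W = W, degree = deg, L = L, dbar = dbar,
                 k_neighbors = k_neighbors),
            class = "spatial_graph")
}

#' Graph Laplacian of a symmetric weight matrix
#'
#' `L = D - W`, the unnormalized combinatorial Laplacian, with the degree
#' matrix `D` holding the row sums of `W` on its diagonal.
#'
#' @param W Symmetric nonnegative weight matrix with zero diagonal (dense or
#'   sparse), or a `"spatial_graph"`.
#' @return Sparse Laplacian matrix of the same dimension.
#' @export
laplacian <- function(W) {
  if (inherits(W, "spatial_graph")) return(W$L)
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  if (!Matrix::isSymmetric(W, tol = 0))
    stop("'W' must be exactly symmetric")
  if (any(W@x < 0)) stop("'W' must be nonnegative")
  if (any(Matrix::diag(W) != 0)) stop("'W' must have a zero diagonal")
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Laplacian quadratic form of a latent matrix
#'
#' `Tr(Z' L Z)`, the smoothness penalty used to keep latent spot codes close
#' for spatially neighbouring spots. Equals
#' `0.5 * sum_ij W_ij * ||z_i - z_j||^2`, so it is nonnegative and vanishes
#' exactly when `Z` is constant on every connected component.
#'
#' @param Z n x k matrix of per-spot latent rows.
#' @param L Laplacian matrix (or a `"spatial_graph"`).
#' @return Nonnegative scalar.
#' @export
laplacian_quadratic <- function(Z, L) {
  if (inherits(L, "spatial_graph")) L <- L$L
  Z <- as.matrix(Z)
  if (nrow(Z) != nrow(L))
    stop("row count of 'Z' (", nrow(Z), ") does not match Laplacian dimension (",
         nrow(L), ")")
  sum(Z * as.matrix(L %*% Z))
}

#' Write a spatial graph as an edge list
#'
#' Tab-separated file with columns `i`, `j`, `weight`, one row per stored
#' (directed) nonzero; the matrix is symmetric so each undirected edge
#' appears twice.
#'
#' @param graph A `"spatial_graph"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  tr <- Matrix::mat2triplet(graph$W)
  utils::write.table(data.frame(i = tr$i, j = tr$j, weight = tr$x),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("Spatial KNN graph: ", x$n, " spots, ",
      Matrix::nnzero(x$W) / 2, " undirected edges",
      if (!is.na(x$k_neighbors)) paste0(" (k = ", x$k_neighbors, ")"), "\n",
      sep = "")
  invisible(x)
}
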