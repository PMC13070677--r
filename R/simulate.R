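#' Generate a synthetic labeled single-cell reference
#'
#' Negative-binomial counts with a planted marker structure: every cell type
#' owns a disjoint block of `n_markers_per_type` marker genes whose mean is
#' `fold` times the baseline. Non-marker genes are exchangeable across types.
#' This gives a fully controlled stand-in for a real annotated scRNA-seq
#' reference, so the whole deconvolution pipeline can be exercised and scored
#' against known truth without any external download.
#'
#' @param k Number of cell types.
#' @param n_per_type Cells simulated per type.
#' @param ng Total number of genes; must satisfy `k * n_markers_per_type <= ng`.
#' @param n_markers_per_type Marker genes per type (default 20).
#' @param fold Mean fold-change of a type's markers over baseline (default 10;
#'   `fold = 1` removes all signal).
#' @param mu Baseline negative-binomial mean (default 1).
#' @param size Negative-binomial dispersion parameter `r` (default 2; smaller
#'   is noisier).
#' @param seed Integer seed; the output is bit-reproducible given the seed.
#' @return A [labeled_reference()] with `k * n_per_type` cells. Type `t`'s
#'   marker block is genes `((t-1) * n_markers_per_type + 1) : (t *
#'   n_markers_per_type)`; gene ids are `gene_0001, ...`, types `type_1, ...`.
#' @examples
#' ref <- generate_reference(k = 3, n_per_type = 20, ng = 60, seed = 7)
#' table(ref$labels)
#' @export
generate_reference <- function(k = 4, n_per_type = 200, ng = 200,
                               n_markers_per_type = 20, fold = 10,
                               mu = 1, size = 2, seed = NULL) {
  if (k < 1 || n_per_type < 1 || ng < 1) stop("k, n_per_type, ng must be >= 1")
  if (k * n_markers_per_type > ng)
    stop("k * n_markers_per_type exceeds the number of genes")
  if (fold < 1) stop("'fold' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_cells <- k * n_per_type
  type_names <- paste0("type_", seq_len(k))
  labels <- rep(type_names, each = n_per_type)
  means <- matrix(mu, nrow = k, ncol = ng)
  for (t in seq_len(k)) {
    block <- ((t - 1L) * n_markers_per_type + 1L):(t * n_markers_per_type)
    means[t, block] <- mu * fold
  }
  counts <- matrix(0, nrow = n_cells, ncol = ng,
                   dimnames = list(paste0("cell_", seq_len(n_cells)),
                                   sprintf("gene_%04d", seq_len(ng))))
  for (t in seq_len(k)) {
    rows <- which(labels == type_names[t])
    counts[rows, ] <- stats::rnbinom(length(rows) * ng, size = size,
                                     mu = rep(means[t, ], each = length(rows)))
  }
  labeled_reference(counts, labels, type_names)
}

#' Marker gene blocks of a generated reference
#'
#' Convenience accessor giving, for each type of a [generate_reference()]
#' output layout, the gene ids of its marker block.
#'
#' @param k,ng,n_markers_per_type The values passed to [generate_reference()].
#' @return Named list of character vectors, one per type.
#' @export
marker_blocks <- function(k = 4, ng = 200, n_markers_per_type = 20) {
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  out <- lapply(seq_len(k), function(t)
    gene_ids[((t - 1L) * n_markers_per_type + 1L):(t * n_markers_per_type)])
  names(out) <- paste0("type_", seq_len(k))
  out
}

#' Simulate pseudo-spots with known cell-type proportions
#'
#' Aggregates labeled single cells into spots on a regular grid. The grid is
#' partitioned into contiguous spatial domains (`"stripes"` slices the grid
#' along y; `"blocks"` makes a checkerboard of rectangular patches), each
#' domain dominated by one cell type assigned round-robin. A spot's intended
#' composition is drawn from a Dirichlet centred on its domain's dominant
#' type (concentration `purity` on the dominant type, 1 on the rest);
#' `cells_per_spot` cells are then sampled with replacement according to that
#' composition and their count vectors summed. The recorded ground truth is
#' the *realized* sampled-cell fraction, so the proportion matrix is exactly
#' consistent with the aggregated expression.
#'
#' @param ref A [labeled_reference()].
#' @param grid Integer vector `c(rows, cols)`; spots sit at integer grid
#'   coordinates (x = column, y = row).
#' @param cells_per_spot Cells aggregated per spot: a single integer or a
#'   length-2 range sampled uniformly per spot (default 10, a typical
#'   Visium-scale spot occupancy).
#' @param domain_layout `"stripes"` (default) or `"blocks"`.
#' @param n_domains Number of spatial domains (default: number of types).
#' @param purity Dirichlet concentration on the dominant type (default 5).
#'   `Inf` gives one-hot compositions (every spot purely its domain type).
#' @param seed Integer seed; same seed gives a bit-identical dataset.
#' @param keep_cells Record the sampled cell ids per spot (attribute
#'   `"cells"` on the result), mainly for auditing.
#' @return A [sim_st()]: pseudo-spot counts + coordinates, the realized
#'   proportion matrix, the type names, and provenance (seed, parameters).
#' @examples
#' ref <- generate_reference(k = 3, n_per_type = 30, ng = 60, seed = 1)
#' sim <- simulate_spots(ref, grid = c(6, 5), seed = 2)
#' rowSums(sim$proportions)[1:3]
#' @export
simulate_spots <- function(ref, grid = c(20, 10), cells_per_spot = 10,
                           domain_layout = c("stripes", "blocks"),
                           n_domains = NULL, purity = 5, seed = NULL,
                           keep_cells = FALSE) {
  stopifnot(inherits(ref, "labeled_reference"))
  domain_layout <- match.arg(domain_layout)
  if (length(grid) != 2L || any(grid < 1)) stop("'grid' must be c(rows, cols), both >= 1")
  if (any(cells_per_spot < 1)) stop("'cells_per_spot' must be >= 1")
  if (purity <= 0) stop("'purity' must be positive")
  k <- length(ref$type_names)
  if (is.null(n_domains)) n_domains <- k
  if (!is.null(seed)) set.seed(seed)

  nrow_g <- as.integer(grid[1]); ncol_g <- as.integer(grid[2])
  ns <- nrow_g * ncol_g
  gy <- rep(seq_len(nrow_g), each = ncol_g)
  gx <- rep(seq_len(ncol_g), times = nrow_g)
  domain <- switch(domain_layout,
    stripes = cut_index(gy, nrow_g, n_domains),
    blocks  = {
      side <- ceiling(sqrt(n_domains))
      by <- cut_index(gy, nrow_g, side)
      bx <- cut_index(gx, ncol_g, ceiling(n_domains / side))
      pmin((by - 1L) * ceiling(n_domains / side) + bx, n_domains)
    })
  dominant <- ((seq_len(n_domains) - 1L) %% k) + 1L

  cps <- if (length(cells_per_spot) == 2L)
    sample(seq(cells_per_spot[1], cells_per_spot[2]), ns, replace = TRUE)
  else rep(as.integer(cells_per_spot), ns)

  cells_by_type <- split(seq_len(nrow(ref$counts)),
                         factor(ref$labels, levels = ref$type_names))
  X <- matrix(0, nrow = ns, ncol = ncol(ref$counts),
              dimnames = list(sprintf("spot_%04d", seq_len(ns)),
                              colnames(ref$counts)))
  P <- matrix(0, nrow = ns, ncol = k,
              dimnames = list(rownames(X), ref$type_names))
  picked <- if (keep_cells) vector("list", ns)
  for (s in seq_len(ns)) {
    dom_type <- dominant[domain[s]]
    if (is.finite(purity)) {
      conc <- rep(1, k); conc[dom_type] <- purity
      p <- rdirichlet1(conc)
    } else {
      p <- numeric(k); p[dom_type] <- 1
    }
    n_by_type <- stats::rmultinom(1, cps[s], p)[, 1]
    ids <- integer(0)
    for (t in which(n_by_type > 0)) {
      pool <- cells_by_type[[t]]
      ids <- c(ids, pool[sample.int(length(pool), n_by_type[t], replace = TRUE)])
    }
    X[s, ] <- colSums(ref$counts[ids, , drop = FALSE])
    P[s, ] <- n_by_type / cps[s]
    if (keep_cells) picked[[s]] <- rownames(ref$counts)[ids]
  }
  st <- st_dataset(X, cbind(x = gx, y = gy), layer = "counts")
  out <- sim_st(st, P, ref$type_names,
                provenance = list(seed = seed, grid = grid,
                                  cells_per_spot = cells_per_spot,
                                  domain_layout = domain_layout,
                                  n_domains = n_domains, purity = purity))
  if (keep_cells) attr(out, "cells") <- picked
  out
}

# Partition positions 1..n into m near-equal contiguous bins.
cut_index <- function(pos, n, m) {
  pmin(ceiling(pos * m / n), m)
}

# One Dirichlet draw via normalized gammas.
rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) == 0) g[which.max(conc)] <- 1 # numerically degenerate draw
  g / sum(g)
}
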