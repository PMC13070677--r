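#' Per-cell-type Pearson correlation of proportion matrices
#'
#' For each cell type, the Pearson correlation across spots between predicted
#' and true proportions; the conventional single-number summary is the mean
#' (and standard deviation) over cell types. A type whose predicted or true
#' column is constant has no defined correlation and is scored 0 with a
#' warning.
#'
#' @param p_hat,p_true Spot-by-type matrices of identical shape (>= 2 spots).
#' @return List with `per_type` (named length-k vector), `mean` and `sd`.
#' @examples
#' p <- rbind(c(.7, .3), c(.2, .8), c(.5, .5))
#' pcc_per_celltype(p, p)$per_type
#' @export
pcc_per_celltype <- function(p_hat, p_true) {
  m <- check_pair(p_hat, p_true)
  if (nrow(m$a) < 2L) stop("need at least two spots")
  k <- ncol(m$a)
  out <- numeric(k)
  for (j in seq_len(k)) {
    if (stats::sd(m$a[, j]) == 0 || stats::sd(m$b[, j]) == 0) {
      warning("zero-variance proportion column (type ", j, "); PCC scored 0")
      out[j] <- 0
    } else out[j] <- stats::cor(m$a[, j], m$b[, j])
  }
  names(out) <- colnames(m$b)
  list(per_type = out, mean = mean(out), sd = stats::sd(out))
}

#' Root-mean-square error between proportion matrices
#'
#' Square root of the mean squared entrywise difference, pooled over all
#' `ns * k` entries.
#'
#' @inheritParams pcc_per_celltype
#' @return Nonnegative scalar.
#' @export
rmse <- function(p_hat, p_true) {
  m <- check_pair(p_hat, p_true)
  sqrt(mean((m$a - m$b)^2))
}

#' Frobenius distance between proportion matrices
#'
#' `sqrt(sum((p_hat - p_true)^2))`; identical to `rmse * sqrt(ns * k)`.
#'
#' @inheritParams pcc_per_celltype
#' @return Nonnegative scalar.
#' @export
frobenius_distance <- function(p_hat, p_true) {
  m <- check_pair(p_hat, p_true)
  sqrt(sum((m$a - m$b)^2))
}

#' Per-spot Jensen-Shannon divergence
#'
#' For each spot, `JSD(p, q) = KL(p, m)/2 + KL(q, m)/2` with `m = (p + q)/2`,
#' between the predicted and true composition. Bounded by `log(2)` under the
#' natural logarithm (the default), attained only on disjoint supports.
#' Rows off the simplex by more than `1e-6` are renormalized with a warning.
#'
#' @inheritParams pcc_per_celltype
#' @param base `"nat"` (natural log, default) or `"log2"`.
#' @return List with `per_spot` (length-ns vector) and `mean`.
#' @export
jsd_per_spot <- function(p_hat, p_true, base = c("nat", "log2")) {
  base <- match.arg(base)
  m <- check_pair(p_hat, p_true)
  a <- simplex_rows(m$a, "p_hat")
  b <- simplex_rows(m$b, "p_true")
  mid <- (a + b) / 2
  kl_term <- function(p, q) {
    x <- p * (log(p) - log(q))
    x[p == 0] <- 0
    rowSums(x)
  }
  out <- kl_term(a, mid) / 2 + kl_term(b, mid) / 2
  out <- pmax(out, 0) # guard tiny negative rounding
  if (base == "log2") out <- out / log(2)
  list(per_spot = out, mean = mean(out))
}

simplex_rows <- function(p, label) {
  if (any(p < 0)) stop("'", label, "' has negative entries")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > 1e-6))
    warning("rows of '", label, "' renormalized to sum to 1")
  p / rs
}

#' Per-cell-type structural similarity of spatial proportion fields
#'
#' Rasterizes each type's proportion field onto the spot lattice (coordinates
#' rounded to the nearest lattice point; the lattice step per axis is the
#' smallest positive gap between sorted unique coordinates), min-max scales
#' each image to `[0, 1]`, and computes the standard SSIM with a Gaussian
#' window (`sigma = 1.5`, 11 x 11, reflective borders) and constants
#' `C1 = 0.01^2`, `C2 = 0.03^2` on data range 1. A constant image min-max
#' scales to all zeros, so two constant fields score 1.
#'
#' @inheritParams pcc_per_celltype
#' @param coords Spot coordinates (n x 2) on, or near, a regular grid.
#' @return Named length-k vector of SSIM values in `[-1, 1]`.
#' @export
ssim_per_celltype <- function(p_hat, p_true, coords) {
  m <- check_pair(p_hat, p_true)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(m$a)) stop("coordinate rows do not match spots")
  idx <- lattice_index(coords)
  k <- ncol(m$a)
  out <- numeric(k)
  for (j in seq_len(k)) {
    img_a <- rasterize_field(m$a[, j], idx)
    img_b <- rasterize_field(m$b[, j], idx)
    out[j] <- ssim_image(minmax01(img_a), minmax01(img_b))
  }
  names(out) <- colnames(m$b)
  out
}

lattice_index <- function(coords) {
  axis_index <- function(v) {
    u <- sort(unique(v))
    step <- if (length(u) > 1) min(diff(u)) else 1
    round((v - min(v)) / step) + 1L
  }
  ix <- axis_index(coords[, 1])
  iy <- axis_index(coords[, 2])
  if (anyDuplicated(cbind(ix, iy)))
    stop("multiple spots collapse onto one raster cell; use finer coordinates")
  list(ix = ix, iy = iy, nx = max(ix), ny = max(iy))
}

rasterize_field <- function(values, idx) {
  img <- matrix(0, nrow = idx$ny, ncol = idx$nx)
  img[cbind(idx$iy, idx$ix)] <- values
  img
}

minmax01 <- function(img) {
  rng <- range(img)
  if (rng[2] == rng[1]) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

# Gaussian-windowed SSIM between two images with values in [0, 1].
ssim_image <- function(a, b, sigma = 1.5, radius = 5L,
                       c1 = 0.01^2, c2 = 0.03^2) {
  stopifnot(all(dim(a) == dim(b)))
  g <- gaussian_filter2(cbind_layers(a, b, a * a, b * b, a * b),
                        sigma, radius, dim(a))
  ua <- g[[1]]; ub <- g[[2]]
  va <- g[[3]] - ua^2
  vb <- g[[4]] - ub^2
  vab <- g[[5]] - ua * ub
  s <- ((2 * ua * ub + c1) * (2 * vab + c2)) /
       ((ua^2 + ub^2 + c1) * (va + vb + c2))
  # ignore the window-radius border, as the reference formulation does,
  # unless the image is too small to have an interior
  ny <- nrow(s); nx <- ncol(s)
  if (ny > 2 * radius && nx > 2 * radius)
    s <- s[(radius + 1):(ny - radius), (radius + 1):(nx - radius), drop = FALSE]
  mean(s)
}

cbind_layers <- function(...) list(...)

# Separable Gaussian filtering with reflective padding of a list of images.
gaussian_filter2 <- function(layers, sigma, radius, dm) {
  x <- (-radius):radius
  w <- exp(-x^2 / (2 * sigma^2))
  w <- w / sum(w)
  reflect_idx <- function(n) {
    # scipy-style 'reflect' (mirror including the edge pixel)
    i <- c(rev(seq_len(radius)), seq_len(n), n - seq_len(radius) + 1L)
    pmin(pmax(i, 1L), n)
  }
  ri <- reflect_idx(dm[1]); ci <- reflect_idx(dm[2])
  filt <- function(img) {
    p <- img[ri, ci, drop = FALSE]
    # rows
    out <- matrix(0, nrow(p) - 2 * radius, ncol(p))
    for (s in -radius:radius)
      out <- out + w[s + radius + 1] *
        p[(radius + 1 + s):(nrow(p) - radius + s), , drop = FALSE]
    # cols
    out2 <- matrix(0, nrow(out), ncol(p) - 2 * radius)
    for (s in -radius:radius)
      out2 <- out2 + w[s + radius + 1] *
        out[, (radius + 1 + s):(ncol(p) - radius + s), drop = FALSE]
    out2
  }
  lapply(layers, filt)
}

#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions, adjusted for chance;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Scalar ARI.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  if (length(labels_a) == 0L) stop("empty labelings")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Cluster purity against a reference labeling
#'
#' For every cluster, count its most frequent true label; purity is the sum
#' of those majority counts divided by n. 1 means every cluster is
#' label-pure; invariant to cluster ids.
#'
#' @param clusters Cluster assignment vector.
#' @param truth True label vector of equal length.
#' @return Scalar in (0, 1].
#' @export
purity <- function(clusters, truth) {
  if (length(clusters) != length(truth)) stop("label vectors differ in length")
  if (length(clusters) == 0L) stop("empty labelings")
  tab <- table(clusters, truth)
  sum(apply(tab, 1, max)) / length(clusters)
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with `z` the centered
#' values and `S0` the total edge weight. Positive values indicate spatially
#' smooth fields, negative checkerboard-like alternation.
#'
#' @param values Per-spot numeric vector (non-constant).
#' @param graph A `"spatial_graph"` or a nonnegative weight matrix.
#' @return Scalar statistic.
#' @export
morans_i <- function(values, graph) {
  W <- graph_weights(graph, length(values))
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("Moran's I is undefined for constant values")
  s0 <- sum(W)
  if (s0 == 0) stop("graph has zero total edge weight")
  (length(values) / s0) * as.numeric(t(z) %*% W %*% z) / denom
}

#' Geary's C spatial autocorrelation
#'
#' `C = ((n - 1) / (2 S0)) * sum_ij w_ij (x_i - x_j)^2 / sum_i z_i^2`.
#' Values below 1 indicate positive spatial autocorrelation.
#'
#' @inheritParams morans_i
#' @return Scalar statistic.
#' @export
gearys_c <- function(values, graph) {
  W <- graph_weights(graph, length(values))
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("Geary's C is undefined for constant values")
  s0 <- sum(W)
  if (s0 == 0) stop("graph has zero total edge weight")
  d2 <- outer(values, values, "-")^2
  ((length(values) - 1) / (2 * s0)) * sum(as.matrix(W) * d2) / denom
}

graph_weights <- function(graph, n) {
  W <- if (inherits(graph, "spatial_graph")) graph$W else graph
  if (nrow(W) != n) stop("graph dimension does not match number of values")
  W
}

#' Score a predicted proportion matrix against ground truth
#'
#' One call computing the full agreement suite between a predicted and a true
#' spot-by-type proportion matrix: per-type PCC (mean and sd), per-type SSIM
#' (when coordinates are supplied), mean per-spot Jensen-Shannon divergence,
#' pooled RMSE, and Frobenius distance.
#'
#' @param p_hat Predicted proportions (or a fitted `"spadecon"` model).
#' @param p_true Ground-truth proportions (or a [sim_st()]).
#' @param coords Optional spot coordinates for SSIM; taken from `p_true` when
#'   it is a `sim_st`.
#' @return Object of class `"deconv_score"`: list with `pcc` (per_type, mean,
#'   sd), `ssim` (per type, or `NULL`), `jsd_mean`, `rmse`, `frobenius`.
#'   `as.data.frame()` gives the tidy (metric, cell_type, value) form.
#' @export
evaluate_deconvolution <- function(p_hat, p_true, coords = NULL) {
  if (inherits(p_hat, "spadecon")) p_hat <- p_hat$proportions
  if (inherits(p_true, "sim_st")) {
    if (is.null(coords)) coords <- p_true$st$coords
    p_true <- p_true$proportions
  }
  pcc <- pcc_per_celltype(p_hat, p_true)
  ssim <- if (!is.null(coords)) ssim_per_celltype(p_hat, p_true, coords)
  structure(list(pcc = pcc, ssim = ssim,
                 jsd_mean = jsd_per_spot(p_hat, p_true)$mean,
                 rmse = rmse(p_hat, p_true),
                 frobenius = frobenius_distance(p_hat, p_true)),
            class = "deconv_score")
}

#' @export
print.deconv_score <- function(x, ...) {
  cat(sprintf("PCC  %.3f +/- %.3f (mean +/- sd over %d cell types)\n",
              x$pcc$mean, x$pcc$sd, length(x$pcc$per_type)))
  if (!is.null(x$ssim))
    cat(sprintf("SSIM %.3f (mean over cell types)\n", mean(x$ssim)))
  cat(sprintf("JSD  %.3f (mean over spots)\nRMSE %.3f\nFrobenius %.3f\n",
              x$jsd_mean, x$rmse, x$frobenius))
  invisible(x)
}

#' @export
as.data.frame.deconv_score <- function(x, ...) {
  rows <- data.frame(metric = "pcc", cell_type = names(x$pcc$per_type),
                     value = unname(x$pcc$per_type))
  if (!is.null(x$ssim))
    rows <- rbind(rows, data.frame(metric = "ssim", cell_type = names(x$ssim),
                                   value = unname(x$ssim)))
  rbind(rows,
        data.frame(metric = c("pcc_mean", "pcc_sd", "jsd_mean", "rmse",
                              "frobenius"),
                   cell_type = NA_character_,
                   value = c(x$pcc$mean, x$pcc$sd, x$jsd_mean, x$rmse,
                             x$frobenius)))
}

check_pair <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("matrices differ in shape: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  list(a = a, b = b)
}
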