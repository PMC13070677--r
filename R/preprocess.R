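#' Select highly variable genes (variance-stabilizing ranking)
#'
#' Rank genes of a raw count matrix by the Seurat-v3-style standardized
#' variance: a loess curve of log10 variance on log10 mean predicts each
#' gene's expected standard deviation; counts are standardized with that
#' expectation, clipped at `sqrt(N)`, and the variance of the clipped values
#' is the ranking statistic. High values flag genes more variable than their
#' expression level predicts.
#'
#' @param counts Cell-by-gene (or spot-by-gene) nonnegative count matrix, or
#'   a [labeled_reference()] / [st_dataset()] holding one.
#' @param n_top Number of genes to return (default 5000, the usual choice for
#'   single-cell references); clipped to the number of available genes.
#' @param span Loess span for the mean-variance trend fit (default 0.3).
#' @return Character vector of `min(n_top, ng)` gene ids, most variable first.
#'   All-zero genes always rank last.
#' @examples
#' ref <- generate_reference(k = 2, n_per_type = 30, ng = 40, seed = 1)
#' head(select_hvg(ref, n_top = 10))
#' @export
select_hvg <- function(counts, n_top = 5000, span = 0.3) {
  if (inherits(counts, "labeled_reference")) counts <- counts$counts
  if (inherits(counts, "st_dataset")) {
    if (counts$layer != "counts") stop("HVG selection expects raw counts")
    counts <- counts$x
  }
  counts <- as_expr_matrix(counts)
  if (any(counts < 0)) stop("HVG selection expects raw nonnegative counts")
  if (n_top < 1) stop("'n_top' must be >= 1")
  n <- nrow(counts)
  if (n < 2L) stop("need at least two observations to rank variance")
  mu <- colMeans(counts)
  v <- colVars(counts)
  stat <- numeric(ncol(counts))
  usable <- v > 0 & mu > 0
  if (any(usable)) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]), span = span,
                        degree = 2)
    sd_exp <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    idx <- which(usable)
    for (j in seq_along(idx)) {
      z <- (counts[, idx[j]] - mu[idx[j]]) / sd_exp[j]
      z <- pmin(z, clip)
      # variance of clipped standardized values around the original mean (0)
      stat[idx[j]] <- sum(z^2) / (n - 1)
    }
  }
  ord <- order(-stat, colnames(counts), method = "radix")
  colnames(counts)[ord][seq_len(min(n_top, ncol(counts)))]
}

# Column variances without forming a centered copy per column.
colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' Normalize, log-transform and optionally scale an expression matrix
#'
#' The standard single-cell preprocessing chain: each row (cell or spot) is
#' rescaled so its counts sum to `target_sum`, values are transformed with
#' `log(1 + x)`, and, if `do_scale`, each gene column is centered to mean 0
#' and unit variance (zero-variance columns become all zeros).
#'
#' @param x Count matrix (observations in rows) or an [st_dataset()] on the
#'   counts layer.
#' @param do_scale Standardize gene columns after the log transform
#'   (default `TRUE`).
#' @param target_sum Library size every row is scaled to (default `1e4`).
#' @return Matrix (or `st_dataset`) of the same shape; the layer tag becomes
#'   `"scaled"` or `"normalized"`. Rows with zero total count are left as
#'   zeros with a warning.
#' @examples
#' preprocess(matrix(c(1, 0, 0, 1, 1, 1), 3, 2), do_scale = FALSE)
#' @export
preprocess <- function(x, do_scale = TRUE, target_sum = 1e4) {
  if (inherits(x, "st_dataset")) {
    if (x$layer != "counts") stop("preprocess expects the counts layer")
    out <- preprocess(x$x, do_scale = do_scale, target_sum = target_sum)
    return(st_dataset(out, x$coords,
                      layer = if (do_scale) "scaled" else "normalized"))
  }
  x <- as_expr_matrix(x)
  if (any(x < 0)) stop("preprocess expects nonnegative counts")
  rs <- rowSums(x)
  zero_rows <- rs == 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " observation(s) with zero total count left as zeros")
    rs[zero_rows] <- 1
  }
  out <- log1p(x * (target_sum / rs))
  if (do_scale) out <- scale_genes(out)
  out
}

# Center each column to mean 0 and unit variance; constant columns -> 0.
scale_genes <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colVars(x))
  s[s == 0 | !is.finite(s)] <- Inf # constant column maps to exact zeros
  out <- sweep(x, 2, mu, "-")
  sweep(out, 2, s, "/")
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene ids, with
#' columns placed in lexicographic order so the result is deterministic
#' regardless of input column order. Needed because a model trained on
#' simulated pseudo-spots can only be applied to real spots over a common
#' gene axis.
#'
#' @param a,b Expression matrices (observations x genes) or [st_dataset()]s.
#' @return List with elements `a` and `b`, both restricted to the shared
#'   genes in identical (sorted) order.
#' @export
align_genes <- function(a, b) {
  ga <- if (inherits(a, "st_dataset")) colnames(a$x) else colnames(as_expr_matrix(a))
  gb <- if (inherits(b, "st_dataset")) colnames(b$x) else colnames(as_expr_matrix(b))
  shared <- sort(intersect(ga, gb), method = "radix")
  if (length(shared) == 0L)
    stop("no shared genes; first ids were [",
         paste(utils::head(ga, 3), collapse = ", "), "] vs [",
         paste(utils::head(gb, 3), collapse = ", "), "]")
  subset_genes <- function(m) {
    if (inherits(m, "st_dataset"))
      st_dataset(m$x[, shared, drop = FALSE], m$coords, layer = m$layer)
    else as_expr_matrix(m)[, shared, drop = FALSE]
  }
  list(a = subset_genes(a), b = subset_genes(b))
}
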