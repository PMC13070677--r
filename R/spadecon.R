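#' Training configuration for [spadecon()]
#'
#' @param alpha Weight of the graph-Laplacian smoothness penalty
#'   (default 0.1; 0 disables spatial regularization). Large values let
#'   spatial smoothness dominate the transcriptional signal.
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs_stage1 Maximum epochs of supervised pretraining on simulated
#'   pseudo-spots (default 2000).
#' @param epochs_stage2 Maximum epochs of reconstruction-only adaptation to
#'   real ST data (default 1000; 0 skips stage 2).
#' @param k_neighbors Neighbours in the spot KNN graph (default 6).
#' @param hidden_dims Encoder hidden layer widths (default `c(512, 128)`).
#' @param seed Integer seed for parameter initialization; with a fixed seed
#'   the whole fit is deterministic on CPU.
#' @param loss_scaling `"mean"` (default) divides each objective term by its
#'   number of elements (reconstruction by `ns * ng`, supervision and the
#'   Laplacian penalty by `ns * k`), so the balance between terms does not
#'   depend on the gene count; `"sum"` uses the plain entrywise sums.
#' @param patience Plateau window in epochs for early stopping (default 200).
#' @param tol Relative change of the trailing-window mean loss below which
#'   training stops (default 1e-5).
#' @param verbose Print a progress line every 100 epochs.
#' @return A list of class `"spadecon_control"`.
#' @export
spadecon_control <- function(alpha = 0.1, lr = 1e-4,
                             epochs_stage1 = 2000, epochs_stage2 = 1000,
                             k_neighbors = 6, hidden_dims = c(512, 128),
                             loss_scaling = c("mean", "sum"),
                             seed = 1L, patience = 200, tol = 1e-5,
                             verbose = FALSE) {
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (lr <= 0) stop("'lr' must be > 0")
  if (epochs_stage1 < 0 || epochs_stage2 < 0) stop("epoch counts must be >= 0")
  structure(list(alpha = alpha, lr = lr, epochs_stage1 = as.integer(epochs_stage1),
                 epochs_stage2 = as.integer(epochs_stage2),
                 k_neighbors = k_neighbors, hidden_dims = hidden_dims,
                 loss_scaling = match.arg(loss_scaling),
                 seed = as.integer(seed), patience = as.integer(patience),
                 tol = tol, verbose = verbose),
            class = "spadecon_control")
}

#' Fit a spatially regularized autoencoder deconvolution model
#'
#' Two-stage training of an autoencoder whose latent width equals the number
#' of cell types. Stage 1 trains on simulated pseudo-spots with known
#' proportions `P`, minimizing
#' `||X_s - dec(enc(X_s))||_1 + ||P - Z||_1 + alpha * Tr(Z' L Z)`
#' (entrywise L1 norms; `L` the spot-graph Laplacian). Stage 2 drops the
#' supervision term and continues optimizing the same parameters on the real
#' ST data with its own spatial graph. The latent code of the target dataset,
#' row-normalized onto the simplex, is the estimated spot-by-type proportion
#' matrix; the decoder weight matrix is the cell-type-by-gene signature.
#'
#' @param sim A [sim_st()] — simulated pseudo-spots with ground-truth
#'   proportions — used for supervised pretraining.
#' @param real Optional [st_dataset()] of real ST counts. When given, genes
#'   are aligned to the shared set, stage 2 runs on it, and the returned
#'   proportions are for its spots; otherwise the simulated spots are the
#'   target.
#' @param control A [spadecon_control()].
#' @param hvg_n If not `NULL`, restrict to this many highly variable genes of
#'   the simulated counts (via [select_hvg()]) before training. Default
#'   `NULL`: use all (aligned) genes, which is appropriate when the input was
#'   already gene-filtered.
#' @return An object of class `"spadecon"` with components `proportions`
#'   (target spots x types, rows on the simplex), `signatures` (types x
#'   genes), `loss_trace` (list with `stage1`, `stage2`), `genes`,
#'   `type_names`, `control`, the fitted network parameters, the target's
#'   preprocessing statistics (for [predict.spadecon()]), and the call.
#'   Methods: `print`, `summary`, `coef` (proportions), `predict`, `fitted`
#'   (reconstruction), `residuals`, `plot`.
#' @examples
#' \donttest{
#' ref <- generate_reference(k = 3, n_per_type = 40, ng = 90, seed = 1)
#' sim <- simulate_spots(ref, grid = c(8, 6), seed = 2)
#' fit <- spadecon(sim, control = spadecon_control(epochs_stage1 = 200,
#'                                                 epochs_stage2 = 0))
#' head(coef(fit))
#' }
#' @seealso [evaluate_deconvolution()] to score a fit against known truth.
#' @export
spadecon <- function(sim, real = NULL, control = spadecon_control(),
                     hvg_n = NULL) {
  stopifnot(inherits(sim, "sim_st"))
  if (!inherits(control, "spadecon_control"))
    stop("'control' must come from spadecon_control()")
  cl <- match.call()
  st_sim <- sim$st
  if (!is.null(hvg_n)) {
    hvg <- select_hvg(st_sim$x, n_top = hvg_n)
    st_sim <- st_dataset(st_sim$x[, hvg, drop = FALSE], st_sim$coords,
                         layer = st_sim$layer)
  }
  if (!is.null(real)) {
    stopifnot(inherits(real, "st_dataset"))
    al <- align_genes(st_sim, real)
    st_sim <- al$a
    real <- al$b
  }
  genes <- colnames(st_sim$x)

  Xs_norm <- preprocess(st_sim$x, do_scale = FALSE)
  sim_center <- colMeans(Xs_norm)
  sim_scale <- sqrt(colVars(Xs_norm))
  Xs <- scale_genes(Xs_norm)
  graph_sim <- build_spatial_graph(st_sim$coords, control$k_neighbors)

  set.seed(control$seed)
  par <- nn_init(ng = length(genes), k = length(sim$type_names),
                 hidden_dims = control$hidden_dims)
  s1 <- nn_train(par, Xs, P = sim$proportions[, sim$type_names, drop = FALSE],
                 L = graph_sim$L, cfg = control,
                 epochs = control$epochs_stage1, stage = "stage1")
  par <- s1$par

  trace2 <- numeric(0)
  if (is.null(real) && control$epochs_stage2 > 0) {
    # no separate real dataset: stage 2 adapts to the simulated spots
    # themselves with the reconstruction-only objective
    s2 <- nn_train(par, Xs, P = NULL, L = graph_sim$L, cfg = control,
                   epochs = control$epochs_stage2, stage = "stage2")
    par <- s2$par
    trace2 <- s2$trace
  }
  if (!is.null(real)) {
    Xr_norm <- preprocess(real$x, do_scale = FALSE)
    center <- colMeans(Xr_norm)
    scl <- sqrt(colVars(Xr_norm))
    Xr <- scale_genes(Xr_norm)
    graph_real <- build_spatial_graph(real$coords, control$k_neighbors)
    s2 <- nn_train(par, Xr, P = NULL, L = graph_real$L, cfg = control,
                   epochs = control$epochs_stage2, stage = "stage2")
    par <- s2$par
    trace2 <- s2$trace
    target_x <- Xr
    target <- real
  } else {
    center <- sim_center
    scl <- sim_scale
    target_x <- Xs
    target <- st_sim
  }

  fwd <- nn_forward(par, target_x)
  props <- row_normalize(fwd$Z)
  dimnames(props) <- list(rownames(target$x), sim$type_names)
  sig <- par$dec
  dimnames(sig) <- list(sim$type_names, genes)

  structure(list(proportions = props, signatures = sig,
                 loss_trace = list(stage1 = s1$trace, stage2 = trace2),
                 params = par, genes = genes, type_names = sim$type_names,
                 control = control,
                 preproc = list(center = center, scale = scl),
                 target_scaled = target_x,
                 target_coords = target$coords, call = cl),
            class = "spadecon")
}

#' Encode spot expression into the latent cell-type space
#'
#' Applies the fitted encoder to a preprocessed (scaled) expression matrix.
#' The softplus output activation guarantees a nonnegative code.
#'
#' @param object A fitted `"spadecon"` model.
#' @param x Matrix with one column per training gene, already normalized and
#'   scaled (as [predict.spadecon()] does internally for raw counts).
#' @return Spot-by-type nonnegative latent matrix `Z`.
#' @export
encode <- function(object, x) {
  stopifnot(inherits(object, "spadecon"))
  x <- as.matrix(x)
  if (ncol(x) != length(object$genes))
    stop("input has ", ncol(x), " genes; model expects ", length(object$genes))
  nn_forward(object$params, x)$Z
}

#' Decode a latent code back to expression space
#'
#' Applies the decoder — a single bias-free linear map — so
#' `decode(object, diag(k))` recovers the signature matrix row by row and
#' decoding is additive in its argument.
#'
#' @param object A fitted `"spadecon"` model.
#' @param z Spot-by-type latent matrix.
#' @return Reconstructed spot-by-gene matrix.
#' @export
decode <- function(object, z) {
  stopifnot(inherits(object, "spadecon"))
  z <- as.matrix(z)
  if (ncol(z) != length(object$type_names))
    stop("latent width ", ncol(z), " does not match number of types ",
         length(object$type_names))
  z %*% object$params$dec
}

#' Row-normalize a nonnegative latent matrix onto the simplex
#'
#' Divides every row by its sum; an all-zero row is mapped to the uniform
#' composition `1/k`. Negative entries are a contract violation (the encoder
#' output is nonnegative by construction) and raise an error.
#'
#' @param z Nonnegative matrix.
#' @return Matrix of the same shape with rows summing to 1.
#' @examples
#' row_normalize(rbind(c(2, 2), c(1, 3), c(0, 0)))
#' @export
row_normalize <- function(z) {
  z <- as.matrix(z)
  if (any(z < 0)) stop("row_normalize expects nonnegative entries")
  rs <- rowSums(z)
  zero <- rs == 0
  if (any(zero)) {
    z[zero, ] <- 1 / ncol(z)
    rs[zero] <- 1
  }
  z / rs
}

#' Cell-type-by-gene signature matrix of a fitted model
#'
#' The decoder's final (and only) layer is linear and bias-free, so the image
#' of the t-th latent basis vector is exactly its t-th weight row: each row
#' is the model's learned expression signature for one cell type.
#'
#' @param object A fitted `"spadecon"` model.
#' @return k x ng matrix with type names on rows and gene ids on columns.
#' @export
extract_signatures <- function(object) {
  stopifnot(inherits(object, "spadecon"))
  object$signatures
}

#' Supervised training objective
#'
#' `||X - Xhat||_1 + ||P - Z||_1 + alpha * Tr(Z' L Z)` with entrywise L1
#' norms. Exposed mainly for testing and for inspecting fitted models; the
#' training loop computes the same quantity internally.
#'
#' @param x Input expression matrix (spots x genes).
#' @param xhat Reconstruction of `x`.
#' @param p Ground-truth proportion matrix (spots x types).
#' @param z Latent code (spots x types).
#' @param L Graph Laplacian (or a `"spatial_graph"`).
#' @param alpha Nonnegative Laplacian weight.
#' @return Scalar objective value.
#' @export
loss_supervised <- function(x, xhat, p, z, L, alpha = 0.1) {
  loss_unsupervised(x, xhat, z, L, alpha) + sum(abs(p - z))
}

#' Unsupervised training objective
#'
#' `||X - Xhat||_1 + alpha * Tr(Z' L Z)` — the supervised objective without
#' the proportion-supervision term; used for adaptation to real ST data
#' where ground-truth proportions do not exist.
#'
#' @inheritParams loss_supervised
#' @return Scalar objective value.
#' @export
loss_unsupervised <- function(x, xhat, z, L, alpha = 0.1) {
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (!all(dim(x) == dim(xhat))) stop("'x' and 'xhat' differ in shape")
  recon <- sum(abs(x - xhat))
  if (alpha == 0) return(recon)
  recon + alpha * laplacian_quadratic(z, L)
}

#' @export
print.spadecon <- function(x, ...) {
  cat("Spatially regularized autoencoder deconvolution fit\n")
  cat("  ", nrow(x$proportions), " spots, ", length(x$type_names),
      " cell types, ", length(x$genes), " genes\n", sep = "")
  cat("  stage 1: ", length(x$loss_trace$stage1), " epochs",
      if (length(x$loss_trace$stage2))
        paste0("; stage 2: ", length(x$loss_trace$stage2), " epochs"),
      "\n", sep = "")
  cat("  alpha = ", x$control$alpha, ", k_neighbors = ",
      x$control$k_neighbors, ", seed = ", x$control$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.spadecon <- function(object, ...) {
  pm <- colMeans(object$proportions)
  tr1 <- object$loss_trace$stage1
  tr2 <- object$loss_trace$stage2
  out <- list(n_spots = nrow(object$proportions),
              type_names = object$type_names,
              mean_proportions = pm,
              dominant_type = object$type_names[
                apply(object$proportions, 1, which.max)],
              final_loss = c(stage1 = if (length(tr1)) tr1[length(tr1)] else NA,
                             stage2 = if (length(tr2)) tr2[length(tr2)] else NA),
              control = object$control)
  class(out) <- "summary.spadecon"
  out
}

#' @export
print.summary.spadecon <- function(x, ...) {
  cat("Deconvolution of", x$n_spots, "spots into",
      length(x$type_names), "cell types\n\n")
  cat("Mean proportions across spots:\n")
  print(round(x$mean_proportions, 4))
  cat("\nSpots by dominant type:\n")
  print(table(factor(x$dominant_type, levels = x$type_names)))
  cat("\nFinal objective: stage1 =", format(x$final_loss[1], digits = 6))
  if (is.finite(x$final_loss[2]))
    cat(", stage2 =", format(x$final_loss[2], digits = 6))
  cat("\n")
  invisible(x)
}

#' @export
coef.spadecon <- function(object, ...) object$proportions

#' Predict cell-type proportions for new spots
#'
#' Raw counts are library-size normalized, log-transformed, and standardized
#' with the preprocessing statistics of the model's target dataset, then
#' passed through the encoder and row-normalized.
#'
#' @param object A fitted `"spadecon"` model.
#' @param newdata An [st_dataset()] or count matrix containing at least the
#'   model's genes; `NULL` returns the fitted proportions.
#' @param ... Unused.
#' @return Spot-by-type proportion matrix (rows on the simplex).
#' @export
predict.spadecon <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$proportions)
  x <- if (inherits(newdata, "st_dataset")) newdata$x else as_expr_matrix(newdata)
  missing <- setdiff(object$genes, colnames(x))
  if (length(missing))
    stop("newdata is missing ", length(missing), " model genes (e.g. ",
         paste(utils::head(missing, 3), collapse = ", "), ")")
  x <- x[, object$genes, drop = FALSE]
  xn <- preprocess(x, do_scale = FALSE)
  s <- object$preproc$scale
  s[s == 0 | !is.finite(s)] <- Inf
  xs <- sweep(sweep(xn, 2, object$preproc$center, "-"), 2, s, "/")
  z <- encode(object, xs)
  props <- row_normalize(z)
  dimnames(props) <- list(rownames(x), object$type_names)
  props
}

#' Reconstruction of the target data
#'
#' `dec(enc(X))` for the target dataset's preprocessed (scaled) expression.
#'
#' @param object A fitted `"spadecon"` model.
#' @param ... Unused.
#' @return Spot-by-gene reconstructed matrix on the scaled expression scale.
#' @export
fitted.spadecon <- function(object, ...) {
  out <- nn_forward(object$params, object$target_scaled)$Xhat
  dimnames(out) <- dimnames(object$target_scaled)
  out
}

#' Residuals of the reconstruction
#'
#' Difference between the target dataset's preprocessed expression and the
#' model reconstruction `dec(enc(X))`, on the scaled expression scale.
#'
#' @param object A fitted `"spadecon"` model.
#' @param ... Unused.
#' @return Spot-by-gene residual matrix.
#' @export
residuals.spadecon <- function(object, ...) {
  object$target_scaled - fitted(object)
}

#' Plot fitted proportions in space
#'
#' One panel per cell type: spots at their spatial coordinates, shaded by the
#' estimated proportion of that type.
#'
#' @param x A fitted `"spadecon"` model.
#' @param types Which cell types to draw (default all).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.spadecon <- function(x, types = x$type_names, ...) {
  coords <- x$target_coords
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(types)),
                       mar = c(2, 2, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::hcl.colors(100, "YlOrRd", rev = TRUE)
  for (t in types) {
    p <- x$proportions[, t]
    col <- pal[pmax(1, ceiling(p / max(p, 1e-12) * 100))]
    graphics::plot(coords[, 1], coords[, 2], col = col, pch = 16,
                   main = t, xlab = "", ylab = "", asp = 1, ...)
  }
  invisible(x)
}
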