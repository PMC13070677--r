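# Internal MLP machinery for the spatially regularized autoencoder.
#
# Encoder: ng -> hidden_dims ... -> k, ELU hidden activations, softplus output
# (so the latent code Z is nonnegative and row-normalizable into proportions).
# Decoder: a single bias-free linear map k -> ng, whose k x ng weight matrix
# is read out directly as the cell-type-by-gene signature.
#
# Everything is full batch: the Laplacian penalty couples all spots, and the
# problem sizes involved (hundreds to a few thousand spots) fit comfortably
# in dense BLAS calls.

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# branch-free forms: for x > 0 the pmin/pmax terms are exact identities
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))

elu_grad <- function(x) exp(pmin(x, 0))

# Fan-in uniform initialization, one layer.
init_layer <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = stats::runif(fan_out, -b, b))
}

# Parameter list: enc = list of layers (W, b), dec = k x ng matrix (no bias).
nn_init <- function(ng, k, hidden_dims = c(512, 128)) {
  dims <- c(ng, hidden_dims, k)
  enc <- vector("list", length(dims) - 1L)
  for (l in seq_along(enc)) enc[[l]] <- init_layer(dims[l], dims[l + 1L])
  dec <- matrix(stats::runif(k * ng, -1 / sqrt(k), 1 / sqrt(k)), k, ng)
  list(enc = enc, dec = dec, dims = dims)
}

# Forward pass; returns activations needed for backprop.
nn_forward <- function(par, X) {
  n_layers <- length(par$enc)
  pre <- vector("list", n_layers)
  act <- vector("list", n_layers + 1L)
  act[[1L]] <- X
  n_obs <- nrow(X)
  for (l in seq_len(n_layers)) {
    p <- act[[l]] %*% par$enc[[l]]$W
    p <- p + rep(par$enc[[l]]$b, each = n_obs)
    pre[[l]] <- p
    act[[l + 1L]] <- if (l < n_layers) elu(p) else softplus(p)
  }
  Z <- act[[n_layers + 1L]]
  list(pre = pre, act = act, Z = Z, Xhat = Z %*% par$dec)
}

# Loss + gradients of the (supervised or unsupervised) objective.
# P = NULL drops the supervision term. L may be NULL when alpha = 0.
# Term weights (w_recon, w_sup, w_lap) implement the loss scaling choice:
# all 1 for the plain entrywise sums, or 1/(elements per term) for
# per-term mean reduction.
nn_loss_grad <- function(par, X, fwd, P = NULL, L = NULL, alpha = 0,
                         w_recon = 1, w_sup = 1, w_lap = 1) {
  Z <- fwd$Z
  Xhat <- fwd$Xhat
  R <- X - Xhat
  loss_recon <- w_recon * sum(abs(R))
  dXhat <- -w_recon * sign(R)
  dZ <- dXhat %*% t(par$dec)
  g_dec <- t(Z) %*% dXhat

  loss_sup <- 0
  if (!is.null(P)) {
    S <- P - Z
    loss_sup <- w_sup * sum(abs(S))
    dZ <- dZ - w_sup * sign(S)
  }
  loss_lap <- 0
  if (alpha > 0) {
    LZ <- as.matrix(L %*% Z)
    loss_lap <- alpha * w_lap * sum(Z * LZ)
    dZ <- dZ + 2 * alpha * w_lap * LZ
  }

  n_layers <- length(par$enc)
  g_enc <- vector("list", n_layers)
  delta <- dZ * sigmoid(fwd$pre[[n_layers]]) # softplus'
  for (l in n_layers:1) {
    g_enc[[l]] <- list(W = t(fwd$act[[l]]) %*% delta, b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(par$enc[[l]]$W)) * elu_grad(fwd$pre[[l - 1L]])
  }
  list(loss = loss_recon + loss_sup + loss_lap,
       terms = c(reconstruction = loss_recon, supervision = loss_sup,
                 laplacian = loss_lap),
       g_enc = g_enc, g_dec = g_dec)
}

adam_init <- function(par) {
  zeros_like <- function(x) {
    if (is.list(x)) lapply(x, zeros_like) else x * 0
  }
  list(m = zeros_like(par[c("enc", "dec")]),
       v = zeros_like(par[c("enc", "dec")]), t = 0L)
}

adam_update_one <- function(theta, g, m, v, lr_t, beta1, beta2, eps) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  theta <- theta - lr_t * m / (sqrt(v) + eps)
  list(theta = theta, m = m, v = v)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (l in seq_along(par$enc)) {
    for (nm in c("W", "b")) {
      u <- adam_update_one(par$enc[[l]][[nm]], grads$g_enc[[l]][[nm]],
                           state$m$enc[[l]][[nm]], state$v$enc[[l]][[nm]],
                           lr_t, beta1, beta2, eps)
      par$enc[[l]][[nm]] <- u$theta
      state$m$enc[[l]][[nm]] <- u$m
      state$v$enc[[l]][[nm]] <- u$v
    }
  }
  u <- adam_update_one(par$dec, grads$g_dec, state$m$dec, state$v$dec,
                       lr_t, beta1, beta2, eps)
  par$dec <- u$theta
  state$m$dec <- u$m
  state$v$dec <- u$v
  list(par = par, state = state)
}

# Full-batch training loop shared by both stages.
# Stops early when the relative change of the trailing-window mean loss
# drops below tol.
nn_train <- function(par, X, P = NULL, L = NULL, cfg, epochs,
                     stage = "stage1") {
  if (epochs == 0L) return(list(par = par, trace = numeric(0)))
  if (identical(cfg$loss_scaling, "mean")) {
    w_recon <- 1 / length(X)
    w_sup <- if (is.null(P)) 1 else 1 / length(P)
    w_lap <- 1 / (nrow(X) * nrow(par$dec)) # n_spots * k latent entries
  } else {
    w_recon <- w_sup <- w_lap <- 1
  }
  state <- adam_init(par)
  trace <- numeric(epochs)
  window <- cfg$patience
  prev_window_mean <- Inf
  for (e in seq_len(epochs)) {
    fwd <- nn_forward(par, X)
    lg <- nn_loss_grad(par, X, fwd, P = P, L = L, alpha = cfg$alpha,
                       w_recon = w_recon, w_sup = w_sup, w_lap = w_lap)
    if (!is.finite(lg$loss)) {
      bad <- names(lg$terms)[!is.finite(lg$terms)]
      stop("non-finite ", stage, " loss at epoch ", e, " (term: ",
           paste(bad, collapse = ", "), ")")
    }
    trace[e] <- lg$loss
    upd <- adam_step(par, lg, state, lr = cfg$lr)
    par <- upd$par
    state <- upd$state
    if (e %% window == 0L) {
      wm <- mean(trace[(e - window + 1L):e])
      if (is.finite(prev_window_mean) &&
          abs(prev_window_mean - wm) < cfg$tol * abs(prev_window_mean)) {
        trace <- trace[seq_len(e)]
        break
      }
      prev_window_mean <- wm
    }
    if (cfg$verbose && e %% 100L == 0L)
      message(stage, " epoch ", e, ": loss ", format(lg$loss, digits = 6))
  }
  list(par = par, trace = trace)
}
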