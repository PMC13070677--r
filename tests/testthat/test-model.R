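# Hand-computed toy for the objective: 3 spots, 2 genes, 2 types.
toy_loss_case <- function() {
  X <- rbind(c(1, 0), c(0, 2), c(1, 1))
  Xhat <- rbind(c(0.5, 0), c(0, 1), c(2, 1))
  P <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  Z <- rbind(c(0.8, 0.1), c(0.2, 0.7), c(0.4, 0.4))
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 0.5
  list(X = X, Xhat = Xhat, P = P, Z = Z, W = W, L = laplacian(W))
}

test_that("supervised and unsupervised objectives match the scalar hand-sum", {
  t <- toy_loss_case()
  # |X - Xhat|_1 = 0.5 + 1 + 1 = 2.5
  # |P - Z|_1 = (0.2+0.1) + (0.2+0.3) + (0.1+0.1) = 1.0
  # Tr(Z'LZ) = sum_edges w * ||zi - zj||^2
  #   edge(1,2): 1 * ((0.6)^2 + (0.6)^2) = 0.72
  #   edge(2,3): 0.5 * ((0.2)^2 + (0.3)^2) = 0.065
  alpha <- 0.1
  expect_equal(loss_unsupervised(t$X, t$Xhat, t$Z, t$L, alpha),
               2.5 + 0.1 * 0.785, tolerance = 1e-10)
  expect_equal(loss_supervised(t$X, t$Xhat, t$P, t$Z, t$L, alpha),
               2.5 + 1.0 + 0.1 * 0.785, tolerance = 1e-10)
})

test_that("objective decomposition and alpha behaviour are exact", {
  t <- toy_loss_case()
  for (alpha in c(0, 0.1, 2)) {
    expect_identical(
      loss_supervised(t$X, t$Xhat, t$P, t$Z, t$L, alpha),
      loss_unsupervised(t$X, t$Xhat, t$Z, t$L, alpha) + sum(abs(t$P - t$Z)))
  }
  # affine and increasing in alpha with slope Tr(Z'LZ) >= 0
  l0 <- loss_supervised(t$X, t$Xhat, t$P, t$Z, t$L, 0)
  l1 <- loss_supervised(t$X, t$Xhat, t$P, t$Z, t$L, 1)
  l2 <- loss_supervised(t$X, t$Xhat, t$P, t$Z, t$L, 2)
  slope <- laplacian_quadratic(t$Z, t$L)
  expect_gte(slope, 0)
  expect_equal(l1 - l0, slope, tolerance = 1e-12)
  expect_equal(l2 - l1, slope, tolerance = 1e-12)
  expect_equal(loss_unsupervised(t$X, t$Xhat, t$Z, t$L, 0),
               sum(abs(t$X - t$Xhat)))
  expect_error(loss_unsupervised(t$X, t$Xhat, t$Z, t$L, -1), "alpha")
  # perfect reconstruction + constant latent rows -> 0
  Zc <- rbind(c(.5, .5), c(.5, .5), c(.5, .5))
  expect_equal(loss_unsupervised(t$X, t$X, Zc, t$L, 5), 0)
  expect_equal(loss_supervised(t$X, t$X, Zc, Zc, t$L, 5), 0)
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(61)
  ng <- 7; k <- 2; n <- 5
  par <- spadecon:::nn_init(ng, k, hidden_dims = c(4, 3))
  X <- matrix(rnorm(n * ng), n, ng)
  P <- row_normalize(matrix(runif(n * k), n, k))
  g <- random_graph(n, seed = 62)
  loss_at <- function(par) {
    fwd <- spadecon:::nn_forward(par, X)
    spadecon:::nn_loss_grad(par, X, fwd, P = P, L = g$L, alpha = 0.3)$loss
  }
  fwd <- spadecon:::nn_forward(par, X)
  an <- spadecon:::nn_loss_grad(par, X, fwd, P = P, L = g$L, alpha = 0.3)
  eps <- 1e-6
  check_block <- function(theta, grad, setter, n_probe = 6) {
    set.seed(63)
    idx <- sample(length(theta), min(n_probe, length(theta)))
    for (i in idx) {
      pp <- par; pm <- par
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      num <- (loss_at(setter(pp, tp)) - loss_at(setter(pm, tm))) / (2 * eps)
      expect_equal(grad[i], num, tolerance = 1e-4)
    }
  }
  for (l in 1:3) {
    check_block(par$enc[[l]]$W, an$g_enc[[l]]$W,
                function(p, th) { p$enc[[l]]$W <- matrix(th, nrow(p$enc[[l]]$W)); p })
    check_block(par$enc[[l]]$b, an$g_enc[[l]]$b,
                function(p, th) { p$enc[[l]]$b <- th; p })
  }
  check_block(par$dec, an$g_dec,
              function(p, th) { p$dec <- matrix(th, nrow(p$dec)); p })
})

test_that("encoder output is nonnegative, pointwise, and shape-checked", {
  fit <- quick_fit()
  Xs <- fit$target_scaled
  Z <- encode(fit, Xs)
  expect_equal(dim(Z), c(nrow(Xs), 3))
  expect_true(all(Z >= 0))
  two <- rbind(Xs[4, ], Xs[4, ])
  Z2 <- encode(fit, two)
  expect_equal(Z2[1, ], Z2[2, ])
  expect_error(encode(fit, Xs[, 1:5]), "expects")
})

test_that("decoder is a bias-free linear map exposing the signatures", {
  fit <- quick_fit()
  k <- length(fit$type_names)
  sig <- extract_signatures(fit)
  expect_equal(dim(sig), c(k, length(fit$genes)))
  expect_equal(decode(fit, diag(k)), unname(sig), ignore_attr = TRUE)
  expect_equal(decode(fit, matrix(0, 1, k)), matrix(0, 1, length(fit$genes)),
               ignore_attr = TRUE)
  set.seed(64)
  za <- matrix(runif(2 * k), 2, k)
  zb <- matrix(runif(2 * k), 2, k)
  expect_equal(decode(fit, za + zb), decode(fit, za) + decode(fit, zb),
               tolerance = 1e-12)
  expect_error(decode(fit, matrix(1, 2, k + 1)), "latent width")
})

test_that("freshly initialized signatures equal the initial decoder weights", {
  set.seed(65)
  par <- spadecon:::nn_init(12, 3)
  expect_equal(dim(par$dec), c(3, 12))
  # the signature IS the final-layer weight matrix, by construction
  fit <- quick_fit(epochs1 = 0, epochs2 = 0)
  expect_identical(fit$signatures, fit$params$dec,
                   ignore_attr = TRUE)
  expect_equal(unname(fit$signatures), fit$params$dec, ignore_attr = TRUE)
})

test_that("row normalization maps onto the simplex with the uniform fallback", {
  expect_equal(row_normalize(rbind(c(2, 2), c(1, 3))),
               rbind(c(.5, .5), c(.25, .75)))
  expect_equal(row_normalize(rbind(c(1, 0), c(0, 1))),
               rbind(c(1, 0), c(0, 1)))
  expect_equal(row_normalize(rbind(c(0, 0, 0))), rbind(rep(1 / 3, 3)))
  expect_error(row_normalize(rbind(c(-1, 2))), "nonnegative")
})

test_that("training is deterministic and stage-2 descends its own objective", {
  sim <- small_sim()
  ctrl <- spadecon_control(epochs_stage1 = 40, epochs_stage2 = 30, seed = 42)
  f1 <- spadecon(sim, control = ctrl)
  f2 <- spadecon(sim, control = ctrl)
  expect_identical(f1$proportions, f2$proportions)
  expect_identical(f1$signatures, f2$signatures)
  # stage 2 on the same data cannot end above its starting objective
  tr2 <- f1$loss_trace$stage2
  expect_lte(tr2[length(tr2)], tr2[1])
  # epochs_stage2 = 0 leaves the stage-1 model untouched
  f0 <- spadecon(sim, control = spadecon_control(epochs_stage1 = 40,
                                                 epochs_stage2 = 0, seed = 42))
  g1 <- spadecon:::nn_train(f0$params, f0$target_scaled, P = NULL, L = NULL,
                            cfg = spadecon_control(alpha = 0), epochs = 0)
  expect_identical(g1$par, f0$params)
})

test_that("a non-finite loss aborts with a diagnostic naming the term", {
  set.seed(66)
  par <- spadecon:::nn_init(5, 2, hidden_dims = c(3))
  X <- matrix(rnorm(20), 4, 5)
  X[2, 3] <- Inf
  expect_error(
    spadecon:::nn_train(par, X, P = NULL, L = NULL,
                        cfg = spadecon_control(alpha = 0), epochs = 3),
    "stage1.*reconstruction")
})

test_that("loss trace decreases over training on a trailing-window average", {
  fit <- quick_fit(epochs1 = 300, epochs2 = 0)
  tr <- fit$loss_trace$stage1
  w <- 50
  means <- sapply(seq(w, length(tr), by = w), function(e) mean(tr[(e - w + 1):e]))
  expect_true(all(diff(means) <= 0))
})
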