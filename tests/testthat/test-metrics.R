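test_that("per-type PCC matches the textbook covariance-ratio formula", {
  p <- rbind(c(.7, .3), c(.2, .8), c(.5, .5))
  expect_equal(unname(pcc_per_celltype(p, p)$per_type), c(1, 1))
  neg <- p
  neg[, 1] <- 2 * mean(p[, 1]) - p[, 1] # reflect around the mean
  expect_equal(unname(pcc_per_celltype(neg, p)$per_type[1]), -1)
  set.seed(51)
  a <- matrix(runif(60), 20, 3)
  b <- matrix(runif(60), 20, 3)
  got <- pcc_per_celltype(a, b)
  for (j in 1:3)
    expect_equal(unname(got$per_type[j]), brute_pcc(a[, j], b[, j]),
                 tolerance = 1e-12)
  expect_equal(got$mean, mean(got$per_type))
  expect_equal(got$sd, sd(got$per_type))
  expect_warning(got0 <- pcc_per_celltype(cbind(c(.5, .5), c(1, 0)),
                                          cbind(c(1, 0), c(0, 1))),
                 "zero-variance")
  expect_equal(unname(got0$per_type), c(0, -1))
})

test_that("RMSE and Frobenius distance satisfy their exact identity", {
  a <- matrix(0, 2, 2)
  b <- a
  b[1, 1] <- 0.5
  expect_equal(frobenius_distance(a, b), 0.5)
  expect_equal(rmse(a, b), 0.25)
  expect_equal(rmse(a, a), 0)
  set.seed(52)
  x <- matrix(runif(45), 15, 3)
  y <- matrix(runif(45), 15, 3)
  expect_equal(frobenius_distance(x, y), rmse(x, y) * sqrt(15 * 3),
               tolerance = 1e-10)
})

test_that("Jensen-Shannon divergence matches its hand expansion and bounds", {
  expect_equal(jsd_per_spot(rbind(c(.4, .6)), rbind(c(.4, .6)))$mean, 0)
  expect_equal(jsd_per_spot(rbind(c(1, 0)), rbind(c(0, 1)))$mean, log(2))
  # p = (.5,.5), q = (1,0); m = (.75,.25)
  hand <- 0.5 * (0.5 * log(0.5 / 0.75) + 0.5 * log(0.5 / 0.25)) +
          0.5 * (1 * log(1 / 0.75))
  expect_equal(jsd_per_spot(rbind(c(.5, .5)), rbind(c(1, 0)))$mean, hand,
               tolerance = 1e-12)
  expect_equal(jsd_per_spot(rbind(c(.5, .5)), rbind(c(1, 0)),
                            base = "log2")$mean, hand / log(2))
  set.seed(53)
  p <- row_normalize(matrix(runif(40), 10, 4))
  q <- row_normalize(matrix(runif(40), 10, 4))
  j <- jsd_per_spot(p, q)$per_spot
  expect_true(all(j >= 0 & j <= log(2) + 1e-12))
  expect_warning(jsd_per_spot(rbind(c(.5, .4)), rbind(c(.5, .5))),
                 "renormalized")
})

test_that("SSIM matches the reference implementation on a seeded toy image", {
  # images generated under seed 99; expected value frozen from an independent
  # reference SSIM (Gaussian window sigma 1.5, C1=0.01^2, C2=0.03^2, range 1)
  set.seed(99)
  a <- matrix(runif(256), 16, 16)
  b <- a
  b[5:9, 5:9] <- b[3:7, 3:7]
  b <- pmin(pmax(b + 0.1 * rnorm(256), 0), 1)
  coords <- cbind(rep(1:16, each = 16), rep(1:16, 16))
  s <- ssim_per_celltype(cbind(as.vector(t(a))), cbind(as.vector(t(b))), coords)
  expect_equal(unname(s), 0.5323180184892932, tolerance = 1e-6)
})

test_that("SSIM degenerate and identity cases behave", {
  coords <- cbind(rep(1:6, each = 6), rep(1:6, 6))
  f <- runif(36)
  expect_equal(unname(ssim_per_celltype(cbind(f), cbind(f), coords)), 1,
               tolerance = 1e-12)
  expect_equal(unname(ssim_per_celltype(cbind(rep(.3, 36)),
                                        cbind(rep(.9, 36)), coords)), 1)
  bad <- coords
  bad[2, ] <- coords[1, ]
  expect_error(ssim_per_celltype(cbind(f), cbind(f), bad), "raster")
})

test_that("ARI matches brute-force pair counting and its invariances", {
  expect_equal(ari(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  set.seed(54)
  a <- sample(1:3, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  expect_equal(ari(a, b), brute_ari(a, b), tolerance = 1e-12)
  expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
  relabel <- c(3, 1, 2)[a]
  expect_equal(ari(relabel, b), ari(a, b), tolerance = 1e-12)
})

test_that("purity counts majority overlap and ignores cluster ids", {
  expect_equal(purity(rep(1, 10), rep(c("x", "y"), 5)), 0.5)
  expect_equal(purity(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  set.seed(55)
  cl <- sample(1:3, 40, replace = TRUE)
  tr <- sample(letters[1:3], 40, replace = TRUE)
  expect_equal(purity(cl, tr), purity(c(9, 2, 5)[cl], tr))
  # direct hand count on a tiny case: clusters {a,a,b},{b,b}
  expect_equal(purity(c(1, 1, 1, 2, 2), c("a", "a", "b", "b", "b")),
               (2 + 2) / 5)
})

test_that("Moran's I and Geary's C match double-loop oracles on a grid", {
  g <- build_spatial_graph(cbind(rep(1:6, each = 6), rep(1:6, 6)),
                           k_neighbors = 4)
  set.seed(56)
  x <- rnorm(36)
  expect_equal(morans_i(x, g), brute_moran(x, g$W), tolerance = 1e-10)
  expect_equal(gearys_c(x, g), brute_geary(x, g$W), tolerance = 1e-10)
  expect_error(morans_i(rep(2, 36), g), "constant")
  expect_error(gearys_c(rep(2, 36), g), "constant")
})

test_that("autocorrelation statistics point the right way", {
  # smooth gradient along a path: positive autocorrelation
  path <- build_spatial_graph(cbind(1:12, 0), k_neighbors = 1)
  expect_gt(morans_i(1:12, path), 0)
  expect_lt(gearys_c(1:12, path), 1)
  # alternating signs on a ring: negative autocorrelation
  theta <- 2 * pi * (0:11) / 12
  ring <- build_spatial_graph(cbind(cos(theta), sin(theta)), k_neighbors = 2)
  expect_lt(morans_i(rep(c(1, -1), 6), ring), 0)
})

test_that("Moran's I agrees with the ape implementation on shared weights", {
  g <- random_graph(15, seed = 57)
  W <- as.matrix(g$W)
  Wrow <- W / rowSums(W) # ape row-normalizes internally
  set.seed(58)
  x <- rnorm(15)
  expect_equal(morans_i(x, Wrow), ape::Moran.I(x, W)$observed,
               tolerance = 1e-10)
})

test_that("metric directions respond monotonically to added noise", {
  sim <- small_sim()
  p <- sim$proportions
  noisy <- function(p, s, seed) {
    set.seed(seed)
    row_normalize(pmax(p + matrix(rnorm(length(p), sd = s), nrow(p)), 0))
  }
  deltas <- sapply(1:20, function(seed) {
    lo <- noisy(p, 0.05, seed)
    hi <- noisy(p, 0.3, seed + 1000)
    c(pcc = pcc_per_celltype(lo, p)$mean - pcc_per_celltype(hi, p)$mean,
      jsd = jsd_per_spot(hi, p)$mean - jsd_per_spot(lo, p)$mean,
      rmse = rmse(hi, p) - rmse(lo, p),
      ssim = mean(ssim_per_celltype(lo, p, sim$st$coords)) -
             mean(ssim_per_celltype(hi, p, sim$st$coords)))
  })
  expect_true(all(rowMeans(deltas) > 0))
})

test_that("evaluate_deconvolution bundles the suite consistently", {
  sim <- small_sim()
  sc <- evaluate_deconvolution(sim$proportions, sim)
  expect_s3_class(sc, "deconv_score")
  expect_equal(unname(sc$pcc$per_type), rep(1, 3))
  expect_equal(sc$jsd_mean, 0)
  expect_equal(sc$rmse, 0)
  expect_equal(sc$frobenius, 0)
  df <- as.data.frame(sc)
  expect_true(all(c("metric", "cell_type", "value") %in% names(df)))
  expect_error(evaluate_deconvolution(sim$proportions[1:5, ], sim$proportions),
               "shape")
})
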