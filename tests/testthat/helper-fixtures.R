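# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code under fixed seeds; no files are shipped.

small_ref <- function(seed = 101) {
  generate_reference(k = 3, n_per_type = 40, ng = 60, n_markers_per_type = 8,
                     fold = 10, seed = seed)
}

small_sim <- function(seed = 102, grid = c(8, 6), purity = 5) {
  simulate_spots(small_ref(), grid = grid, cells_per_spot = 10,
                 domain_layout = "stripes", purity = purity, seed = seed)
}

# A quick, deterministic fit for method-contract tests (not for accuracy).
quick_fit <- function(sim = small_sim(), epochs1 = 50, epochs2 = 10,
                      seed = 7) {
  spadecon(sim, control = spadecon_control(epochs_stage1 = epochs1,
                                           epochs_stage2 = epochs2,
                                           seed = seed))
}

random_graph <- function(n, seed) {
  set.seed(seed)
  build_spatial_graph(matrix(runif(n * 2, 0, 10), n, 2),
                      k_neighbors = min(4, n - 1))
}

# --- independent oracles ---------------------------------------------------

# Pairwise-sum form of the Laplacian quadratic form, explicit double loop.
brute_lap_quad <- function(Z, W) {
  W <- as.matrix(W)
  total <- 0
  for (i in seq_len(nrow(W)))
    for (j in seq_len(nrow(W)))
      total <- total + W[i, j] * sum((Z[i, ] - Z[j, ])^2)
  total / 2
}

# ARI by direct enumeration of all point pairs.
brute_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxi - expected)
}

# Moran's I and Geary's C by direct double loops over the formulas.
brute_moran <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

brute_geary <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * (x[i] - x[j])^2
  ((n - 1) / (2 * sum(W))) * num / sum(z^2)
}

# Textbook covariance-ratio Pearson correlation from raw sums.
brute_pcc <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
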