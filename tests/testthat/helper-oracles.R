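# Independent oracles used across tests. These deliberately avoid the
# package's solution paths: the coordinate descent below works on the
# penalized criterion directly (no augmented-data transformation), the BH
# search is exhaustive, and the count statistic is brute force.

# Direct coordinate descent on
#   ||y - X b||^2 + l1 ||b||_1 + l2 b' L b
# soft-threshold updates from the subgradient equations.
cd_grace_oracle <- function(X, y, L, l1, l2, max_iter = 5000, tol = 1e-12) {
  p <- ncol(X)
  b <- numeric(p)
  xtx <- colSums(X^2)
  for (it in seq_len(max_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      r_j <- y - X[, -j, drop = FALSE] %*% b[-j]
      z <- 2 * sum(X[, j] * r_j) - 2 * l2 * sum(L[j, -j] * b[-j])
      denom <- 2 * xtx[j] + 2 * l2 * L[j, j]
      b[j] <- sign(z) * max(0, abs(z) - l1) / denom
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

# Exhaustive BH threshold search over all order indices.
bh_oracle <- function(agc, alpha) {
  p <- length(agc)
  qs <- sort(agc)
  k_best <- 0L
  for (k in seq_len(p)) {
    if (qs[k] <= k * alpha / p) k_best <- k
  }
  if (k_best == 0L) return(list(bh_index = 0L, selected = integer(0)))
  list(bh_index = k_best, selected = which(agc <= qs[k_best]))
}

# Brute-force intermediate statistic.
q_oracle <- function(W) {
  p <- length(W)
  vapply(seq_len(p), function(j) {
    if (W[j] > 0) (1 + sum(W <= -W[j])) / p else 1
  }, numeric(1))
}

# Random sparse weighted graph for property tests.
random_graph <- function(p, n_edges, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(p, 2))
    pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
    grace_graph(
      tibble::tibble(
        u = pairs[pick, 1], v = pairs[pick, 2],
        weight = stats::runif(length(pick), 0.2, 2)
      ),
      n_vertices = p
    )
  })
}

# Small standardized regression instance with a graph penalty.
small_instance <- function(n, p, seed, n_edges = p) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(rep(2, ceiling(p / 3)), rep(0, p - ceiling(p / 3)))
    y <- drop(X %*% beta) + rnorm(n)
  })
  std <- standardize_xy(X, y)
  g <- random_graph(p, n_edges, seed + 1)
  list(X = std$X, y = std$y, L = normalized_laplacian(g), graph = g)
}
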