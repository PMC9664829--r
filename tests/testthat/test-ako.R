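test_that("coefficient-difference statistic and its flip-sign property", {
  expect_equal(lcd_statistic(c(0.5, 0, 0.2, 0.4)), c(0.3, -0.4))
  expect_equal(lcd_statistic(rep(0, 6)), rep(0, 3))
  expect_error(lcd_statistic(c(1, 2, 3)), "even")

  b <- withr::with_seed(1, rnorm(10))
  W <- lcd_statistic(b)
  for (j in 1:5) {
    b_swap <- b
    b_swap[c(j, j + 5)] <- b[c(j + 5, j)]
    W_swap <- lcd_statistic(b_swap)
    expect_equal(W_swap[j], -W[j])
    expect_equal(W_swap[-j], W[-j])
  }
})

test_that("intermediate statistic matches the brute-force count", {
  expect_equal(intermediate_statistic(c(0.9, -0.4, 0.2, -0.5)),
               c(0.25, 1, 0.75, 1))
  expect_equal(intermediate_statistic(c(-1, -2, -0.1)), rep(1, 3))
  expect_equal(intermediate_statistic(2), 1)
  expect_equal(intermediate_statistic(c(0, 1)), c(1, 0.5))  # W = 0 is conservative

  for (r in 1:100) {
    W <- withr::with_seed(r, round(rnorm(12), 2))  # rounding creates ties
    q <- intermediate_statistic(W)
    expect_equal(q, q_oracle(W))
    expect_true(all(q > 0 & q <= 1))
  }
})

test_that("quantile aggregation uses the conservative order statistic", {
  expect_equal(quantile_aggregate(matrix(c(0.05, 0.3), 1), gamma = 0.1),
               c(0.5, 1))
  expect_equal(quantile_aggregate(matrix(0.05, 25, 1), gamma = 0.1), 0.5)
  expect_equal(quantile_aggregate(matrix(1, 10, 3), gamma = 0.2), rep(1, 3))
  # ceiling(gamma B)-th smallest: B = 25, gamma = 0.1 -> 3rd order statistic
  col <- c(rep(0.01, 3), rep(0.9, 22))
  expect_equal(quantile_aggregate(matrix(col, 25, 1), 0.1), 0.1)
  expect_equal(quantile_aggregate(matrix(c(0.01, 0.01, rep(0.9, 23)), 25, 1), 0.1),
               1)
})

test_that("BH selection agrees with exhaustive threshold search", {
  r1 <- bh_select(c(0.02, 0.5, 0.04, 1.0), alpha = 0.2)
  expect_equal(r1$bh_index, 2L)
  expect_equal(r1$selected, c(1L, 3L))

  expect_equal(bh_select(rep(1, 6), 0.1)$selected, integer(0))
  expect_equal(bh_select(rep(1, 6), 0.1)$bh_index, 0L)

  p <- 10
  boundary <- c(0.1 / p, rep(1, p - 1))
  expect_equal(bh_select(boundary, 0.1)$selected, 1L)

  for (r in 1:1000) {
    agc <- withr::with_seed(r, {
      v <- sample(c(runif(6), runif(6)^3, rep(1, 4)), 16)
      round(v, 2)  # induce exact ties
    })
    agc[agc == 0] <- 0.005
    got <- bh_select(agc, 0.15)
    want <- bh_oracle(agc, 0.15)
    expect_identical(got$bh_index, want$bh_index)
    expect_identical(got$selected, want$selected)
  }
})

test_that("full run is deterministic and internally consistent", {
  sim <- sim_regulatory_data(n = 60, g = 4, seed = 8)
  args <- list(sim$X, sim$y, sim$graph, B = 3,
               lambda1_grid = c(120, 160), lambda2_grid = c(1, 5),
               k_folds = 3, seed = 21)
  r1 <- do.call(grace_ako, args)
  r2 <- do.call(grace_ako, args)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$agc, r2$agc)
  expect_identical(r1$W, r2$W)
  # reported AGC is the capped gamma-scaled aggregate of the Q matrix
  qg <- apply(r1$Q, 2, function(col) sort(col)[ceiling(0.1 * 3)])
  expect_equal(r1$agc, pmin(1, qg / 0.1))
  expect_equal(r1$selected, bh_select(qg, r1$alpha)$selected)
})

test_that("single-draw run degenerates to selection on its own q vector", {
  sim <- sim_regulatory_data(n = 60, g = 4, seed = 9)
  res <- grace_ako(sim$X, sim$y, sim$graph, B = 1,
                   lambda1_grid = c(120, 160), lambda2_grid = c(1, 5),
                   k_folds = 3, seed = 5)
  expect_equal(dim(res$Q), c(1, 44))
  expect_equal(res$selected, bh_select(res$Q[1, ], res$alpha)$selected)
})

test_that("aggregate scores are invariant to the order of draws", {
  Q <- withr::with_seed(3, matrix(runif(25 * 8, 0.01, 1), 25, 8))
  perm <- withr::with_seed(4, sample(25))
  expect_equal(quantile_aggregate(Q, 0.1), quantile_aggregate(Q[perm, ], 0.1))
})

test_that("selection grows monotonically with the nominal level", {
  for (r in 1:20) {
    agc <- withr::with_seed(600 + r, runif(30)^2)
    agc[agc == 0] <- 1e-4
    sel_prev <- integer(0)
    for (a in c(0.05, 0.1, 0.2, 0.4)) {
      sel <- bh_select(agc, a)$selected
      expect_true(all(sel_prev %in% sel))
      sel_prev <- sel
    }
  }
})

test_that("fit and statistic pipeline are equivariant under relabelling", {
  sim <- sim_regulatory_data(n = 50, g = 4, seed = 12)
  std <- standardize_xy(sim$X, sim$y)
  L <- normalized_laplacian(sim$graph)
  km <- knockoff_model(std$X)
  Xk <- sample_knockoffs(std$X, km, seed = 31)
  p <- sim$p
  fit <- grace_fit(cbind(std$X, Xk), std$y, augment_laplacian(L), 120, 2)
  W <- lcd_statistic(coef(fit))

  perm <- withr::with_seed(32, sample(p))
  Lp <- L[perm, perm]
  fit_p <- grace_fit(cbind(std$X[, perm], Xk[, perm]), std$y,
                     augment_laplacian(Lp), 120, 2)
  W_p <- lcd_statistic(coef(fit_p))
  # coordinate descent visits coordinates in a different order after the
  # permutation, so agreement is to solver precision, not bitwise
  expect_equal(W_p, W[perm], tolerance = 1e-3)
  expect_equal(intermediate_statistic(W_p),
               intermediate_statistic(W)[perm], tolerance = 1e-12)
})
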