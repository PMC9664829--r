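test_that("standardization centres and scales to unit sum of squares", {
  s <- standardize_xy(matrix(c(1, 2, 3), 3, 1), c(4, 4, 4))
  expect_equal(drop(s$X), c(-1, 0, 1) / sqrt(2))
  expect_equal(s$y, c(0, 0, 0))
  # idempotence
  s2 <- standardize_xy(s$X)
  expect_equal(s2$X, s$X, tolerance = 1e-12)

  X <- withr::with_seed(1, matrix(rnorm(30), 10, 3))
  std <- standardize_xy(X)$X
  expect_equal(colSums(std), rep(0, 3), tolerance = 1e-12)
  expect_equal(colSums(std^2), rep(1, 3), tolerance = 1e-12)

  Xbad <- cbind(X, bad = 7)
  expect_error(standardize_xy(Xbad), "zero-variance.*bad")
})

test_that("augmented problem has the documented shape and limits", {
  X <- withr::with_seed(2, matrix(rnorm(100 * 220), 100, 220))
  ap <- build_augmented(X, rnorm(100), diag(220), lambda1 = 5, lambda2 = 2)
  expect_equal(dim(ap$design), c(320, 220))
  expect_equal(length(ap$response), 320)
  expect_equal(ap$response[101:320], rep(0, 220))

  ap0 <- build_augmented(X[, 1:5], rnorm(100), diag(5), lambda1 = 3, lambda2 = 0)
  expect_equal(ap0$design[101:105, ], matrix(0, 5, 5))
  expect_equal(ap0$effective_lambda, 3)
  expect_equal(ap0$back_scale, 1)

  ap1 <- build_augmented(X[, 1:4], rnorm(100), diag(4), lambda1 = 1, lambda2 = 1)
  expect_equal(ap1$design[101:104, ], diag(4) / sqrt(2), tolerance = 1e-12)
})

test_that("lambda2 = 0 reduces the fit to a plain lasso", {
  inst <- small_instance(n = 40, p = 8, seed = 4)
  l1 <- 3
  fit <- grace_fit(inst$X, inst$y, inst$L, lambda1 = l1, lambda2 = 0)
  # independent route: coordinate descent on the plain lasso criterion
  obj_fit <- grace_objective(inst$X, inst$y, inst$L, coef(fit), l1, 0)
  b_cd <- cd_grace_oracle(inst$X, inst$y, inst$L, l1, 0)
  obj_cd <- grace_objective(inst$X, inst$y, inst$L, b_cd, l1, 0)
  expect_equal(obj_fit, obj_cd, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), b_cd, tolerance = 1e-5)
})

test_that("lambda1 = 0 with n > p matches the generalized-ridge closed form", {
  inst <- small_instance(n = 60, p = 8, seed = 5)
  l2 <- 3
  fit <- grace_fit(inst$X, inst$y, inst$L, lambda1 = 0, lambda2 = l2)
  closed <- solve(crossprod(inst$X) + l2 * inst$L, crossprod(inst$X, inst$y))
  expect_equal(unname(coef(fit)), drop(closed), tolerance = 1e-4)
})

test_that("augmented-lasso solution matches direct coordinate descent on the criterion", {
  for (seed in 1:5) {
    inst <- small_instance(n = 25, p = 7, seed = seed)
    l1 <- withr::with_seed(seed, runif(1, 0.5, 4))
    l2 <- withr::with_seed(seed + 50, runif(1, 0.2, 3))
    fit <- grace_fit(inst$X, inst$y, inst$L, l1, l2)
    b_cd <- cd_grace_oracle(inst$X, inst$y, inst$L, l1, l2)
    obj_fit <- grace_objective(inst$X, inst$y, inst$L, coef(fit), l1, l2)
    obj_cd <- grace_objective(inst$X, inst$y, inst$L, b_cd, l1, l2)
    expect_lt(abs(obj_fit - obj_cd), 1e-5 * (1 + abs(obj_cd)))
    expect_equal(unname(coef(fit)), b_cd, tolerance = 1e-4)
  }
})

test_that("returned solution is locally optimal against random perturbations", {
  inst <- small_instance(n = 8, p = 3, seed = 9)
  fit <- grace_fit(inst$X, inst$y, inst$L, lambda1 = 1, lambda2 = 0.5)
  b <- coef(fit)
  obj <- grace_objective(inst$X, inst$y, inst$L, b, 1, 0.5)
  pert <- withr::with_seed(10, matrix(rnorm(10000 * 3, sd = 0.05), 10000, 3))
  objs <- apply(pert, 1, function(d) {
    grace_objective(inst$X, inst$y, inst$L, b + d, 1, 0.5)
  })
  expect_true(all(objs >= obj - 1e-9))
})

test_that("objective never exceeds its value at the zero vector", {
  for (seed in 1:4) {
    inst <- small_instance(n = 30, p = 10, seed = seed)
    fit <- grace_fit(inst$X, inst$y, inst$L, lambda1 = 2, lambda2 = 1)
    expect_lte(fit$objective_value,
               grace_objective(inst$X, inst$y, inst$L, rep(0, 10), 2, 1))
  }
})

test_that("perfectly correlated predictors with equal degree get equal coefficients", {
  withr::with_seed(20, {
    x <- rnorm(50)
    X <- cbind(x, x, matrix(rnorm(50 * 3), 50, 3))
    y <- drop(2 * x + rnorm(50, sd = 0.5))
  })
  std <- standardize_xy(X, y)
  # symmetric graph: the twin columns are both linked to column 3
  g <- grace_graph(data.frame(u = c(1, 2), v = c(3, 3), weight = 1),
                   n_vertices = 5)
  fit <- grace_fit(std$X, std$y, normalized_laplacian(g),
                   lambda1 = 0.5, lambda2 = 2)
  expect_equal(coef(fit)[[1]], coef(fit)[[2]], tolerance = 1e-6)
})

test_that("sparsity is monotone non-increasing along the lambda1 grid", {
  sim <- sim_regulatory_data(n = 60, g = 5, seed = 3)
  std <- standardize_xy(sim$X, sim$y)
  L <- normalized_laplacian(sim$graph)
  nz <- vapply(seq(110, 200, by = 5), function(l1) {
    sum(coef(grace_fit(std$X, std$y, L, l1, 1)) != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("cross-validation covers the grid and honours ties and edge cases", {
  inst <- small_instance(n = 30, p = 6, seed = 7)
  single <- grace_cv(inst$X, inst$y, inst$L, lambda1_grid = 2,
                     lambda2_grid = 1, k_folds = 3, seed = 1)
  expect_equal(single$lambda1, 2)
  expect_equal(single$lambda2, 1)
  expect_equal(nrow(single$cv_table), 1)

  cv <- grace_cv(inst$X, inst$y, inst$L, lambda1_grid = c(1, 2, 4),
                 lambda2_grid = c(0.5, 1), k_folds = 3, seed = 1)
  expect_equal(nrow(cv$cv_table), 6)
  expect_true(all(c("lambda1", "lambda2", "mean_cv_error", "se_cv_error")
                  %in% names(cv$cv_table)))
  expect_error(
    grace_cv(inst$X, inst$y, inst$L, numeric(0), 1, k_folds = 3),
    "nonempty"
  )
})

test_that("pure-noise responses push cross-validation toward sparser fits", {
  grid <- c(0.5, 1, 2, 4, 8)
  hits <- 0
  for (r in 1:20) {
    withr::with_seed(300 + r, {
      X <- matrix(rnorm(80 * 10), 80, 10)
      y <- rnorm(80)
    })
    std <- standardize_xy(X, y)
    cv <- grace_cv(std$X, std$y, diag(10), lambda1_grid = grid,
                   lambda2_grid = 0.5, k_folds = 5, seed = r)
    if (cv$lambda1 >= 2) hits <- hits + 1
  }
  expect_gte(hits, 14)
})
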