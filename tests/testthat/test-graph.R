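test_that("degrees sum incident edge weights", {
  star <- grace_graph(
    tibble::tibble(u = 1, v = 2:11, weight = 1), n_vertices = 11
  )
  expect_equal(degrees(star), c(10, rep(1, 10)))

  empty <- grace_graph(tibble::tibble(u = integer(), v = integer(),
                                      weight = numeric()), n_vertices = 4)
  expect_equal(degrees(empty), rep(0, 4))

  one <- grace_graph(data.frame(u = 1, v = 2, weight = 2.5), n_vertices = 2)
  expect_equal(degrees(one), c(2.5, 2.5))
})

test_that("graph construction enforces the invariants", {
  expect_error(grace_graph(data.frame(u = 1, v = 1, weight = 1)), "self-loop")
  expect_error(grace_graph(data.frame(u = 1, v = 2, weight = -1)), "nonnegative")
  expect_error(
    grace_graph(data.frame(u = c(1, 2), v = c(2, 1), weight = 1)),
    "duplicate"
  )
  # zero-weight edges are dropped at construction
  g <- grace_graph(data.frame(u = c(1, 1), v = c(2, 3), weight = c(0, 1)),
                   n_vertices = 3)
  expect_equal(nrow(g$edges), 1)
})

test_that("normalized Laplacian matches the closed form", {
  two <- grace_graph(data.frame(u = 1, v = 2, weight = 1))
  expect_equal(normalized_laplacian(two),
               matrix(c(1, -1, -1, 1), 2, 2))

  star <- sim_network(1)
  L <- normalized_laplacian(star)
  expect_equal(diag(L), rep(1, 11))
  expect_equal(L[1, 2:11], rep(-1 / sqrt(10), 10))
  expect_equal(L[2:11, 2:11] - diag(10), matrix(0, 10, 10))

  empty <- grace_graph(tibble::tibble(u = integer(), v = integer(),
                                      weight = numeric()), n_vertices = 3)
  expect_equal(normalized_laplacian(empty), matrix(0, 3, 3))
})

test_that("normalized Laplacians are PSD and quadratic form matches edge sum", {
  for (seed in 1:6) {
    g <- random_graph(p = 12, n_edges = 20, seed = seed)
    L <- normalized_laplacian(g)
    expect_true(isSymmetric(L))
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    d <- degrees(g)
    for (k in 1:17) {
      beta <- withr::with_seed(100 * seed + k, rnorm(12))
      edge_sum <- sum(
        (beta[g$edges$u] / sqrt(d[g$edges$u]) -
           beta[g$edges$v] / sqrt(d[g$edges$v]))^2 * g$edges$weight
      )
      expect_equal(laplacian_quadform(L, beta), edge_sum, tolerance = 1e-10)
    }
  }
})

test_that("quadratic form handles the simple closed-form cases", {
  L <- normalized_laplacian(grace_graph(data.frame(u = 1, v = 2, weight = 1)))
  expect_equal(laplacian_quadform(L, c(1, 1)), 0)
  expect_equal(laplacian_quadform(L, c(1, -1)), 4)
  expect_equal(laplacian_quadform(L, c(0, 0)), 0)
  expect_error(laplacian_quadform(L, c(1, 2, 3)), "length")
})

test_that("augmented Laplacian is block-diagonal with mirrored spectrum", {
  L <- normalized_laplacian(grace_graph(data.frame(u = 1, v = 2, weight = 1)))
  L2 <- augment_laplacian(L)
  expect_equal(dim(L2), c(4, 4))
  expect_equal(L2[1:2, 1:2], L)
  expect_equal(L2[3:4, 3:4], L)
  expect_equal(L2[1:2, 3:4], matrix(0, 2, 2))

  g <- random_graph(p = 8, n_edges = 12, seed = 3)
  L <- normalized_laplacian(g)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  ev2 <- eigen(augment_laplacian(L), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev2), sort(rep(ev, 2)), tolerance = 1e-10)

  expect_equal(augment_laplacian(matrix(0, 3, 3)), matrix(0, 6, 6))
  # the no-knockoff-penalty variant zeroes the second block
  expect_equal(augment_laplacian(L, "none")[9:16, 9:16], matrix(0, 8, 8))
})

test_that("augmentation commutes with simultaneous relabelling", {
  g <- random_graph(p = 6, n_edges = 8, seed = 11)
  L <- normalized_laplacian(g)
  perm <- withr::with_seed(12, sample(6))
  P <- diag(6)[perm, ]
  P2 <- rbind(cbind(P, matrix(0, 6, 6)), cbind(matrix(0, 6, 6), P))
  expect_equal(augment_laplacian(P %*% L %*% t(P)),
               P2 %*% augment_laplacian(L) %*% t(P2))
})

test_that("edge-list files round trip through the 0-based dialect", {
  g <- random_graph(p = 9, n_edges = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path, n_vertices = 9)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$n_vertices, g$n_vertices)
  # comment lines are ignored
  lines <- readLines(path)
  writeLines(c("# a comment", lines), path)
  expect_equal(read_edge_list(path, n_vertices = 9)$edges, g$edges)
})
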