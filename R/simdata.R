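#' Transcription-factor module network
#'
#' Builds the regulatory network used in the simulation design: `g`
#' disconnected star modules, each a transcription factor (TF) linked by
#' unit-weight edges to the 10 genes it regulates. Vertices are ordered
#' module by module, TF first (so module m occupies indices
#' 11(m-1)+1 ... 11m and its TF sits at 11(m-1)+1), matching the layout of
#' the simulated coefficient vector.
#'
#' @param g number of TF modules (>= 1).
#' @return a [grace_graph()] with `11 g` vertices and `10 g` edges.
#' @export
sim_network <- function(g) {
  stopifnot(g >= 1)
  tf <- 11 * (seq_len(g) - 1) + 1
  edges <- tibble(
    u = rep(tf, each = 10),
    v = rep(tf, each = 10) + rep(1:10, times = g),
    weight = 1
  )
  grace_graph(edges, n_vertices = 11 * g)
}

#' Simulated coefficient vector
#'
#' The fixed effect pattern of the simulation design: four active modules
#' with TF effects 5, -5, 3, -3, each followed by ten regulated genes at
#' the TF effect divided by sqrt(10), then zeros. Exactly 44 coefficients
#' are nonzero; their squared sum is 136, so the simulation's noise level
#' sum(beta^2)/4 equals 34.
#'
#' @param p total number of predictors (>= 44).
#' @return numeric vector of length p.
#' @export
sim_beta <- function(p) {
  if (p < 44) stop("p must be at least 44 (four active modules)", call. = FALSE)
  block <- function(a) c(a, rep(a / sqrt(10), 10))
  c(block(5), block(-5), block(3), block(-3), rep(0, p - 44))
}

#' Simulate TF-module regulatory data
#'
#' Generates one dataset from the simulation design: TF expression columns
#' are i.i.d. standard normal; conditional on its TF, each regulated gene
#' is `rho * TF + sqrt(1 - rho^2) * noise`, so gene columns keep unit
#' marginal variance and correlate with their TF at `rho` (0.7 by
#' default; genes sharing a TF correlate at `rho^2`). The response is
#' `y = X beta + eps` with `eps` mean-zero Gaussian noise whose scale
#' parameter defaults to the design's noise level `sum(beta^2)/4 = 34`
#' (i.e. `sd(eps) = 34`): this is the calibration under which the
#' benchmark quantities of interest — selection counts, power around
#' one half, the comparator's loss of FDR control — arise; treating the
#' same quantity as a *variance* makes the signal overwhelming and every
#' procedure trivially recovers the full support (see the methods
#' vignette). Modules are mutually independent.
#'
#' @param n sample size.
#' @param g number of TF modules (>= 4, so the 44 true coefficients fit).
#' @param rho TF-gene correlation (default 0.7).
#' @param noise_sd standard deviation of the response noise; default
#'   `sum(beta^2)/4` = 34.
#' @param seed integer seed; the draw is bit-reproducible.
#' @return an object of class `grace_sim`: list with `X` (n x 11g), `y`,
#'   `graph`, `beta`, `true_set` (indices 1..44), `null_set`,
#'   `noise_level` (`sum(beta^2)/4`), `noise_sd`, and the design
#'   parameters `n`, `g`, `p`, `rho`, `seed`.
#' @export
sim_regulatory_data <- function(n, g, rho = 0.7, noise_sd = NULL, seed = 1) {
  stopifnot(n >= 2, g >= 4, rho > -1, rho < 1)
  p <- 11 * g
  beta <- sim_beta(p)
  noise_level <- sum(beta^2) / 4
  if (is.null(noise_sd)) noise_sd <- noise_level
  out <- withr::with_seed(seed, {
    X <- matrix(NA_real_, n, p)
    for (m in seq_len(g)) {
      tf_col <- 11 * (m - 1) + 1
      tf <- rnorm(n)
      X[, tf_col] <- tf
      X[, tf_col + 1:10] <- rho * tf +
        sqrt(1 - rho^2) * matrix(rnorm(10 * n), n, 10)
    }
    y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
    list(X = X, y = y)
  })
  colnames(out$X) <- paste0("g", seq_len(p))
  structure(
    list(
      X = out$X, y = out$y, graph = sim_network(g), beta = beta,
      true_set = which(beta != 0), null_set = which(beta == 0),
      noise_level = noise_level, noise_sd = noise_sd,
      n = n, g = g, p = p, rho = rho, seed = seed
    ),
    class = "grace_sim"
  )
}

#' @export
print.grace_sim <- function(x, ...) {
  cat("<grace_sim> n =", x$n, " p =", x$p, " (", x$g,
      "TF modules ), noise sd =", x$noise_sd, "\n")
  invisible(x)
}

#' Misspecify a Laplacian penalty for robustness studies
#'
#' Perturbs a normalized Laplacian the way the robustness experiment does:
#' `n_zeroed` vertices sampled without replacement from the first 44 (the
#' true support) have their degrees treated as zero, which zeroes their
#' rows and columns; and selected TFs are assigned false degrees, rebuilding
#' their rows/columns with \eqn{-w/\sqrt{d_{false} d_v}} for each still
#' connected neighbour. The result is symmetric but generally indefinite —
#' pass it to [grace_ako()] with `lambda_L = "auto"`.
#'
#' @param L a p x p normalized Laplacian from [sim_network()] (p >= 44).
#' @param seed integer seed for sampling the zeroed vertices.
#' @param n_zeroed how many true-support vertices to zero out (default 20).
#' @param false_degrees named numeric vector: names are module numbers of
#'   the TFs to corrupt, values the false degrees. The default corrupts
#'   TF 1 with degree 1 and TF 3 with degree 4.
#' @return list with `L` (the perturbed matrix), `zeroed` (the sampled
#'   vertex indices) and `false_degrees`.
#' @export
misspecify_laplacian <- function(L, seed, n_zeroed = 20,
                                 false_degrees = c("1" = 1, "3" = 4)) {
  p <- ncol(L)
  stopifnot(p >= 44, n_zeroed <= 44)
  zeroed <- withr::with_seed(seed, sample(1:44, n_zeroed))
  M <- L
  M[zeroed, ] <- 0
  M[, zeroed] <- 0
  for (nm in names(false_degrees)) {
    m <- as.integer(nm)
    d_false <- false_degrees[[nm]]
    tf <- 11 * (m - 1) + 1
    children <- tf + 1:10
    alive <- setdiff(children, zeroed)
    M[tf, ] <- 0
    M[, tf] <- 0
    M[tf, tf] <- 1
    # children keep their original unit degree in the star
    M[tf, alive] <- -1 / sqrt(d_false * 1)
    M[alive, tf] <- -1 / sqrt(d_false * 1)
  }
  list(L = M, zeroed = sort(zeroed), false_degrees = false_degrees)
}

#' Correlation-ranking variable screening
#'
#' Plain sure-independence-style screening helper: ranks predictors by
#' absolute marginal correlation with the response and keeps the top `k`.
#' Mirrors the screening step used before network-constrained selection on
#' real data; no iterative refinement is implemented.
#'
#' @param X design matrix or data frame.
#' @param y response vector.
#' @param k number of predictors to keep.
#' @return integer vector of the k column indices, in original order.
#' @export
screen_correlation <- function(X, y, k) {
  X <- as.matrix(X)
  stopifnot(k >= 1, k <= ncol(X))
  r <- abs(drop(cor(X, y)))
  sort(order(r, decreasing = TRUE)[seq_len(k)])
}
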