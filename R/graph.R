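#' Predictor networks as weighted undirected graphs
#'
#' A `grace_graph` stores the known network on the predictors (for
#' gene-expression data, typically a regulatory pathway graph: vertices are
#' genes, edges are pathway links, weights express confidence in a link).
#' Each unordered pair is stored once, self-loops are forbidden, and weights
#' must be nonnegative; zero-weight edges are dropped at construction.
#'
#' @param edges a data frame (or tibble) with columns `u`, `v`, `weight`
#'   giving 1-based vertex indices and nonnegative edge weights. An edge
#'   list with zero rows is allowed (an edgeless graph).
#' @param n_vertices number of vertices; defaults to the largest index seen.
#' @return an object of class `grace_graph` with fields `n_vertices` and
#'   `edges` (a tibble with columns `u`, `v`, `weight`, `u < v`).
#' @examples
#' g <- grace_graph(data.frame(u = 1, v = 2, weight = 1), n_vertices = 3)
#' degrees(g)
#' @export
grace_graph <- function(edges, n_vertices = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("u", "v", "weight") %in% names(edges))) {
    stop("`edges` must have columns u, v, weight", call. = FALSE)
  }
  edges <- edges[c("u", "v", "weight")]
  if (nrow(edges) > 0) {
    if (any(edges$u == edges$v)) stop("self-loops are not allowed", call. = FALSE)
    if (any(edges$weight < 0)) stop("edge weights must be nonnegative", call. = FALSE)
    edges <- edges[edges$weight > 0, , drop = FALSE]
    # canonical orientation u < v, one row per unordered pair
    swap <- edges$u > edges$v
    tmp <- edges$u[swap]
    edges$u[swap] <- edges$v[swap]
    edges$v[swap] <- tmp
    if (anyDuplicated(edges[c("u", "v")])) {
      stop("duplicate edges: each unordered pair may appear once", call. = FALSE)
    }
  }
  if (is.null(n_vertices)) {
    n_vertices <- if (nrow(edges) > 0) max(edges$v) else 0L
  }
  n_vertices <- as.integer(n_vertices)
  if (nrow(edges) > 0 && (min(edges$u) < 1 || max(edges$v) > n_vertices)) {
    stop("vertex indices must lie in [1, n_vertices]", call. = FALSE)
  }
  structure(list(n_vertices = n_vertices, edges = edges), class = "grace_graph")
}

#' @export
print.grace_graph <- function(x, ...) {
  cat("<grace_graph>", x$n_vertices, "vertices,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Weighted vertex degrees
#'
#' The degree of vertex v is the sum of the weights of its incident edges,
#' \eqn{d_v = \sum_{u \sim v} w(u, v)}; isolated vertices have degree zero.
#'
#' @param graph a [grace_graph()].
#' @return numeric vector of length `n_vertices`.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "grace_graph"))
  d <- numeric(graph$n_vertices)
  if (nrow(graph$edges) > 0) {
    inc <- tapply(
      c(graph$edges$weight, graph$edges$weight),
      c(graph$edges$u, graph$edges$v),
      sum
    )
    d[as.integer(names(inc))] <- inc
  }
  d
}

#' Normalized graph Laplacian
#'
#' Builds the symmetric normalized Laplacian used as the network penalty
#' matrix: \eqn{L(u,u) = 1} for connected vertices (graphs here have no
#' self-loops), \eqn{L(u,v) = -w(u,v)/\sqrt{d_u d_v}} for adjacent pairs,
#' and 0 otherwise. Rows and columns of isolated vertices are all zero.
#' The result is symmetric positive semidefinite.
#'
#' @param graph a [grace_graph()].
#' @param lambda_L optional nonnegative diagonal loading: `lambda_L * I` is
#'   added to the Laplacian. Useful when a user-supplied or perturbed
#'   penalty matrix is indefinite; default 0.
#' @return a `p x p` numeric matrix, `p = n_vertices`.
#' @export
normalized_laplacian <- function(graph, lambda_L = 0) {
  stopifnot(inherits(graph, "grace_graph"), lambda_L >= 0)
  p <- graph$n_vertices
  d <- degrees(graph)
  L <- matrix(0, p, p)
  if (p > 0) diag(L) <- ifelse(d > 0, 1, 0)
  if (nrow(graph$edges) > 0) {
    u <- graph$edges$u
    v <- graph$edges$v
    off <- -graph$edges$weight / sqrt(d[u] * d[v])
    L[cbind(u, v)] <- off
    L[cbind(v, u)] <- off
  }
  if (lambda_L > 0 && p > 0) L <- L + lambda_L * diag(p)
  L
}

#' Extend a Laplacian penalty to the knockoff-augmented predictor set
#'
#' Knockoff copies inherit the correlation structure of the originals, so
#' the network penalty applied to them mirrors the original penalty: the
#' default returns the 2p x 2p block-diagonal matrix `diag(L, L)`. No edges
#' are placed between originals and knockoffs, which would couple each
#' coefficient with its knockoff's and bias the coefficient-difference
#' statistic. Setting `knockoff_penalty = "none"` leaves the knockoff block
#' zero (no smoothing of knockoff coefficients), for sensitivity analysis.
#'
#' @param L a `p x p` Laplacian (symmetric PSD) matrix.
#' @param knockoff_penalty `"mirror"` (default) or `"none"`.
#' @return a `2p x 2p` matrix.
#' @export
augment_laplacian <- function(L, knockoff_penalty = c("mirror", "none")) {
  knockoff_penalty <- match.arg(knockoff_penalty)
  p <- ncol(L)
  stopifnot(nrow(L) == p)
  L2 <- matrix(0, 2 * p, 2 * p)
  L2[seq_len(p), seq_len(p)] <- L
  if (knockoff_penalty == "mirror") L2[p + seq_len(p), p + seq_len(p)] <- L
  L2
}

#' Laplacian quadratic form
#'
#' Evaluates \eqn{\beta^T L \beta}, which for a normalized Laplacian equals
#' the weighted sum of squared degree-scaled coefficient differences over
#' edges, \eqn{\sum_{u \sim v} (\beta_u/\sqrt{d_u} - \beta_v/\sqrt{d_v})^2 w(u,v)}.
#'
#' @param L penalty matrix.
#' @param beta coefficient vector of matching length.
#' @return a scalar.
#' @export
laplacian_quadform <- function(L, beta) {
  if (length(beta) != ncol(L)) {
    stop("length(beta) must equal ncol(L)", call. = FALSE)
  }
  drop(crossprod(beta, L %*% beta))
}

# Symmetric PSD square root by eigendecomposition. Eigenvalues in
# (-tol, 0) are float noise and are clipped to 0; anything more negative
# means the matrix is not a valid penalty.
laplacian_sqrt <- function(L, tol = 1e-8) {
  if (ncol(L) == 0) return(L)
  e <- eigen(L, symmetric = TRUE)
  if (min(e$values) < -tol * max(1, abs(e$values[1]))) {
    stop("penalty matrix is not positive semidefinite; ",
         "consider diagonal loading via lambda_L", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Smallest diagonal loading on a candidate grid that renders M PSD.
choose_lambda_L <- function(M, grid = seq(0.1, 2.0, by = 0.1), tol = 1e-8) {
  emin <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (emin >= -tol) return(0)
  ok <- grid[grid + emin >= -tol]
  if (length(ok) == 0) {
    stop("no lambda_L on the grid makes the penalty matrix PSD", call. = FALSE)
  }
  min(ok)
}

#' Read and write edge-list files
#'
#' The on-disk dialect is a TSV with header `u	v	weight`, 0-based
#' integer vertex indices, and `#` comment lines. Indices are converted to
#' 1-based on read and back to 0-based on write, so a write/read round trip
#' is exact.
#'
#' @param path file path.
#' @param n_vertices optional vertex count (defaults to max index + 1).
#' @return `read_edge_list()` returns a [grace_graph()];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path, n_vertices = NULL) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("u", "v", "weight") %in% names(df))) {
    stop("edge-list file must have header: u, v, weight", call. = FALSE)
  }
  grace_graph(
    tibble(u = df$u + 1L, v = df$v + 1L, weight = df$weight),
    n_vertices = n_vertices
  )
}

#' @rdname read_edge_list
#' @param graph a [grace_graph()] to write.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "grace_graph"))
  df <- data.frame(
    u = graph$edges$u - 1L,
    v = graph$edges$v - 1L,
    weight = graph$edges$weight
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
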