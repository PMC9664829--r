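#' Centre the response and standardize the predictors
#'
#' Applies the convention used throughout the model: each predictor column
#' is centred and scaled to unit *sum of squares* (not unit variance), and
#' the response is centred, so the criterion needs no intercept.
#'
#' @param X numeric matrix or data frame, samples in rows.
#' @param y numeric response vector (optional).
#' @return a list with `X` (standardized matrix), `y` (centred, or `NULL`),
#'   `center`, `scale` (per-column statistics; `x_std = (x - center)/scale`),
#'   and `y_center`.
#' @export
standardize_xy <- function(X, y = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2) stop("need at least 2 rows", call. = FALSE)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colSums(Xc^2))
  bad <- which(scl <= 0 | !is.finite(scl))
  if (length(bad) > 0) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- bad
    stop("zero-variance column(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  Xs <- sweep(Xc, 2, scl, "/")
  yc <- NULL
  y_center <- NA_real_
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
    y_center <- mean(y)
    yc <- y - y_center
  }
  list(X = Xs, y = yc, center = ctr, scale = scl, y_center = y_center)
}

#' Augmented lasso formulation of the network-constrained criterion
#'
#' The graph-constrained criterion
#' \deqn{(y - X\beta)^T(y - X\beta) + \lambda_1 \|\beta\|_1 + \lambda_2 \beta^T L \beta}
#' is solved as a lasso on an augmented dataset: the design is
#' \eqn{(1+\lambda_2)^{-1/2} [X; \sqrt{\lambda_2} L^{1/2}]} (so the sample
#' size grows from n to n + p), the response is padded with p zeros, the
#' effective L1 penalty is \eqn{\lambda_1/\sqrt{1+\lambda_2}}, and the
#' augmented solution maps back to the original scale through the factor
#' \eqn{(1+\lambda_2)^{-1/2}}.
#'
#' @param X standardized design matrix (n x p).
#' @param y centred response.
#' @param L penalty matrix (p x p, symmetric PSD).
#' @param lambda1,lambda2 nonnegative penalties.
#' @param L_half optional precomputed symmetric square root of `L`
#'   (recycled across calls during cross-validation).
#' @return list with `design` ((n+p) x p), `response` (length n+p),
#'   `effective_lambda`, `back_scale`.
#' @export
build_augmented <- function(X, y, L, lambda1, lambda2, L_half = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(ncol(L) == p, nrow(L) == p, lambda1 >= 0, lambda2 >= 0)
  if (is.null(L_half)) L_half <- laplacian_sqrt(L)
  sc <- 1 / sqrt(1 + lambda2)
  design <- rbind(X, sqrt(lambda2) * L_half) * sc
  list(
    design = design,
    response = c(y, rep(0, p)),
    effective_lambda = lambda1 * sc,
    back_scale = sc
  )
}

# Decreasing lambda path ending at the target value. glmnet's coordinate
# descent warm-starts down a path, which is both faster and more accurate
# than a cold single-lambda call.
lambda_path_to <- function(target, design, response) {
  n_rows <- nrow(design)
  lmax <- max(abs(crossprod(design, response))) / n_rows
  lmax <- max(lmax, target, .Machine$double.eps)
  if (target > 0) {
    unique(c(lmax * c(1, 0.5, 0.25), target * c(8, 4, 2, 1.0001), target))
  } else {
    c(lmax * c(1, 0.3, 0.1, 0.03, 0.01, 0.003), 0)
  }
}

sort_path <- function(path) sort(unique(path[path >= 0]), decreasing = TRUE)

# glmnet stops early along a user-supplied lambda path once the deviance
# plateaus, which silently drops the smallest (target) lambdas; disable
# that for the duration of a call so every requested lambda is solved.
glmnet_exact <- function(design, response, lambda, thresh) {
  old <- glmnet::glmnet.control()
  on.exit(do.call(glmnet::glmnet.control, old[c("fdev", "devmax")]))
  glmnet::glmnet.control(fdev = 0, devmax = 1)
  fit <- glmnet::glmnet(
    design, response, family = "gaussian", alpha = 1, lambda = lambda,
    standardize = FALSE, intercept = FALSE, thresh = thresh, maxit = 1e5
  )
  stopifnot(length(fit$lambda) == length(lambda))
  fit
}

#' Fit the network-constrained (Grace) regression
#'
#' Solves the criterion of [build_augmented()] at fixed penalties by lasso
#' coordinate descent (via glmnet) on the augmented problem, then rescales
#' the solution to the original coefficient scale. Inputs are assumed
#' standardized (see [standardize_xy()]); no intercept is fit.
#'
#' @inheritParams build_augmented
#' @param thresh coordinate-descent convergence threshold passed to glmnet.
#' @return an object of class `grace_fit`: a list with `coefficients`,
#'   `lambda1`, `lambda2`, `objective_value` (the criterion at the
#'   solution), `n_iter` (coordinate-descent passes), `converged`,
#'   `back_scale`, and `intercept` (always 0 under centring).
#' @examples
#' set.seed(1)
#' X <- standardize_xy(matrix(rnorm(40), 10, 4))$X
#' y <- X %*% c(2, -2, 0, 0) + rnorm(10, sd = 0.1)
#' fit <- grace_fit(X, drop(y - mean(y)), diag(4), lambda1 = 0.5, lambda2 = 1)
#' coef(fit)
#' @export
grace_fit <- function(X, y, L, lambda1, lambda2, L_half = NULL, thresh = 1e-10) {
  ap <- build_augmented(X, y, L, lambda1, lambda2, L_half = L_half)
  n_rows <- nrow(ap$design)
  target <- ap$effective_lambda / (2 * n_rows)
  path <- sort_path(lambda_path_to(target, ap$design, ap$response))
  fit <- glmnet_exact(ap$design, ap$response, path, thresh)
  beta_star <- as.numeric(fit$beta[, ncol(fit$beta)])
  beta <- beta_star * ap$back_scale
  names(beta) <- colnames(X)
  obj <- grace_objective(X, y, L, beta, lambda1, lambda2)
  structure(
    list(
      coefficients = beta,
      intercept = 0,
      lambda1 = lambda1,
      lambda2 = lambda2,
      objective_value = obj,
      n_iter = fit$npasses,
      converged = fit$jerr == 0,
      back_scale = ap$back_scale
    ),
    class = "grace_fit"
  )
}

#' Evaluate the network-constrained criterion
#'
#' @inheritParams build_augmented
#' @param beta coefficient vector.
#' @return the scalar criterion value
#'   \eqn{\|y - X\beta\|_2^2 + \lambda_1\|\beta\|_1 + \lambda_2 \beta^T L \beta}.
#' @export
grace_objective <- function(X, y, L, beta, lambda1, lambda2) {
  r <- y - drop(as.matrix(X) %*% beta)
  sum(r^2) + lambda1 * sum(abs(beta)) + lambda2 * laplacian_quadform(L, beta)
}

#' @export
coef.grace_fit <- function(object, ...) object$coefficients

#' @export
print.grace_fit <- function(x, ...) {
  cat("<grace_fit> lambda1 =", x$lambda1, " lambda2 =", x$lambda2,
      " nonzero =", sum(x$coefficients != 0), "/", length(x$coefficients), "\n")
  invisible(x)
}

#' Cross-validated tuning of the Grace penalties
#'
#' K-fold cross-validation over a (lambda1, lambda2) grid. Folds partition
#' the *original* rows only; the penalty pseudo-rows of the augmented
#' problem are artifacts of the solver, enter every training fit, and never
#' contribute to the validation error. Fold assignment is drawn once from
#' `seed` and reused across the whole grid, so the comparison between grid
#' points is paired. Ties in mean validation error are broken toward larger
#' lambda1, then larger lambda2 (sparser, then smoother).
#'
#' @inheritParams build_augmented
#' @param lambda1_grid,lambda2_grid nonempty penalty grids.
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return list with `lambda1`, `lambda2` (the selected pair) and
#'   `cv_table`, a tibble with one row per grid point
#'   (`lambda1`, `lambda2`, `mean_cv_error`, `se_cv_error`).
#' @export
grace_cv <- function(X, y, L, lambda1_grid, lambda2_grid, k_folds = 10,
                     seed = NULL, L_half = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(lambda1_grid) == 0 || length(lambda2_grid) == 0) {
    stop("penalty grids must be nonempty", call. = FALSE)
  }
  stopifnot(k_folds >= 2, n >= k_folds)
  if (is.null(L_half)) L_half <- laplacian_sqrt(L)
  folds <- withr::with_seed(
    if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
    sample(rep(seq_len(k_folds), length.out = n))
  )
  l1 <- sort(unique(lambda1_grid))
  zeros <- rep(0, p)
  rows <- list()
  for (l2 in sort(unique(lambda2_grid))) {
    sc <- 1 / sqrt(1 + l2)
    pen_block <- sqrt(l2) * L_half * sc
    err <- matrix(NA_real_, k_folds, length(l1))
    for (k in seq_len(k_folds)) {
      tr <- folds != k
      design <- rbind(X[tr, , drop = FALSE] * sc, pen_block)
      resp <- c(y[tr], zeros)
      path <- sort(l1 * sc / (2 * nrow(design)), decreasing = TRUE)
      fit <- glmnet_exact(design, resp, path, thresh = 1e-8)
      # columns of fit$beta follow `path` (decreasing lambda1); reverse to
      # ascending l1 order and map back to the original coefficient scale
      B <- as.matrix(fit$beta)
      B <- B[, rev(seq_len(ncol(B))), drop = FALSE] * sc
      pred <- X[!tr, , drop = FALSE] %*% B
      err[k, ] <- colMeans((y[!tr] - pred)^2)
    }
    rows[[length(rows) + 1]] <- tibble(
      lambda1 = l1,
      lambda2 = l2,
      mean_cv_error = colMeans(err),
      se_cv_error = apply(err, 2, sd) / sqrt(k_folds)
    )
  }
  cv_table <- dplyr::bind_rows(rows)
  best <- cv_table[order(cv_table$mean_cv_error,
                         -cv_table$lambda1, -cv_table$lambda2), ][1, ]
  list(lambda1 = best$lambda1, lambda2 = best$lambda2, cv_table = cv_table)
}
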