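#' End-to-end simulation benchmark
#'
#' Replicates the simulation study: for each (n, g) setting and each
#' replicate, one dataset is drawn from [sim_regulatory_data()] and every
#' requested method is run on that same dataset, so method comparisons are
#' paired. Replicate r of a run with base seed `s` uses seed
#' `s * 1e6 + r`, making any single replicate reproducible in isolation.
#'
#' Methods: `"grace_ako"` (the full aggregated-knockoff procedure),
#' `"grace_ko"` (single knockoff draw, B = 1) and `"grace"` (the
#' no-knockoff baseline selecting all nonzero CV-tuned coefficients).
#'
#' @param settings data frame with columns `n` and `g`, one row per
#'   simulation setting.
#' @param methods character subset of `c("grace", "grace_ko", "grace_ako")`.
#' @param replications replicates per setting (R).
#' @param alpha,B,gamma,lambda1_grid,lambda2_grid,k_folds passed to the
#'   selection procedures.
#' @param seed base seed for the replicate schedule.
#' @return an object of class `grace_benchmark`: list with `results` (a
#'   tidy tibble: n, g, p, method, replicate, mfdr, tpp, n_selected),
#'   `summary` (per setting x method means and Monte Carlo standard
#'   errors), `n_failed` (replicates excluded after errors) and the
#'   resolved configuration.
#' @export
grace_benchmark <- function(settings,
                            methods = c("grace_ako", "grace"),
                            replications = 10,
                            alpha = 0.1, B = 25, gamma = 0.1,
                            lambda1_grid = seq(110, 200, by = 5),
                            lambda2_grid = 1:10,
                            k_folds = 10, seed = 1) {
  settings <- as_tibble(settings)
  stopifnot(all(c("n", "g") %in% names(settings)), replications >= 1)
  methods <- match.arg(methods, c("grace", "grace_ko", "grace_ako"),
                       several.ok = TRUE)
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(settings))) {
    n <- settings$n[i]
    g <- settings$g[i]
    for (r in seq_len(replications)) {
      rep_seed <- seed * 1e6 + r
      sim <- sim_regulatory_data(n = n, g = g, seed = rep_seed)
      for (m in methods) {
        rec <- tryCatch(
          run_one_method(m, sim, alpha, B, gamma, lambda1_grid,
                         lambda2_grid, k_folds, rep_seed),
          error = function(e) {
            warning("replicate ", r, " (n=", n, ", g=", g, ", ", m,
                    ") failed: ", conditionMessage(e), call. = FALSE)
            NULL
          }
        )
        if (is.null(rec)) {
          n_failed <- n_failed + 1L
          next
        }
        rows[[length(rows) + 1]] <- tibble(
          n = n, g = g, p = sim$p, method = m, replicate = r,
          mfdr = rec$mfdr, tpp = rec$tpp, n_selected = rec$n_selected
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- if (nrow(results) >= 2) {
    summarize_replicates(
      dplyr::select(results, -"replicate", -"p"),
      by = c("n", "g", "method")
    )
  } else {
    results
  }
  structure(
    list(
      results = results, summary = summary, n_failed = n_failed,
      config = list(
        settings = settings, methods = methods, replications = replications,
        alpha = alpha, B = B, gamma = gamma, lambda1_grid = lambda1_grid,
        lambda2_grid = lambda2_grid, k_folds = k_folds, seed = seed
      )
    ),
    class = "grace_benchmark"
  )
}

run_one_method <- function(method, sim, alpha, B, gamma,
                           lambda1_grid, lambda2_grid, k_folds, rep_seed) {
  sel <- switch(
    method,
    grace_ako = grace_ako(sim$X, sim$y, sim$graph, alpha = alpha, B = B,
                          gamma = gamma, lambda1_grid = lambda1_grid,
                          lambda2_grid = lambda2_grid, k_folds = k_folds,
                          seed = rep_seed)$selected,
    grace_ko = grace_ako(sim$X, sim$y, sim$graph, alpha = alpha, B = 1,
                         gamma = gamma, lambda1_grid = lambda1_grid,
                         lambda2_grid = lambda2_grid, k_folds = k_folds,
                         seed = rep_seed)$selected,
    grace = grace_select(sim$X, sim$y, sim$graph,
                         lambda1_grid = lambda1_grid,
                         lambda2_grid = lambda2_grid, k_folds = k_folds,
                         seed = rep_seed)$selected
  )
  list(
    mfdr = mfdr(sel, sim$null_set, alpha),
    tpp = tpp(sel, sim$true_set),
    n_selected = length(sel)
  )
}

#' @export
print.grace_benchmark <- function(x, ...) {
  cat("<grace_benchmark>", nrow(x$results), "records")
  if (x$n_failed > 0) cat(" (", x$n_failed, "failed replicates excluded )")
  cat("\n")
  print(x$summary)
  invisible(x)
}

#' Laplacian-misspecification robustness experiment
#'
#' Runs the aggregated-knockoff procedure at n = 100, g = 10 with a
#' corrupted penalty matrix: per replicate, 20 vertices sampled from the
#' 44 true ones have their Laplacian rows/columns zeroed, and TFs 1 and 3
#' are rebuilt with false degrees 1 and 4. The corrupted matrix is
#' indefinite, so the smallest diagonal loading on the 0.1–2.0 grid that
#' restores positive semidefiniteness is applied automatically.
#'
#' @param replications number of replicates.
#' @param seed base seed (same replicate schedule as [grace_benchmark()]).
#' @param n,g simulation setting (defaults 100 and 10).
#' @param n_zeroed,false_degrees passed to [misspecify_laplacian()];
#'   `n_zeroed = 0` with empty `false_degrees` reduces to the standard run.
#' @param alpha,B,gamma,lambda1_grid,lambda2_grid,k_folds passed to
#'   [grace_ako()].
#' @return list with `results` (tidy per-replicate tibble) and `summary`
#'   (means and Monte Carlo standard errors of mfdr, tpp, n_selected).
#' @export
robustness_experiment <- function(replications = 10, seed = 1,
                                  n = 100, g = 10,
                                  n_zeroed = 20,
                                  false_degrees = c("1" = 1, "3" = 4),
                                  alpha = 0.1, B = 25, gamma = 0.1,
                                  lambda1_grid = seq(110, 200, by = 5),
                                  lambda2_grid = 1:10, k_folds = 10) {
  rows <- list()
  for (r in seq_len(replications)) {
    rep_seed <- seed * 1e6 + r
    sim <- sim_regulatory_data(n = n, g = g, seed = rep_seed)
    L <- normalized_laplacian(sim$graph)
    if (n_zeroed > 0 || length(false_degrees) > 0) {
      L <- misspecify_laplacian(L, seed = rep_seed, n_zeroed = n_zeroed,
                                false_degrees = false_degrees)$L
    }
    res <- grace_ako(sim$X, sim$y, laplacian = L, lambda_L = "auto",
                     alpha = alpha, B = B, gamma = gamma,
                     lambda1_grid = lambda1_grid, lambda2_grid = lambda2_grid,
                     k_folds = k_folds, seed = rep_seed)
    rows[[r]] <- tibble(
      replicate = r,
      mfdr = mfdr(res$selected, sim$null_set, alpha),
      tpp = tpp(res$selected, sim$true_set),
      n_selected = length(res$selected)
    )
  }
  results <- dplyr::bind_rows(rows)
  summary <- if (replications >= 2) {
    dplyr::mutate(summarize_replicates(dplyr::select(results, -"replicate")),
                  n = n, g = g, .before = 1)
  } else {
    results
  }
  list(results = results, summary = summary)
}
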