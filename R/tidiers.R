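#' Tidy a selection result
#'
#' @param x a `grace_ako` object.
#' @param ... unused.
#' @return a tibble with one row per variable: `variable`, `w_mean` (mean
#'   coefficient-difference statistic across draws), `agc` (aggregated
#'   score) and `selected`.
#' @export
tidy.grace_ako <- function(x, ...) {
  tibble(
    variable = x$variables,
    w_mean = colMeans(x$W),
    agc = x$agc,
    selected = seq_along(x$agc) %in% x$selected
  )
}

#' @rdname tidy.grace_ako
#' @return `glance()` returns a one-row tibble with `n_selected`,
#'   `bh_index`, `lambda1`, `lambda2`, `alpha`, `gamma`, `B`, `seed`.
#' @export
glance.grace_ako <- function(x, ...) {
  tibble(
    n_selected = length(x$selected), bh_index = x$bh_index,
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    alpha = x$alpha, gamma = x$gamma, B = x$B, seed = x$seed
  )
}

#' Tidy a Grace fit
#'
#' @param x a `grace_fit` object.
#' @param ... unused.
#' @return a tibble with `variable` and `estimate`.
#' @export
tidy.grace_fit <- function(x, ...) {
  nm <- names(x$coefficients)
  if (is.null(nm)) nm <- paste0("V", seq_along(x$coefficients))
  tibble(variable = nm, estimate = unname(x$coefficients))
}

#' @rdname tidy.grace_fit
#' @export
glance.grace_fit <- function(x, ...) {
  tibble(
    lambda1 = x$lambda1, lambda2 = x$lambda2,
    objective_value = x$objective_value,
    n_nonzero = sum(x$coefficients != 0),
    n_iter = x$n_iter, converged = x$converged
  )
}

#' @export
tidy.grace_benchmark <- function(x, ...) x$results

#' @export
glance.grace_benchmark <- function(x, ...) x$summary

#' Plot aggregated knockoff scores
#'
#' One point per variable: aggregated score against variable index,
#' selected variables highlighted and the Benjamini-Hochberg threshold
#' value drawn as a dashed line (when the selection is nonempty).
#'
#' @param object a `grace_ako` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grace_ako <- function(object, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  pl <- ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$agc,
                                        colour = .data$selected)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "variable index", y = "aggregated score",
                  colour = "selected") +
    ggplot2::theme_minimal()
  if (object$bh_index > 0) {
    thr <- sort(object$agc)[object$bh_index]
    pl <- pl + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  pl
}

#' Plot benchmark results
#'
#' Boxplots of per-replicate modified FDR and power by method, faceted by
#' simulation setting, with the nominal level drawn as a dashed line on
#' the mFDR panel.
#'
#' @param object a `grace_benchmark` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.grace_benchmark <- function(object, ...) {
  d <- tidyr::pivot_longer(object$results, c("mfdr", "tpp"),
                           names_to = "metric", values_to = "value")
  d$metric <- factor(d$metric, c("mfdr", "tpp"), c("mFDR", "power"))
  d$setting <- paste0("n=", d$n, ", p=", d$p)
  ref <- tibble(metric = factor("mFDR", levels(d$metric)),
                level = object$config$alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$setting, y = .data$value,
                                  fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, linewidth = 0.3) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$level),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
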