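#' Modified false discovery proportion of a selection
#'
#' Per-replicate term of the modified FDR,
#' \eqn{|\hat S \cap S_0| / (|\hat S| + 1/\alpha)}: the number of selected
#' nulls over the selection size offset by \eqn{1/\alpha}. The offset makes
#' the expectation controllable in finite samples and is always strictly
#' smaller than the classical false discovery proportion when anything is
#' selected.
#'
#' @param selected integer vector of selected indices.
#' @param null_set integer vector of true-null indices.
#' @param alpha the nominal level used in the offset.
#' @return a scalar in \[0, 1).
#' @export
mfdr <- function(selected, null_set, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  length(intersect(selected, null_set)) / (length(selected) + 1 / alpha)
}

#' True positive proportion (power)
#'
#' Fraction of truly associated variables that were selected,
#' \eqn{|\hat S \cap S_1| / |S_1|}. Reported as "power" in benchmark
#' summaries; the two labels share this one implementation.
#'
#' @param selected integer vector of selected indices.
#' @param true_set nonempty integer vector of truly nonzero indices.
#' @return a scalar in \[0, 1\].
#' @export
tpp <- function(selected, true_set) {
  if (length(true_set) == 0) stop("true_set must be nonempty", call. = FALSE)
  length(intersect(selected, true_set)) / length(true_set)
}

#' Summarize replicate metrics with Monte Carlo standard errors
#'
#' @param records a data frame of per-replicate metrics; every numeric
#'   column is summarized. Grouping columns (character or factor, or any
#'   columns named in `by`) are preserved.
#' @param by optional character vector of grouping column names.
#' @return a tibble with one row per group and, for each metric `m`,
#'   columns `m_mean` and `m_se` (`se = sd/sqrt(R)`, sd with denominator
#'   R - 1), plus the replicate count `n_replicates`.
#' @export
summarize_replicates <- function(records, by = NULL) {
  records <- as_tibble(records)
  if (nrow(records) < 2) stop("need at least 2 replicates", call. = FALSE)
  if (is.null(by)) {
    by <- names(records)[vapply(records, function(x) is.character(x) || is.factor(x), logical(1))]
  }
  metric_cols <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                         c(by, "replicate"))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(metric_cols),
        list(mean = mean, se = ~ sd(.x) / sqrt(dplyr::n()))
      ),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
}
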