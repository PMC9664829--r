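#' Read a numeric matrix from TSV/CSV
#'
#' Reads a delimited numeric matrix with an optional header row and an
#' optional leading label column (both auto-detected). Any missing or
#' non-numeric cell is an error that names its location: silent NA
#' propagation into a fit is never allowed.
#'
#' @param path file path; the delimiter is a tab unless the file ends in
#'   `.csv`.
#' @return a numeric matrix, with dimnames when labels were present.
#' @export
read_matrix_tsv <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  first <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#")
  rown <- NULL
  if (ncol(df) > 1 && is.character(df[[1]])) {
    rown <- df[[1]]
    df <- df[-1]
  }
  m <- as.matrix(df)
  dimnames(m) <- if (has_header) list(NULL, names(df)) else NULL
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    loc <- apply(head(idx, 5), 1, function(z) paste0("[", z[1], ",", z[2], "]"))
    stop("missing/non-numeric cells at ", paste(loc, collapse = " "),
         if (nrow(idx) > 5) " ..." else "", call. = FALSE)
  }
  if (!is.null(rown)) rownames(m) <- rown
  m
}

#' Write a numeric matrix to TSV
#'
#' Values are written with 15 significant digits so a write/read round
#' trip reproduces them exactly at double precision.
#'
#' @param m numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(signif(m, 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Write a selection result to disk
#'
#' Emits the per-variable result table as TSV (columns `index`, `variable`,
#' `W_mean`, `agc`, `selected`) and a JSON sidecar with the full resolved
#' configuration, the tuned penalties and the selection summary. Output is
#' byte-deterministic given identical inputs.
#'
#' @param result a `grace_ako` object.
#' @param path output TSV path; the sidecar is written to
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "grace_ako"))
  tab <- tidy(result)
  out <- data.frame(
    index = seq_along(result$agc),
    variable = tab$variable,
    W_mean = signif(tab$w_mean, 15),
    agc = signif(tab$agc, 15),
    selected = as.integer(tab$selected)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(result$config,
            list(lambda1 = result$lambda1, lambda2 = result$lambda2,
                 bh_index = result$bh_index,
                 n_selected = length(result$selected)))
  jsonlite::write_json(side, paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
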