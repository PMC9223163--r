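#' Read a feature table of taxon abundances
#'
#' Reads a tab-separated feature table with either samples in rows and taxa
#' in columns (`orientation = "samples"`, first column the sample id) or
#' taxa in rows and samples in columns (`orientation = "taxa"`, first
#' column the taxon id). Counts are converted to relative abundances per
#' sample when `as_relative = TRUE` and any row sum exceeds 1.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples"` or `"taxa"`.
#' @param as_relative Convert counts to relative abundances (default
#'   `TRUE`).
#' @return A numeric matrix, samples in rows, taxa in columns, with sample
#'   ids as row names.
#' @export
read_feature_table <- function(path, orientation = c("samples", "taxa"),
                               as_relative = TRUE) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "taxa") mat <- t(mat)
  if (as_relative && any(rowSums(mat) > 1 + 1e-8)) {
    mat <- mat / rowSums(mat)
  }
  mat
}

#' Read a per-sample metadata table
#'
#' @param path Path to a TSV file with columns for sample id, outcome,
#'   exposure and library size.
#' @param id_col,outcome_col,exposure_col,lib_size_col Column names
#'   (defaults `sample_id`, `y`, `x`, `lib_size`).
#' @return A tibble with columns `sample_id`, `y`, `x`, `lib_size`.
#' @export
read_metadata <- function(path, id_col = "sample_id", outcome_col = "y",
                          exposure_col = "x", lib_size_col = "lib_size") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c(id_col, outcome_col, exposure_col, lib_size_col)
  if (!all(need %in% names(df))) {
    abort(paste("Metadata is missing columns:",
                paste(setdiff(need, names(df)), collapse = ", ")))
  }
  tibble(sample_id = as.character(df[[id_col]]),
         y = as.numeric(df[[outcome_col]]),
         x = as.numeric(df[[exposure_col]]),
         lib_size = as.numeric(df[[lib_size_col]]))
}

#' Write screening results to a TSV file
#'
#' @param results A `marzic_screen` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_screen_results <- function(results, path) {
  utils::write.table(as.data.frame(tidy(results)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
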