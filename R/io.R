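#' Read an RDM from delimited text
#'
#' The file carries stimulus ids in the first row and first column; empty
#' cells or the token `NaN`/`NA` mark missing dissimilarities. Symmetry
#' (within `tol`) and a zero diagonal are validated on load.
#'
#' @param path File path.
#' @param metric Metric tag to attach.
#' @param sep Field separator (default: inferred from the extension, comma
#'   for `.csv`, tab otherwise).
#' @param tol Symmetry tolerance.
#' @return An [rdm()].
#' @export
read_rdm <- function(path, metric = c("correlation", "sqeuclidean"),
                     sep = NULL, tol = 1e-8) {
  metric <- match.arg(metric)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, na.strings = c("", "NA", "NaN"))
  m <- as.matrix(tab)
  rdm(m, metric = metric, tol = tol)
}

#' Write an RDM to delimited text
#'
#' @param x An [rdm()].
#' @param path File path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param na Token for missing cells (default `"NaN"`).
#' @export
write_rdm <- function(x, path, na = "NaN") {
  stopifnot(inherits(x, "rdm"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, na = na,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from delimited text or a binary matrix container
#'
#' Delimited text carries a header of feature names and the stimulus id in
#' the first column. Files ending in `.feather`/`.arrow` are read through the
#' `arrow` package when it is installed, for large inputs.
#'
#' @param path File path.
#' @param model_name Model label (default: file name without extension).
#' @param sep Field separator for text input (inferred from extension by
#'   default).
#' @return A [feature_matrix()].
#' @export
read_features <- function(path, model_name = NULL, sep = NULL) {
  if (is.null(model_name)) {
    model_name <- sub("\\.[^.]*$", "", basename(path))
  }
  if (grepl("\\.(feather|arrow)$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading ", path, " requires the 'arrow' package")
    }
    df <- as.data.frame(arrow::read_feather(path))
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  feature_matrix(m, ids = ids, model_name = model_name)
}

#' Write a feature matrix to delimited text
#'
#' @param x A [feature_matrix()].
#' @param path File path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @export
write_features <- function(x, path) {
  stopifnot(inherits(x, "feature_matrix"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  m <- unclass(x)
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%d", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
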