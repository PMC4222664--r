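#' Feature matrix for one model representation
#'
#' A stimuli-by-features real matrix with stimulus ids as row names. This is
#' the unit of input for RDM computation, model combination, remixing and
#' categorization.
#'
#' @param values Numeric matrix, `n_stimuli x n_features`; row names are the
#'   stimulus ids (or supply `ids`).
#' @param ids Optional character vector of stimulus ids overriding row names.
#' @param model_name Label for the model that produced the features.
#' @return A `feature_matrix` (a numeric matrix with a `model_name`
#'   attribute).
#' @export
feature_matrix <- function(values, ids = NULL, model_name = "model") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(ids)) rownames(values) <- as.character(ids)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("stim%03d", seq_len(nrow(values)))
  }
  if (nrow(values) < 3) stop("a feature matrix needs at least 3 stimuli")
  if (ncol(values) < 1) stop("a feature matrix needs at least 1 feature")
  if (anyDuplicated(rownames(values))) stop("stimulus ids must be unique")
  if (!all(is.finite(values))) stop("feature values must be finite (no missing values)")
  structure(values, model_name = model_name, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix '%s': %d stimuli x %d features>\n",
    attr(x, "model_name"), nrow(x), ncol(x)
  ))
  invisible(x)
}

stimulus_ids <- function(x) rownames(x)

#' Representational dissimilarity matrix
#'
#' Wraps a square symmetric dissimilarity matrix over a stimulus set.
#' The diagonal is exactly zero; cells may be missing (`NA`), and missingness
#' must be symmetric. The `metric` tag records how dissimilarities were
#' computed: `"correlation"` (1 minus Pearson correlation of the response
#' patterns, range \[0, 2\]) or `"sqeuclidean"` (squared Euclidean distance of
#' mean-centered, unit-norm patterns, which equals twice the correlation
#' distance).
#'
#' @param d Square numeric matrix with stimulus ids as dimnames (or supply
#'   `ids`). `NA` marks missing cells.
#' @param metric `"correlation"` or `"sqeuclidean"`.
#' @param ids Optional character vector of stimulus ids.
#' @param tol Symmetry tolerance for validation.
#' @return An `rdm` object (numeric matrix with a `metric` attribute).
#' @export
rdm <- function(d, metric = c("correlation", "sqeuclidean"), ids = NULL,
                tol = 1e-8) {
  metric <- match.arg(metric)
  d <- as.matrix(d)
  storage.mode(d) <- "double"
  if (nrow(d) != ncol(d)) stop("an RDM must be square")
  if (!is.null(ids)) {
    rownames(d) <- colnames(d) <- as.character(ids)
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- sprintf("stim%03d", seq_len(nrow(d)))
  }
  if (!identical(rownames(d), colnames(d))) {
    stop("row and column stimulus ids must match")
  }
  if (anyDuplicated(rownames(d))) stop("stimulus ids must be unique")
  if (!all(is.na(d) == is.na(t(d)))) stop("missing cells must be symmetric")
  ok <- !is.na(d)
  if (any(abs(d[ok] - t(d)[ok]) > tol)) {
    stop("RDM is not symmetric within tolerance ", tol)
  }
  if (any(abs(diag(d)) > tol, na.rm = TRUE)) stop("RDM diagonal must be zero")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(d, metric = metric, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  nmiss <- sum(is.na(x[upper.tri(x)]))
  cat(sprintf(
    "<rdm: %d stimuli, metric = %s, %d/%d pairs missing>\n",
    nrow(x), attr(x, "metric"), nmiss, nrow(x) * (nrow(x) - 1) / 2
  ))
  invisible(x)
}

rdm_metric <- function(x) attr(x, "metric")

#' Compute an RDM from a feature matrix
#'
#' Dissimilarity between two stimuli is 1 minus the Pearson correlation of
#' their feature vectors (`metric = "correlation"`), or the squared Euclidean
#' distance after mean-centering each pattern and scaling it to unit norm
#' (`metric = "sqeuclidean"`, which equals exactly twice the correlation
#' distance). Correlation distance is undefined for single-feature
#' representations; those must use `"sqeuclidean"`, where each pattern
#' reduces to a z-scored scalar.
#'
#' @param features A [feature_matrix()] (or a numeric matrix with stimulus
#'   ids as row names).
#' @param metric `"correlation"` or `"sqeuclidean"`.
#' @return An [rdm()].
#' @examples
#' fm <- feature_matrix(matrix(rnorm(40), 10, 4))
#' compute_rdm(fm)
#' @export
compute_rdm <- function(features, metric = c("correlation", "sqeuclidean")) {
  metric <- match.arg(metric)
  if (!inherits(features, "feature_matrix")) features <- feature_matrix(features)
  x <- unclass(features)
  n <- nrow(x)
  p <- ncol(x)
  if (p == 0) stop("feature matrix has zero features")
  ctr <- x - rowMeans(x)
  nrm <- sqrt(rowSums(ctr^2))
  if (metric == "correlation") {
    if (p < 2) {
      stop("correlation distance requires at least 2 features; ",
           "use metric = 'sqeuclidean' for single-feature representations")
    }
    bad <- which(nrm == 0)
    if (length(bad)) {
      stop("constant response pattern for stimulus ",
           paste(rownames(x)[bad], collapse = ", "),
           ": correlation distance is undefined")
    }
    z <- ctr / nrm
    d <- 1 - tcrossprod(z)
  } else {
    if (p == 1) {
      # single feature: z-score across stimuli, unit-normalize the column
      v <- drop(x)
      s <- stats::sd(v)
      if (s == 0) stop("constant single-feature representation")
      z <- (v - mean(v)) / s
      d <- outer(z, z, function(a, b) (a - b)^2)
    } else {
      bad <- which(nrm == 0)
      if (length(bad)) {
        stop("constant response pattern for stimulus ",
             paste(rownames(x)[bad], collapse = ", "))
      }
      z <- ctr / nrm
      d <- 2 * (1 - tcrossprod(z))
    }
  }
  d[d < 0] <- 0
  diag(d) <- 0
  rdm(d, metric = metric, ids = rownames(x))
}

pair_index <- function(n) {
  # row-major upper triangle: (1,2), (1,3), ..., (1,n), (2,3), ...
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

# upper-triangle vector in canonical row-major pair order; NA = masked
utv <- function(x) {
  n <- nrow(x)
  pi <- pair_index(n)
  x[cbind(pi[, 1], pi[, 2])]
}

#' Vectorize an RDM into its canonical pair list
#'
#' Serializes the upper triangle in fixed row-major order: (1,2), (1,3), ...,
#' (1,n), (2,3), ... Missing cells appear with `value = NA` and
#' `valid = FALSE`; all downstream statistics exclude them.
#'
#' @param x An [rdm()].
#' @return A tibble with columns `i`, `j` (stimulus ids, i before j in the
#'   set order), `value`, and `valid`.
#' @export
vectorize <- function(x) {
  stopifnot(inherits(x, "rdm"))
  ids <- stimulus_ids(x)
  pi <- pair_index(nrow(x))
  v <- utv(x)
  tibble::tibble(
    i = ids[pi[, 1]],
    j = ids[pi[, 2]],
    value = v,
    valid = !is.na(v)
  )
}

#' Reassemble an RDM from a vectorized pair table
#'
#' Inverse of [vectorize()].
#'
#' @param pairs A tibble as returned by [vectorize()].
#' @param metric Metric tag for the result.
#' @return An [rdm()].
#' @export
unvectorize <- function(pairs, metric = c("correlation", "sqeuclidean")) {
  metric <- match.arg(metric)
  ids <- unique(c(pairs$i, pairs$j))
  n <- length(ids)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ii <- match(pairs$i, ids)
  jj <- match(pairs$j, ids)
  d[cbind(ii, jj)] <- pairs$value
  d[cbind(jj, ii)] <- pairs$value
  diag(d) <- 0
  rdm(d, metric = metric)
}

#' Embed an RDM into a larger stimulus set
#'
#' Returns an RDM over `target_ids` in which every cell involving a stimulus
#' absent from `x` is missing and every cell present in `x` is unchanged.
#' This is how a dissimilarity matrix measured on a subset of the stimuli
#' (e.g. 92 of 96) is aligned with matrices over the full set, filling the
#' gaps with missing values.
#'
#' @param x An [rdm()].
#' @param target_ids Character vector of target stimulus ids; must contain
#'   all ids of `x`.
#' @return An [rdm()] over `target_ids`.
#' @export
embed_rdm <- function(x, target_ids) {
  stopifnot(inherits(x, "rdm"))
  target_ids <- as.character(target_ids)
  missing_ids <- setdiff(stimulus_ids(x), target_ids)
  if (length(missing_ids)) {
    stop("stimuli absent from target_ids: ", paste(missing_ids, collapse = ", "))
  }
  n <- length(target_ids)
  d <- matrix(NA_real_, n, n, dimnames = list(target_ids, target_ids))
  idx <- match(stimulus_ids(x), target_ids)
  d[idx, idx] <- unclass(x)
  diag(d) <- 0
  rdm(d, metric = rdm_metric(x))
}

#' Restrict an RDM to a subset of stimuli
#'
#' @param x An [rdm()].
#' @param keep Which stimuli to keep: a character vector of ids, a logical
#'   vector aligned with the stimulus order, or a predicate function mapping
#'   an id vector to a logical vector.
#' @return The principal submatrix over the kept stimuli, as an [rdm()].
#' @export
subset_rdm <- function(x, keep) {
  stopifnot(inherits(x, "rdm"))
  ids <- stimulus_ids(x)
  if (is.function(keep)) {
    sel <- keep(ids)
  } else if (is.character(keep)) {
    bad <- setdiff(keep, ids)
    if (length(bad)) stop("unknown stimulus ids: ", paste(bad, collapse = ", "))
    sel <- ids %in% keep
  } else {
    sel <- as.logical(keep)
    stopifnot(length(sel) == length(ids))
  }
  if (sum(sel) < 3) stop("fewer than 3 stimuli kept")
  rdm(unclass(x)[sel, sel, drop = FALSE], metric = rdm_metric(x))
}

#' Rank-transform an RDM
#'
#' Replaces every valid cell by its rank among the valid cells (average ranks
#' for ties); missing cells stay missing. Rank transformation precedes
#' averaging of subject RDMs in noise-ceiling estimation.
#'
#' @param x An [rdm()].
#' @return An [rdm()] of ranks (same metric tag).
#' @export
rank_transform <- function(x) {
  stopifnot(inherits(x, "rdm"))
  v <- utv(x)
  ok <- !is.na(v)
  v[ok] <- rank(v[ok])
  n <- nrow(x)
  d <- matrix(NA_real_, n, n, dimnames = dimnames(x))
  pi <- pair_index(n)
  d[pi] <- v
  d[pi[, c(2, 1)]] <- v
  diag(d) <- 0
  rdm(d, metric = rdm_metric(x))
}

#' Element-wise average of RDMs
#'
#' Cells are averaged over the RDMs in which they are valid; a cell missing
#' everywhere stays missing.
#'
#' @param rdms List of [rdm()] objects over identical stimulus ids.
#' @return An [rdm()].
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1)
  ids <- stimulus_ids(rdms[[1]])
  for (r in rdms) stopifnot(identical(stimulus_ids(r), ids))
  arr <- vapply(rdms, utv, numeric(length(ids) * (length(ids) - 1) / 2))
  if (is.null(dim(arr))) arr <- matrix(arr, ncol = length(rdms))
  v <- rowMeans(arr, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  n <- length(ids)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  pi <- pair_index(n)
  d[pi] <- v
  d[pi[, c(2, 1)]] <- v
  diag(d) <- 0
  rdm(d, metric = rdm_metric(rdms[[1]]))
}

#' Convert an RDM to a long tibble
#'
#' @param x An [rdm()].
#' @param ... Unused.
#' @return Tibble with one row per ordered upper-triangle pair.
#' @exportS3Method tibble::as_tibble
as_tibble.rdm <- function(x, ...) vectorize(x)
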