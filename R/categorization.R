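stratified_folds <- function(labels, k) {
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes")
  fold <- integer(length(y))
  for (lev in levels(y)) {
    pos <- which(y == lev)
    if (length(pos) < k) {
      stop("class '", lev, "' has fewer than k = ", k, " members")
    }
    fold[pos] <- sample(rep_len(seq_len(k), length(pos)))
  }
  fold
}

#' Crossvalidated linear categorization accuracy
#'
#' Linear-kernel SVM decoding of a binary category from a representation,
#' assessed by stratified k-fold crossvalidation: the stimuli are randomly
#' partitioned into `k` folds balanced across the two classes (with 96
#' stimuli, balanced labels and `k = 12`, every fold holds out 8 stimuli, 4
#' per class); each fold in turn is the validation set for a classifier
#' trained on the rest, and the per-fold held-out accuracies are averaged.
#'
#' @param features A [feature_matrix()].
#' @param labels Binary labels aligned with the stimuli (logical or
#'   two-level factor/vector).
#' @param k Number of folds (default 12).
#' @param seed Integer seed for the fold assignment.
#' @param cost SVM regularization constant (default 1).
#' @param folds Optional precomputed fold assignment (integer vector in
#'   `1:k`), so the same folds can be reused across models for paired
#'   comparisons.
#' @return Mean held-out accuracy, with the fold assignment as attribute
#'   `"folds"`.
#' @export
kfold_accuracy <- function(features, labels, k = 12, seed = 1, cost = 1,
                           folds = NULL) {
  if (!inherits(features, "feature_matrix")) features <- feature_matrix(features)
  x <- unclass(features)
  y <- as.factor(labels)
  stopifnot(length(y) == nrow(x))
  if (is.null(folds)) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    folds <- stratified_folds(y, k)
  }
  acc <- vapply(seq_len(k), function(f) {
    te <- folds == f
    fit <- e1071::svm(x[!te, , drop = FALSE], y[!te], kernel = "linear",
                      cost = cost, scale = FALSE)
    mean(stats::predict(fit, x[te, , drop = FALSE]) == y[te])
  }, numeric(1))
  structure(mean(acc), folds = folds)
}

# balanced random dichotomy orthogonal to the true one: each pseudo-class
# takes (as near as possible) half of each true class
orthogonal_dichotomy <- function(y) {
  y <- as.factor(y)
  g <- logical(length(y))
  exact <- TRUE
  for (lev in levels(y)) {
    pos <- which(y == lev)
    h <- length(pos) / 2
    if (h != floor(h)) exact <- FALSE
    take <- sample(pos, floor(h) + stats::rbinom(1, 1, h - floor(h)))
    g[take] <- TRUE
  }
  structure(g, exact = exact)
}

#' Category-orthogonalized dichotomy null for decoding accuracy
#'
#' Tests whether a representation's categorization accuracy exceeds what
#' generic discriminability of arbitrary stimulus splits would produce. The
#' null retrains the classifier on random balanced dichotomies constructed
#' orthogonal to the true category division: each random pseudo-class takes
#' exactly half of each true class, so the null dichotomies share no
#' category signal with the true one. Odd within-class counts make the
#' exact split impossible; the nearest balanced split is used and flagged.
#' Add-one p-value of the observed accuracy against the null accuracies.
#'
#' @inheritParams kfold_accuracy
#' @param n_dichotomies Number of random dichotomies (default 1000).
#' @return One-row tibble: `statistic` (observed accuracy), `null_mean`,
#'   `p_value`, `n_resamples`, `method`, `exact_orthogonal`, `seed`.
#' @export
dichotomy_null <- function(features, labels, n_dichotomies = 1000, k = 12,
                           seed = 1, cost = 1) {
  if (!inherits(features, "feature_matrix")) features <- feature_matrix(features)
  y <- as.factor(labels)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  folds <- stratified_folds(y, k)
  obs <- as.numeric(kfold_accuracy(features, y, k = k, cost = cost,
                                   folds = folds))
  exact_all <- TRUE
  null_acc <- vapply(seq_len(n_dichotomies), function(b) {
    g <- orthogonal_dichotomy(y)
    if (!attr(g, "exact")) exact_all <<- FALSE
    gf <- stratified_folds(g, k)
    as.numeric(kfold_accuracy(features, g, k = k, cost = cost, folds = gf))
  }, numeric(1))
  p <- (1 + sum(null_acc >= obs)) / (n_dichotomies + 1)
  tibble::tibble(
    statistic = obs, null_mean = mean(null_acc), p_value = p,
    n_resamples = n_dichotomies,
    method = "category-orthogonalized dichotomy permutation",
    exact_orthogonal = exact_all, seed = seed
  )
}
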