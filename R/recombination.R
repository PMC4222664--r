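#' Combine model feature sets on equal footing
#'
#' Each model's features are mean-centered, projected onto their leading
#' `n_pcs` principal components, and the block is rescaled to unit total
#' variance, so every model contributes the same number of features and the
#' same total variance; the blocks are then concatenated in input order.
#' With `n` stimuli the covariance matrix has at most `n - 1` non-zero
#' eigenvalues, so `n_pcs` cannot exceed `n_stimuli - 1` (the default is
#' `min(n_stimuli - 1, 95)`).
#'
#' @param models List of [feature_matrix()] objects over the same stimuli.
#' @param n_pcs Number of principal components kept per model.
#' @param model_name Name for the combined representation.
#' @return A [feature_matrix()] of width `n_pcs * length(models)`.
#' @export
combine_models <- function(models, n_pcs = NULL, model_name = "combi") {
  stopifnot(length(models) >= 1)
  ids <- stimulus_ids(models[[1]])
  n <- length(ids)
  if (n < 2) stop("need at least 2 stimuli")
  for (m in models) {
    if (!identical(stimulus_ids(m), ids)) stop("models must share stimulus ids")
  }
  if (is.null(n_pcs)) n_pcs <- min(n - 1, 95)
  if (n_pcs > n - 1) {
    stop("n_pcs = ", n_pcs, " exceeds the number of non-zero eigenvalues (",
         n - 1, ") for ", n, " stimuli")
  }
  blocks <- lapply(models, function(m) {
    pc <- stats::prcomp(unclass(m), center = TRUE, scale. = FALSE)
    if (sum(pc$sdev > 1e-12) < n_pcs) {
      stop("model '", attr(m, "model_name"), "' has fewer than ", n_pcs,
           " non-degenerate principal components")
    }
    sc <- pc$x[, seq_len(n_pcs), drop = FALSE]
    totvar <- sum(apply(sc, 2, stats::var))
    sc / sqrt(totvar)
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- sprintf(
    "%s_pc%d",
    rep(vapply(models, attr, character(1), "model_name"), each = n_pcs),
    rep(seq_len(n_pcs), times = length(models))
  )
  feature_matrix(out, ids = ids, model_name = model_name)
}

#' Train a linear discriminant and read out decision values
#'
#' Fits a linear maximum-margin classifier (linear-kernel SVM) on a labeled
#' training representation and returns the signed decision value for each
#' test stimulus as a single-feature representation ("remixed" feature).
#' Training and test stimulus ids must be disjoint: the discriminant is
#' learned on held-out labeled stimuli, never on the stimuli it will
#' describe.
#'
#' @param train A [feature_matrix()] of training stimuli.
#' @param train_labels Binary labels for the training stimuli (logical, or a
#'   factor/vector with two levels).
#' @param test A [feature_matrix()] over the same feature space.
#' @param cost Regularization constant of the margin (default 1).
#' @return A one-column [feature_matrix()] of decision values for the test
#'   stimuli.
#' @export
train_discriminant <- function(train, train_labels, test, cost = 1) {
  stopifnot(inherits(train, "feature_matrix"), inherits(test, "feature_matrix"))
  if (ncol(train) != ncol(test)) stop("train and test must share a feature space")
  overlap <- intersect(stimulus_ids(train), stimulus_ids(test))
  if (length(overlap)) {
    stop("train and test stimuli overlap (leakage): ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  y <- as.factor(train_labels)
  if (nlevels(y) != 2) stop("training labels must have exactly two classes")
  fit <- e1071::svm(unclass(train), y, kernel = "linear", cost = cost,
                    scale = FALSE)
  dv <- attr(
    stats::predict(fit, unclass(test), decision.values = TRUE),
    "decision.values"
  )
  feature_matrix(matrix(as.numeric(dv), ncol = 1,
                        dimnames = list(stimulus_ids(test), "decision_value")),
                 model_name = paste0("disc_", levels(y)[1], "_vs_", levels(y)[2]))
}

#' Component set for RDM reweighting
#'
#' @param components Named list of components: each a [feature_matrix()] or a
#'   precomputed [rdm()]. Feature matrices are converted once to RDMs with
#'   the squared-Euclidean metric on normalized patterns, under which the
#'   RDM of weighted features equals the weighted sum of component RDMs.
#' @param kinds Optional character vector of kind tags (`"model"`,
#'   `"combined"`, `"discriminant"`, `"layer"`).
#' @return A `component_set`: list of [rdm()]s plus metadata.
#' @export
component_set <- function(components, kinds = NULL) {
  stopifnot(length(components) >= 1)
  if (is.null(names(components)) || any(names(components) == "")) {
    stop("components must be named")
  }
  rdms <- lapply(components, function(cmp) {
    if (inherits(cmp, "rdm")) cmp else compute_rdm(cmp, metric = "sqeuclidean")
  })
  ids <- stimulus_ids(rdms[[1]])
  for (r in rdms) {
    if (!identical(stimulus_ids(r), ids)) stop("components must share stimulus ids")
  }
  if (is.null(kinds)) kinds <- rep("model", length(rdms))
  structure(
    list(rdms = rdms, names = names(components), kinds = kinds,
         stimulus_ids = ids),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set: %d components over %d stimuli>\n",
              length(x$rdms), length(x$stimulus_ids)))
  invisible(x)
}

#' Non-negative least-squares weights over component RDMs
#'
#' Finds the non-negative weights `w` minimizing the sum of squared
#' deviations between the reference dissimilarities and the weighted sum of
#' component dissimilarities over the jointly valid cells. Because the
#' squared Euclidean distance between concatenations of `sqrt(w_k)`-scaled
#' normalized feature blocks equals the weighted sum of the per-component
#' squared distances, fitting at the RDM level is exact for feature
#' reweighting. Solved by the Lawson-Hanson active-set algorithm.
#'
#' @param components A [component_set()].
#' @param reference An [rdm()] over the same stimulus ids.
#' @return A tibble with columns `component`, `kind`, `weight`, carrying the
#'   residual sum of squares as attribute `"rss"`.
#' @export
nnls_weights <- function(components, reference) {
  stopifnot(inherits(components, "component_set"), inherits(reference, "rdm"))
  if (!identical(stimulus_ids(reference), components$stimulus_ids)) {
    stop("reference and components must share stimulus ids")
  }
  b <- utv(reference)
  A <- vapply(components$rdms, utv, numeric(length(b)))
  if (is.null(dim(A))) A <- matrix(A, ncol = length(components$rdms))
  ok <- !is.na(b) & rowSums(is.na(A)) == 0
  if (!any(ok)) stop("no jointly valid cells between reference and components")
  sol <- pracma::lsqnonneg(A[ok, , drop = FALSE], b[ok])
  tibble::new_tibble(
    list(component = components$names, kind = components$kinds,
         weight = sol$x),
    nrow = length(components$names),
    class = "nnls_weights",
    rss = sol$resid.norm
  )
}

#' Stimulus-crossvalidated reweighted RDM
#'
#' Assembles the RDM of the reweighted combination without overfitting to
#' the stimulus set: on each fold a stratified random holdout (by default 8
#' stimuli, balanced across the strata, e.g. 4 animates and 4 inanimates) is
#' removed; the non-negative weights are fitted on the cells among the
#' remaining stimuli only; the fitted weights then predict the
#' holdout-internal cells. Folds are repeated with fresh random holdouts
#' until every off-diagonal pair has been predicted at least once (cells
#' predicted several times are averaged) or `max_folds` is reached.
#'
#' @param components A [component_set()].
#' @param reference An [rdm()] to fit against.
#' @param holdout_size Number of stimuli held out per fold (default 8).
#' @param strata Stratum labels (see [bootstrap_stimuli()]); the holdout is
#'   split evenly across strata. `NULL` for unstratified holdouts.
#' @param seed Integer seed.
#' @param max_folds Fold cap (default 50000).
#' @return The assembled [rdm()], with attributes `fold_weights` (matrix of
#'   per-fold weights), `n_folds`, and `coverage` (fraction of pairs
#'   predicted).
#' @export
crossvalidated_weighted_rdm <- function(components, reference,
                                        holdout_size = 8, strata = NULL,
                                        seed = 1, max_folds = 50000) {
  stopifnot(inherits(components, "component_set"), inherits(reference, "rdm"))
  ids <- components$stimulus_ids
  if (!identical(stimulus_ids(reference), ids)) {
    stop("reference and components must share stimulus ids")
  }
  if (holdout_size < 3) stop("holdout_size must be at least 3")
  n <- length(ids)
  strat <- stratum_vector(ids, strata)
  groups <- split(seq_len(n), strat)
  per_stratum <- holdout_size / length(groups)
  if (per_stratum != round(per_stratum)) {
    stop("holdout_size must be divisible by the number of strata")
  }
  if (any(vapply(groups, length, integer(1)) <= per_stratum)) {
    stop("a stratum is too small for the requested holdout")
  }
  pi <- pair_index(n)
  ref_v <- utv(reference)
  K <- length(components$rdms)
  A <- vapply(components$rdms, utv, numeric(nrow(pi)))
  if (is.null(dim(A))) A <- matrix(A, ncol = K)

  pred_sum <- numeric(nrow(pi))
  pred_n <- integer(nrow(pi))
  weights <- list()

  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  fold <- 0
  while (any(pred_n == 0) && fold < max_folds) {
    fold <- fold + 1
    hold <- unlist(lapply(groups, sample, size = per_stratum), use.names = FALSE)
    in_hold <- seq_len(n) %in% hold
    hold_pair <- in_hold[pi[, 1]] & in_hold[pi[, 2]]
    train_pair <- !in_hold[pi[, 1]] & !in_hold[pi[, 2]]
    stopifnot(!any(hold_pair & train_pair))   # leakage guard
    ok <- train_pair & !is.na(ref_v) & rowSums(is.na(A)) == 0
    if (sum(ok) < K + 1) next
    w <- pracma::lsqnonneg(A[ok, , drop = FALSE], ref_v[ok])$x
    pred <- drop(A[hold_pair, , drop = FALSE] %*% w)
    usable <- !is.na(pred)
    tgt <- which(hold_pair)[usable]
    pred_sum[tgt] <- pred_sum[tgt] + pred[usable]
    pred_n[tgt] <- pred_n[tgt] + 1L
    weights[[fold]] <- w
  }
  if (any(pred_n == 0)) {
    stop("coverage not achieved within ", fold, " folds: ",
         sum(pred_n == 0), " of ", nrow(pi), " pairs never predicted")
  }
  v <- pred_sum / pred_n
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  d[pi] <- v
  d[pi[, c(2, 1)]] <- v
  diag(d) <- 0
  out <- rdm(d, metric = "sqeuclidean")
  fw <- do.call(rbind, weights)
  colnames(fw) <- components$names
  structure(out, fold_weights = fw, n_folds = fold,
            coverage = mean(pred_n > 0))
}
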