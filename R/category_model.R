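#' Build the category-cluster predictor model
#'
#' One predictor RDM per category: a pair of stimuli that both belong to the
#' category gets -1, every other pair 0, so with this coding a larger
#' positive fitted coefficient means a more tightly clustered category
#' (within-category dissimilarities pulled below the overall level). A
#' constant all-ones predictor (confound mean RDM) is appended. Predictor
#' columns follow the canonical row-major pair order of [vectorize()].
#'
#' @param stimuli A [stimulus_set()] covering all ten categories.
#' @return A `category_model`: list with `design` (pairs x 11 matrix),
#'   `categories`, `stimulus_ids`, `coding`.
#' @export
build_category_model <- function(stimuli) {
  validate_stimulus_set(stimuli)
  cats <- category_names()
  empty <- cats[vapply(cats, function(k) sum(stimuli[[k]]) == 0, logical(1))]
  if (length(empty)) {
    stop("empty category: ", paste(empty, collapse = ", "))
  }
  n <- nrow(stimuli)
  pi <- pair_index(n)
  design <- vapply(cats, function(k) {
    member <- stimuli[[k]]
    -as.numeric(member[pi[, 1]] & member[pi[, 2]])
  }, numeric(nrow(pi)))
  design <- cbind(design, constant = 1)
  structure(
    list(design = design, categories = cats, stimulus_ids = stimuli$id,
         coding = "within-category pairs = -1"),
    class = "category_model"
  )
}

#' @export
print.category_model <- function(x, ...) {
  cat(sprintf("<category_model: %d predictors + constant over %d stimuli>\n",
              length(x$categories), length(x$stimulus_ids)))
  invisible(x)
}

#' Fit the category-cluster model to an RDM
#'
#' Ordinary least squares of the vectorized RDM on the category predictor
#' columns plus the constant, over the valid cells, minimizing the sum of
#' squared dissimilarity deviations. The category clustering index (CCI) is
#' the proportion of RDM variance explained by the fit: the squared Pearson
#' correlation between fitted and observed valid cells. A rank-deficient
#' design is solved by the minimum-norm least-squares solution and flagged.
#'
#' @param x An [rdm()] over the model's stimulus ids.
#' @param model A [build_category_model()] result.
#' @return A `category_fit`: list with `betas` (named, one per category plus
#'   constant), `cci`, `fitted` and `residual` [rdm()]s, `rank_deficient`,
#'   `coding`, `n_cells`.
#' @export
fit_category_model <- function(x, model) {
  stopifnot(inherits(x, "rdm"), inherits(model, "category_model"))
  if (!identical(stimulus_ids(x), model$stimulus_ids)) {
    stop("RDM stimulus ids do not match the category model")
  }
  v <- utv(x)
  ok <- !is.na(v)
  if (sum(ok) < 12) stop("need at least 12 valid cells to fit")
  A <- model$design[ok, , drop = FALSE]
  b <- v[ok]
  qr_A <- qr(A)
  rank_deficient <- qr_A$rank < ncol(A)
  if (!rank_deficient) {
    beta <- qr.coef(qr_A, b)
  } else {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
    beta <- drop(beta)
    names(beta) <- colnames(A)
  }
  fit_v <- rep(NA_real_, length(v))
  fit_v[ok] <- drop(model$design[ok, , drop = FALSE] %*% beta)
  res_v <- v - fit_v
  cci <- if (stats::sd(fit_v[ok]) == 0 || stats::sd(b) == 0) {
    0
  } else {
    stats::cor(fit_v[ok], b)^2
  }
  # betas are reported with the -1 coding sign convention: positive = tighter
  betas <- beta
  names(betas) <- colnames(model$design)
  build <- function(values) {
    n <- length(model$stimulus_ids)
    d <- matrix(NA_real_, n, n,
                dimnames = list(model$stimulus_ids, model$stimulus_ids))
    pi <- pair_index(n)
    d[pi] <- values
    d[pi[, c(2, 1)]] <- values
    diag(d) <- 0
    structure(d, metric = rdm_metric(x), class = c("rdm", "matrix", "array"))
  }
  structure(
    list(
      betas = betas, cci = unname(cci),
      fitted = build(fit_v), residual = build(res_v),
      rank_deficient = rank_deficient, coding = model$coding,
      n_cells = sum(ok)
    ),
    class = "category_fit"
  )
}

#' @export
print.category_fit <- function(x, ...) {
  cat(sprintf("<category_fit: cci = %.3f over %d cells%s>\n", x$cci, x$n_cells,
              if (x$rank_deficient) ", rank-deficient (minimum-norm)" else ""))
  print(round(x$betas, 4))
  invisible(x)
}

#' Category-label randomization test of categoricality
#'
#' Null distribution of the category clustering index obtained by randomly
#' permuting the full hierarchical category label tuple across stimuli
#' (preserving category sizes and containments), rebuilding the predictors
#' and refitting on each randomization. Add-one p-value.
#'
#' @param x An [rdm()].
#' @param stimuli A [stimulus_set()] aligned with `x`.
#' @param n_rand Number of label randomizations (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `statistic` (observed CCI), `p_value`,
#'   `n_resamples`, `method`, `seed`.
#' @export
categoricality_test <- function(x, stimuli, n_rand = 1000, seed = 1) {
  stopifnot(inherits(x, "rdm"))
  model <- build_category_model(stimuli)
  obs <- fit_category_model(x, model)$cci
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  null_cci <- vapply(seq_len(n_rand), function(b) {
    fit_category_model(x, build_category_model(permute_labels(stimuli)))$cci
  }, numeric(1))
  p <- (1 + sum(null_cci >= obs)) / (n_rand + 1)
  tibble::tibble(
    statistic = obs, p_value = p, n_resamples = n_rand,
    method = "category-label randomization", seed = seed
  )
}

#' Bootstrap confidence intervals for category clustering strength
#'
#' Stratified stimulus bootstrap of the per-category fitted coefficients:
#' each resample draws stimuli with replacement within categories (strata =
#' leaf categories), rebuilds the RDM cells (masking relocated diagonal
#' zeros) and predictor columns, and refits. Percentile confidence
#' intervals; two-sided add-one bootstrap p-values against zero, optionally
#' Bonferroni-adjusted for a stated number of comparisons.
#'
#' @param x An [rdm()].
#' @param stimuli A [stimulus_set()] aligned with `x`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param bonferroni Number of comparisons to correct the p-values for
#'   (default 1 = no correction; e.g. 30 representations x 10 categories =
#'   300).
#' @return Tibble with one row per category: `category`, `beta`, `ci_low`,
#'   `ci_high`, `p_value`, `p_adjusted`.
#' @export
clustering_strength_ci <- function(x, stimuli, n_boot = 1000, seed = 1,
                                   level = 0.95, bonferroni = 1) {
  stopifnot(inherits(x, "rdm"))
  model <- build_category_model(stimuli)
  obs <- fit_category_model(x, model)$betas
  n <- nrow(stimuli)
  pi <- pair_index(n)
  m <- unclass(x)
  strat <- stimuli$leaf
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  boot <- matrix(NA_real_, n_boot, length(obs), dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_boot)) {
    idx <- stratified_resample(strat)
    ss_b <- stimulus_set(sprintf("r%03d", seq_len(n)), stimuli$leaf[idx])
    model_b <- build_category_model(ss_b)
    v <- m[idx, idx][pi]
    v[idx[pi[, 1]] == idx[pi[, 2]]] <- NA_real_
    ok <- !is.na(v)
    fit <- tryCatch(
      qr.coef(qr(model_b$design[ok, , drop = FALSE]), v[ok]),
      error = function(e) rep(NA_real_, length(obs))
    )
    boot[b, ] <- fit
  }
  alpha <- 1 - level
  cats <- model$categories
  rows <- lapply(cats, function(k) {
    d <- boot[, k]
    d <- d[!is.na(d)]
    ci <- stats::quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    p_lo <- (1 + sum(d <= 0)) / (length(d) + 1)
    p_hi <- (1 + sum(d >= 0)) / (length(d) + 1)
    tibble::tibble(
      category = k, beta = unname(obs[k]),
      ci_low = ci[1], ci_high = ci[2],
      p_value = min(1, 2 * min(p_lo, p_hi))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * bonferroni)
  out
}

# mean pairwise Pearson correlation between RDM vectors (jointly valid cells)
mean_pairwise_q <- function(rdms) {
  V <- vapply(rdms, utv, numeric(nrow(rdms[[1]]) * (nrow(rdms[[1]]) - 1) / 2))
  cc <- stats::cor(V, use = "pairwise.complete.obs")
  mean(cc[upper.tri(cc)])
}

#' Equate a model's noise level to a target RDM reliability
#'
#' Adds Gaussian noise to a model's features until the model's RDM
#' reliability matches a target: `n_instances` noisy instantiations of the
#' features are created (per-feature noise sd = `alpha` times that feature's
#' sd), an RDM is computed for each, and the mean pairwise Pearson
#' correlation `q_m` between the vectorized instantiation RDMs is compared
#' with `target_q` (e.g. the mean pairwise correlation between single-subject
#' brain RDMs). The noise scale `alpha` is found by bisection (the noise
#' deviates are drawn once and scaled, so `q_m(alpha)` is monotone and the
#' search is deterministic given the seed); the returned RDM is the
#' element-wise average of the instantiation RDMs.
#'
#' @param features A [feature_matrix()].
#' @param target_q Target mean pairwise instantiation correlation, in (0, 1].
#' @param n_instances Number of noisy instantiations (default 4).
#' @param tol Tolerance on `|q_m - target_q|` (default 0.01).
#' @param max_iter Maximum bisection iterations (default 60).
#' @param seed Integer seed for the noise deviates.
#' @param metric Metric for the instantiation RDMs.
#' @return The noise-equated average [rdm()], with attributes `alpha`
#'   (noise scale) and `achieved_q`.
#' @export
equate_noise <- function(features, target_q, n_instances = 4, tol = 0.01,
                         max_iter = 60, seed = 1,
                         metric = c("correlation", "sqeuclidean")) {
  metric <- match.arg(metric)
  if (!inherits(features, "feature_matrix")) features <- feature_matrix(features)
  if (!(target_q > 0 && target_q <= 1)) stop("target_q must be in (0, 1]")
  if (n_instances < 2) stop("need at least 2 noisy instantiations")
  x <- unclass(features)
  base <- compute_rdm(features, metric = metric)
  if (target_q == 1) {
    return(structure(base, alpha = 0, achieved_q = 1))
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- mean(sds[sds > 0])
  noise <- lapply(seq_len(n_instances), function(i) {
    matrix(stats::rnorm(length(x)), nrow(x), ncol(x)) %*% diag(sds, ncol(x))
  })
  q_at <- function(alpha) {
    rdms <- lapply(noise, function(z) {
      compute_rdm(
        feature_matrix(x + alpha * z, ids = rownames(x),
                       model_name = attr(features, "model_name")),
        metric = metric
      )
    })
    list(q = mean_pairwise_q(rdms), rdms = rdms)
  }
  # bracket: expand alpha_hi geometrically until q drops below target
  lo <- 0
  hi <- 1
  q_hi <- q_at(hi)$q
  expand <- 0
  while (q_hi > target_q && expand < 30) {
    lo <- hi
    hi <- hi * 2
    q_hi <- q_at(hi)$q
    expand <- expand + 1
  }
  if (q_hi > target_q) {
    stop("could not bracket target_q: q_m at alpha = ", hi,
         " is still ", round(q_hi, 4))
  }
  res <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- q_at(mid)
    if (abs(r$q - target_q) <= tol) {
      res <- list(alpha = mid, q = r$q, rdms = r$rdms)
      break
    }
    if (r$q > target_q) lo <- mid else hi <- mid
  }
  if (is.null(res)) {
    stop("noise equating did not converge within ", max_iter,
         " iterations; bracket alpha = [", lo, ", ", hi, "]")
  }
  out <- average_rdms(res$rdms)
  structure(out, alpha = res$alpha, achieved_q = res$q)
}
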