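#' Stimulus-label randomization test for RDM relatedness
#'
#' Tests whether a candidate RDM is related to a reference RDM by comparing
#' the observed Kendall tau-a to a null distribution obtained by applying
#' random simultaneous row/column permutations of the stimulus labels to the
#' candidate. The p-value uses the add-one convention
#' `p = (1 + #\{tau_null >= tau_obs\}) / (n_perm + 1)`, so `p > 0` and the
#' test is exact-valid.
#'
#' @param reference,candidate [rdm()] objects over the same stimulus ids.
#' @param n_perm Number of label randomizations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble: `statistic` (observed tau-a), `p_value`,
#'   `n_resamples`, `method`, `seed`.
#' @export
permutation_test <- function(reference, candidate, n_perm = 10000, seed = 1) {
  stopifnot(inherits(reference, "rdm"), inherits(candidate, "rdm"))
  if (!identical(stimulus_ids(reference), stimulus_ids(candidate))) {
    stop("reference and candidate must share stimulus ids")
  }
  if (n_perm < 100) stop("n_perm must be at least 100")
  n <- nrow(reference)
  ref_v <- utv(reference)
  cand <- unclass(candidate)
  obs <- kendall_tau_a(ref_v, utv(candidate))
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  null_tau <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    kendall_tau_a(ref_v, utv(cand[p, p]))
  }, numeric(1))
  p <- (1 + sum(null_tau >= obs)) / (n_perm + 1)
  tibble::tibble(
    statistic = obs, p_value = p, n_resamples = n_perm,
    method = "stimulus-label randomization", seed = seed
  )
}

# seed handling: per-call streams that restore the caller's RNG state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

stratum_vector <- function(ids, strata) {
  if (is.null(strata)) return(rep("all", length(ids)))
  if (inherits(strata, "stimulus_set") || (is.data.frame(strata) && "id" %in% names(strata))) {
    key <- if ("leaf" %in% names(strata)) strata$leaf else strata[[2]]
    idx <- match(ids, strata$id)
    if (anyNA(idx)) stop("strata table does not cover all stimulus ids")
    return(as.character(key)[idx])
  }
  stopifnot(length(strata) == length(ids))
  as.character(strata)
}

# one stratified resample of stimulus indices (with replacement, sizes kept)
stratified_resample <- function(strata) {
  idx <- integer(length(strata))
  for (s in unique(strata)) {
    pos <- which(strata == s)
    if (length(pos) < 2) stop("stratum '", s, "' has fewer than 2 members")
    idx[pos] <- sample(pos, length(pos), replace = TRUE)
  }
  idx
}

#' Stratified stimulus bootstrap of RDM correlations
#'
#' Resamples stimuli with replacement independently within each category
#' stratum (so the category proportions are identical across resamples),
#' recomputes the tau-a correlation between the reference and each candidate
#' RDM on every resample, and returns the bootstrap distributions and
#' standard errors. When a stimulus is drawn more than once, the off-diagonal
#' cells comparing it with itself are zeros from the original diagonal; these
#' are treated as missing and excluded.
#'
#' @param reference An [rdm()].
#' @param candidates A named list of [rdm()] objects over the same ids.
#' @param strata A [stimulus_set()], a table with `id` and stratum columns,
#'   a vector of stratum labels aligned with the stimulus order, or `NULL`
#'   for unstratified resampling.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return A list with `tau` (n_boot x n_candidates matrix of bootstrap
#'   tau-a values), `se` (per-candidate bootstrap standard errors),
#'   `observed` (tau-a on the original sample), and `seed`.
#' @export
bootstrap_stimuli <- function(reference, candidates, strata = NULL,
                              n_boot = 1000, seed = 1) {
  stopifnot(inherits(reference, "rdm"), length(candidates) >= 1)
  if (n_boot < 100) stop("n_boot must be at least 100")
  ids <- stimulus_ids(reference)
  for (cand in candidates) {
    if (!identical(stimulus_ids(cand), ids)) stop("all RDMs must share stimulus ids")
  }
  if (is.null(names(candidates))) {
    names(candidates) <- sprintf("candidate%d", seq_along(candidates))
  }
  strat <- stratum_vector(ids, strata)
  ref_m <- unclass(reference)
  cand_m <- lapply(candidates, unclass)
  n <- length(ids)
  pi <- pair_index(n)

  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  tau <- matrix(NA_real_, n_boot, length(candidates),
                dimnames = list(NULL, names(candidates)))
  for (b in seq_len(n_boot)) {
    idx <- stratified_resample(strat)
    dup <- idx[pi[, 1]] == idx[pi[, 2]]
    rv <- ref_m[idx, idx][pi]
    rv[dup] <- NA_real_
    for (k in seq_along(cand_m)) {
      cv <- cand_m[[k]][idx, idx][pi]
      cv[dup] <- NA_real_
      tau[b, k] <- kendall_tau_a(rv, cv)
    }
  }
  observed <- vapply(candidates, function(cand) {
    kendall_tau_a(utv(reference), utv(cand))
  }, numeric(1))
  list(
    tau = tau,
    se = apply(tau, 2, stats::sd),
    observed = observed,
    seed = seed
  )
}

#' Pairwise model comparison with FDR control
#'
#' Compares every pair of candidate RDMs in how well they explain the
#' reference RDM. For each pair the bootstrap distribution of the tau-a
#' difference (from a shared stratified stimulus bootstrap) yields a
#' two-sided add-one p-value `2 * min(P(diff <= 0), P(diff >= 0))`; the
#' Benjamini-Hochberg step-up procedure controls the expected false
#' discovery rate across all pairs at `fdr`.
#'
#' @inheritParams bootstrap_stimuli
#' @param fdr Expected false-discovery-rate level (default 0.05).
#' @return A list with `pairs` (tibble: model_a, model_b, tau_a, tau_b,
#'   diff, p_value, p_adjusted, significant), `p_matrix` (symmetric matrix of
#'   raw p-values), and the underlying `bootstrap` object.
#' @export
compare_candidates <- function(reference, candidates, strata = NULL,
                               n_boot = 1000, seed = 1, fdr = 0.05) {
  if (length(candidates) < 2) stop("need at least 2 candidates to compare")
  bs <- bootstrap_stimuli(reference, candidates, strata = strata,
                          n_boot = n_boot, seed = seed)
  nm <- colnames(bs$tau)
  k <- length(nm)
  pm <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  rows <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      d <- bs$tau[, a] - bs$tau[, b]
      p_lo <- (1 + sum(d <= 0)) / (n_boot + 1)
      p_hi <- (1 + sum(d >= 0)) / (n_boot + 1)
      p <- min(1, 2 * min(p_lo, p_hi))
      pm[a, b] <- pm[b, a] <- p
      rows[[length(rows) + 1]] <- tibble::tibble(
        model_a = nm[a], model_b = nm[b],
        tau_a = bs$observed[a], tau_b = bs$observed[b],
        diff = bs$observed[a] - bs$observed[b], p_value = p
      )
    }
  }
  pairs <- dplyr::bind_rows(rows)
  pairs$p_adjusted <- stats::p.adjust(pairs$p_value, method = "BH")
  pairs$significant <- pairs$p_adjusted <= fdr
  list(pairs = pairs, p_matrix = pm, bootstrap = bs)
}

#' Correlate model-level scores
#'
#' Pearson or Spearman correlation between two aligned lists of per-model
#' scores (e.g. IT-resemblance vs. categorization accuracy across models).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return The correlation coefficient.
#' @export
correlate_scores <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired scores")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("scores have zero variance; correlation undefined")
  }
  stats::cor(x, y, method = method)
}
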