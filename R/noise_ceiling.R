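#' Multi-subject ensemble of RDMs
#'
#' @param rdms List of [rdm()] objects over identical stimulus ids (one per
#'   subject; cells may be missing per subject).
#' @param subject_ids Optional subject labels.
#' @return A `subject_ensemble` object.
#' @export
subject_ensemble <- function(rdms, subject_ids = NULL) {
  stopifnot(length(rdms) >= 2)
  ids <- stimulus_ids(rdms[[1]])
  for (r in rdms) {
    stopifnot(inherits(r, "rdm"))
    if (!identical(stimulus_ids(r), ids)) stop("subjects must share stimulus ids")
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("subject%d", seq_along(rdms))
  structure(list(rdms = rdms, subject_ids = subject_ids, stimulus_ids = ids),
            class = "subject_ensemble")
}

#' @export
print.subject_ensemble <- function(x, ...) {
  cat(sprintf("<subject_ensemble: %d subjects, %d stimuli>\n",
              length(x$rdms), length(x$stimulus_ids)))
  invisible(x)
}

# matrix of rank-transformed subject dissimilarity vectors (pairs x subjects)
rank_vectors <- function(ensemble) {
  vapply(ensemble$rdms, function(r) utv(rank_transform(r)),
         numeric(length(ensemble$stimulus_ids) *
                   (length(ensemble$stimulus_ids) - 1) / 2))
}

# Greedy refinement of a consensus ordering. tau-a depends only on the
# candidate's ordering of the cells, so the search space is orderings: we
# repeatedly propose swapping two cells adjacent in the current order and
# accept when the swap raises the mean tau-a across subjects. For an
# adjacent swap only the swapped pair changes relative order, so the gain is
# 2/n0 * sum_s sign(b_s[i] - b_s[j]) - an O(n_subjects) update.
refine_consensus <- function(v0, B, max_iter = 50) {
  m <- length(v0)
  ord <- order(v0, seq_len(m))    # strict ordering; ties broken by index
  for (pass in seq_len(max_iter)) {
    changed <- FALSE
    for (k in seq_len(m - 1)) {
      i <- ord[k]
      j <- ord[k + 1]
      # currently i ranks below j; swapping flips only pair (i, j)
      gain <- sum(sign(B[i, ] - B[j, ]), na.rm = TRUE)
      if (gain > 0) {
        ord[k] <- j
        ord[k + 1] <- i
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ranks <- integer(m)
  ranks[ord] <- seq_len(m)
  ranks
}

mean_tau_to_subjects <- function(candidate_v, B) {
  mean(vapply(seq_len(ncol(B)), function(s) {
    kendall_tau_a(candidate_v, B[, s])
  }, numeric(1)))
}

#' Noise ceiling for RDM correlations
#'
#' Estimates upper and lower bounds on the group-average Kendall tau-a
#' correlation that the (unknown) true model's RDM could achieve with the
#' single-subject RDMs, given inter-subject variability.
#'
#' The upper bound comes from a consensus RDM overfitted to the group: the
#' element-wise mean of the rank-transformed subject RDMs, refined by a
#' greedy local search over cell orderings (adjacent-rank swaps accepted
#' when they raise the mean tau-a) until a full pass accepts no swap or
#' `max_iter` passes elapse. Because the consensus is fitted to all
#' subjects, its mean correlation overestimates the true model's, giving an
#' upper bound. The lower bound is leave-one-subject-out: each subject's
#' RDM is correlated with the average of the other subjects' rank-transformed
#' RDMs, which underestimates the true model's correlation. Missing cells
#' are excluded pairwise per subject.
#'
#' @param ensemble A [subject_ensemble()].
#' @param max_iter Maximum refinement passes for the upper bound.
#' @param tol Unused by the discrete search (kept as a knob for alternative
#'   refiners); convergence is a pass with no accepted swap.
#' @return A one-row tibble: `lower`, `upper`, `n_subjects`, plus the
#'   consensus RDM in the `"consensus"` attribute. A warning is attached
#'   when fewer than 3 subjects are available (the bounds are then weakly
#'   constrained).
#' @export
noise_ceiling <- function(ensemble, max_iter = 50, tol = 0) {
  stopifnot(inherits(ensemble, "subject_ensemble"))
  lower <- lower_bound(ensemble)
  upper <- upper_bound(ensemble, max_iter = max_iter, tol = tol)
  if (length(ensemble$rdms) < 3) {
    warning("noise ceiling estimated from fewer than 3 subjects; ",
            "bounds are weakly constrained")
  }
  out <- tibble::tibble(
    lower = lower, upper = as.numeric(upper), n_subjects = length(ensemble$rdms)
  )
  attr(out, "consensus") <- attr(upper, "consensus")
  out
}

#' Upper bound of the noise ceiling
#'
#' Mean tau-a between an overfitted consensus RDM and the single-subject
#' RDMs; see [noise_ceiling()] for the construction. The returned value is
#' never below the mean tau-a of the unrefined rank-mean initializer.
#'
#' @inheritParams noise_ceiling
#' @return The upper bound (numeric scalar) with the consensus [rdm()] as
#'   attribute `"consensus"`.
#' @export
upper_bound <- function(ensemble, max_iter = 50, tol = 0) {
  stopifnot(inherits(ensemble, "subject_ensemble"))
  B <- rank_vectors(ensemble)
  v0 <- rowMeans(B, na.rm = TRUE)
  v0[is.nan(v0)] <- NA_real_
  ok <- !is.na(v0)
  base_tau <- mean_tau_to_subjects(v0, B)
  refined <- v0
  refined[ok] <- refine_consensus(v0[ok], B[ok, , drop = FALSE],
                                  max_iter = max_iter)
  ref_tau <- mean_tau_to_subjects(refined, B)
  if (ref_tau >= base_tau) {
    best <- refined
    ub <- ref_tau
  } else {
    best <- v0
    ub <- base_tau
  }
  ids <- ensemble$stimulus_ids
  n <- length(ids)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  pi <- pair_index(n)
  d[pi] <- best
  d[pi[, c(2, 1)]] <- best
  diag(d) <- 0
  consensus <- rdm(d, metric = rdm_metric(ensemble$rdms[[1]]))
  structure(ub, consensus = consensus)
}

#' Lower bound of the noise ceiling
#'
#' Leave-one-subject-out: the mean over subjects of the tau-a correlation
#' between each subject's RDM and the element-wise average of the other
#' subjects' rank-transformed RDMs.
#'
#' @inheritParams noise_ceiling
#' @return The lower bound (numeric scalar).
#' @export
lower_bound <- function(ensemble) {
  stopifnot(inherits(ensemble, "subject_ensemble"))
  B <- rank_vectors(ensemble)
  S <- ncol(B)
  taus <- vapply(seq_len(S), function(s) {
    others <- rowMeans(B[, -s, drop = FALSE], na.rm = TRUE)
    others[is.nan(others)] <- NA_real_
    kendall_tau_a(B[, s], others)
  }, numeric(1))
  mean(taus)
}
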