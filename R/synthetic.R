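#' Specification for synthetic object-vision data
#'
#' Describes the shape of a simulated study: a balanced hierarchical
#' stimulus set (by default 96 stimuli — 48 animates split into 24 faces and
#' 24 bodies, each half human and half non-human, and 48 inanimates split
#' into 24 natural and 24 artificial), per-category cluster tightness (how
#' strongly a category's members are pulled together in feature space),
#' feature dimensionality and noise, and a subject ensemble size and noise
#' level.
#'
#' @param n_stimuli Number of stimuli, divisible by 8 (default 96).
#' @param tightness Named numeric vector of cluster-tightness values (signal
#'   sd contributed by each category's prototype, in units of the feature
#'   noise sd); names from [category_names()]. Unnamed categories default
#'   to 0. A single unnamed number applies to all ten categories.
#' @param n_features Number of model features (default 100).
#' @param feature_noise_sd I.i.d. Gaussian feature noise sd (default 1).
#' @param n_subjects Number of subjects for ensembles (default 4).
#' @param subject_noise_sd RDM-cell noise sd for subject ensembles
#'   (default 0.15).
#' @param seed Base seed (default 1).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_stimuli = 96, tightness = 0, n_features = 100,
                           feature_noise_sd = 1, n_subjects = 4,
                           subject_noise_sd = 0.15, seed = 1) {
  tight <- stats::setNames(rep(0, length(category_names())), category_names())
  if (is.null(names(tightness))) {
    stopifnot(length(tightness) == 1)
    tight[] <- tightness
  } else {
    bad <- setdiff(names(tightness), category_names())
    if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
    tight[names(tightness)] <- tightness
  }
  if (any(tight < 0)) stop("tightness values must be >= 0")
  if (feature_noise_sd < 0 || subject_noise_sd < 0) stop("sds must be >= 0")
  if (n_features < 2) stop("n_features must be at least 2")
  structure(
    list(
      n_stimuli = n_stimuli, tightness = tight, n_features = n_features,
      feature_noise_sd = feature_noise_sd, n_subjects = n_subjects,
      subject_noise_sd = subject_noise_sd, seed = seed,
      stimuli = default_stimulus_set(n_stimuli)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec: %d stimuli, %d features, %d subjects, seed %d>\n",
    x$n_stimuli, x$n_features, x$n_subjects, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic model feature matrix
#'
#' Features are a sum of category-prototype signals plus i.i.d. Gaussian
#' noise: every category with non-zero tightness contributes a random
#' prototype direction (drawn once per category) scaled by its tightness,
#' added to the rows of its member stimuli. Because subcategory prototypes
#' add to their parents' (a human face carries the animate, face and
#' human-face prototypes), members of tight categories end up close
#' together — shrunk toward the shared prototype — which is exactly the
#' cluster geometry the category-cluster model measures. Deterministic
#' given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param model_name Label for the generated representation.
#' @param seed Optional seed override.
#' @return A [feature_matrix()].
#' @export
generate_model_features <- function(spec, model_name = "synthetic_model",
                                    seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ss <- spec$stimuli
  n <- spec$n_stimuli
  p <- spec$n_features
  x <- matrix(stats::rnorm(n * p, sd = spec$feature_noise_sd), n, p)
  for (k in category_names()) {
    tk <- spec$tightness[[k]]
    if (tk > 0) {
      proto <- stats::rnorm(p, sd = tk)
      member <- ss[[k]]
      x[member, ] <- x[member, ] + matrix(proto, sum(member), p, byrow = TRUE)
    }
  }
  feature_matrix(x, ids = ss$id, model_name = model_name)
}

#' Generate a multi-subject RDM ensemble around a true RDM
#'
#' Each subject's RDM is the shared true RDM plus independent symmetric
#' zero-diagonal Gaussian cell noise, clipped to the metric's valid range
#' (\[0, 2\] for correlation distance, \[0, 4\] for the squared-Euclidean
#' metric). Missing cells of the true RDM stay missing.
#'
#' @param true_rdm An [rdm()].
#' @param n_subjects Number of subjects (default 4).
#' @param noise_sd Cell noise sd (default 0.15).
#' @param seed Integer seed.
#' @return A [subject_ensemble()].
#' @export
generate_subject_ensemble <- function(true_rdm, n_subjects = 4,
                                      noise_sd = 0.15, seed = 1) {
  stopifnot(inherits(true_rdm, "rdm"), noise_sd >= 0, n_subjects >= 2)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- nrow(true_rdm)
  pi <- pair_index(n)
  v0 <- utv(true_rdm)
  hi <- if (rdm_metric(true_rdm) == "correlation") 2 else 4
  rdms <- lapply(seq_len(n_subjects), function(s) {
    v <- v0 + stats::rnorm(length(v0), sd = noise_sd)
    v <- pmin(pmax(v, 0), hi)
    v[is.na(v0)] <- NA_real_
    d <- matrix(NA_real_, n, n, dimnames = dimnames(true_rdm))
    d[pi] <- v
    d[pi[, c(2, 1)]] <- v
    diag(d) <- 0
    rdm(d, metric = rdm_metric(true_rdm))
  })
  subject_ensemble(rdms)
}

#' Generate a ground-truth non-negative mixture RDM
#'
#' Reference RDM equal to the weighted sum of the component RDMs plus
#' optional symmetric Gaussian cell noise — the oracle input for weight
#' recovery.
#'
#' @param components A [component_set()].
#' @param true_weights Non-negative numeric weights, one per component.
#' @param cell_noise_sd Gaussian cell noise sd (default 0).
#' @param seed Integer seed.
#' @return An [rdm()] with attribute `"true_weights"`.
#' @export
generate_mixture <- function(components, true_weights, cell_noise_sd = 0,
                             seed = 1) {
  stopifnot(inherits(components, "component_set"))
  w <- as.numeric(true_weights)
  if (length(w) != length(components$rdms)) {
    stop("need one weight per component")
  }
  if (any(w < 0)) stop("mixture weights must be non-negative")
  ids <- components$stimulus_ids
  n <- length(ids)
  A <- vapply(components$rdms, utv, numeric(n * (n - 1) / 2))
  if (is.null(dim(A))) A <- matrix(A, ncol = length(w))
  v <- drop(A %*% w)
  if (cell_noise_sd > 0) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    v <- pmax(v + stats::rnorm(length(v), sd = cell_noise_sd), 0)
  }
  pi <- pair_index(n)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  d[pi] <- v
  d[pi[, c(2, 1)]] <- v
  diag(d) <- 0
  structure(rdm(d, metric = "sqeuclidean"), true_weights = w)
}
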