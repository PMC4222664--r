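# Independent oracles, kept deliberately naive.

# O(m^2) Kendall tau-a by exhaustive pair enumeration
brute_tau_a <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  m <- length(x)
  s <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s / (m * (m - 1) / 2)
}

# per-pair Pearson correlation distance, straight from the formula
brute_corr_rdm <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- 1 - stats::cor(x[i, ], x[j, ])
    }
  }
  d
}

# a random valid correlation-distance RDM over n stimuli
random_rdm <- function(n, seed = NULL, n_features = 20) {
  if (!is.null(seed)) set.seed(seed)
  compute_rdm(feature_matrix(matrix(stats::rnorm(n * n_features), n, n_features),
                             ids = sprintf("stim%03d", seq_len(n))))
}

# block-structured RDM: within-category dissimilarity `within`, rest `between`
block_rdm <- function(stimuli, category, within = 0.4, between = 1.0) {
  n <- nrow(stimuli)
  member <- stimuli[[category]]
  d <- matrix(between, n, n)
  d[member, member] <- within
  d[!member, !member] <- within
  diag(d) <- 0
  rdm(d, ids = stimuli$id)
}

# canonical upper-triangle values via the public vectorizer
utv_for_test <- function(r) vectorize(r)$value
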