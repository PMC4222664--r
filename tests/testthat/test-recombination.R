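make_models <- function(n_models, n, p, seed) {
  set.seed(seed)
  lapply(seq_len(n_models), function(k) {
    feature_matrix(matrix(rnorm(n * p), n, p),
                   ids = sprintf("stim%03d", seq_len(n)),
                   model_name = sprintf("m%d", k))
  })
}

test_that("combining models gives equal-width, equal-variance blocks", {
  models <- make_models(4, 20, 30, seed = 1)
  combi <- combine_models(models, n_pcs = 10)
  expect_equal(ncol(combi), 40)
  # per-block total variance is equal across blocks
  vars <- vapply(seq_len(4), function(b) {
    block <- unclass(combi)[, ((b - 1) * 10 + 1):(b * 10)]
    sum(apply(block, 2, var))
  }, numeric(1))
  expect_lt(max(vars) - min(vars), 1e-8)
})

test_that("a single combined model preserves its PC geometry", {
  models <- make_models(1, 15, 25, seed = 2)
  combi <- combine_models(models, n_pcs = 10)
  expect_equal(ncol(combi), 10)
  pc <- prcomp(unclass(models[[1]]), center = TRUE)$x[, 1:10]
  r1 <- compute_rdm(feature_matrix(pc, ids = rownames(models[[1]])))
  r2 <- compute_rdm(combi)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("n_pcs is capped by the stimulus count", {
  models <- make_models(2, 10, 30, seed = 3)
  expect_error(combine_models(models, n_pcs = 10), "non-zero eigenvalues")
  expect_silent(combine_models(models, n_pcs = 9))
})

test_that("discriminant decision values classify separable held-out clusters", {
  set.seed(4)
  p <- 10
  mu <- rnorm(p) * 4
  draw <- function(n, sgn, prefix) {
    feature_matrix(
      t(replicate(n, sgn * mu + rnorm(p, sd = 0.5))),
      ids = sprintf("%s%03d", prefix, seq_len(n))
    )
  }
  train <- feature_matrix(rbind(unclass(draw(30, 1, "tr_a")),
                                unclass(draw(30, -1, "tr_b"))),
                          ids = sprintf("tr%03d", 1:60))
  labels <- rep(c("pos", "neg"), each = 30)
  test <- feature_matrix(rbind(unclass(draw(20, 1, "te_a")),
                               unclass(draw(20, -1, "te_b"))),
                         ids = sprintf("te%03d", 1:40))
  dv <- train_discriminant(train, labels, test)
  expect_equal(ncol(dv), 1)
  truth <- rep(c(1, -1), each = 20)
  signs <- sign(drop(unclass(dv)))
  agree <- max(mean(signs == truth), mean(signs == -truth))
  expect_gte(agree, 0.95)
})

test_that("duplicating every training point leaves the max-margin solution unchanged", {
  # margin invariance holds when the margin term dominates (separable data,
  # large cost): the support set and hence the decision function are
  # determined by the margin geometry, which duplication does not move
  set.seed(5)
  mu <- rnorm(5) * 4
  labels <- rep(c("a", "b"), 20)
  x <- t(sapply(labels == "a", function(p) (if (p) mu else -mu) +
                                             rnorm(5, sd = 0.4)))
  train <- feature_matrix(x, ids = sprintf("tr%03d", 1:40))
  test <- feature_matrix(matrix(rnorm(10 * 5), 10, 5),
                         ids = sprintf("te%03d", 1:10))
  dv1 <- train_discriminant(train, labels, test, cost = 1000)
  doubled <- feature_matrix(rbind(x, x), ids = sprintf("tr%03d", 1:80))
  dv2 <- train_discriminant(doubled, rep(labels, 2), test, cost = 1000)
  expect_equal(unclass(dv1), unclass(dv2), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("training/test overlap and single-class training are rejected", {
  train <- feature_matrix(matrix(rnorm(20 * 4), 20, 4),
                          ids = sprintf("s%03d", 1:20))
  test <- feature_matrix(matrix(rnorm(5 * 4), 5, 4),
                         ids = sprintf("s%03d", 18:22))
  expect_error(train_discriminant(train, rep(c("a", "b"), 10), test),
               "leakage")
  test_ok <- feature_matrix(matrix(rnorm(5 * 4), 5, 4),
                            ids = sprintf("t%03d", 1:5))
  expect_error(train_discriminant(train, rep("a", 20), test_ok),
               "two classes")
})

test_that("three category discriminants yield three single-feature RDMs", {
  set.seed(6)
  ss <- default_stimulus_set(24)
  train <- feature_matrix(matrix(rnorm(48 * 12), 48, 12),
                          ids = sprintf("tr%03d", 1:48))
  train_ss <- default_stimulus_set(48)
  test <- feature_matrix(matrix(rnorm(24 * 12), 24, 12), ids = ss$id)
  tasks <- list(
    animate = train_ss$animate,
    face = train_ss$face,
    body = train_ss$body
  )
  rdms <- lapply(tasks, function(lab) {
    compute_rdm(train_discriminant(train, lab, test), metric = "sqeuclidean")
  })
  expect_length(rdms, 3)
  for (r in rdms) expect_s3_class(r, "rdm")
})

test_that("exact mixtures are recovered by the non-negative fit", {
  set.seed(7)
  models <- make_models(3, 18, 25, seed = 7)
  comps <- component_set(setNames(models, c("a", "b", "c")))
  # reference = component b exactly
  w <- nnls_weights(comps, comps$rdms[["b"]])
  expect_equal(w$weight, c(0, 1, 0), tolerance = 1e-8)

  mix <- generate_mixture(comps, c(0.3, 0.7, 0))
  w2 <- nnls_weights(comps, mix)
  expect_equal(w2$weight, c(0.3, 0.7, 0), tolerance = 1e-6)
})

test_that("the two-component fit matches a grid-search oracle", {
  set.seed(8)
  models <- make_models(2, 14, 20, seed = 8)
  comps <- component_set(setNames(models, c("a", "b")))
  ref <- generate_mixture(comps, c(0.4, 0.6), cell_noise_sd = 0.05, seed = 9)
  w <- nnls_weights(comps, ref)
  # oracle: dense grid over the two weights
  A <- cbind(utv_for_test(comps$rdms[[1]]), utv_for_test(comps$rdms[[2]]))
  b <- utv_for_test(ref)
  grid <- seq(0, 1.5, by = 0.005)
  best <- c(NA, NA)
  best_rss <- Inf
  for (w1 in grid) {
    r <- b - A[, 1] * w1
    # optimal w2 given w1, clipped at 0
    w2 <- max(0, sum(A[, 2] * r) / sum(A[, 2]^2))
    rss <- sum((r - A[, 2] * w2)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- c(w1, w2)
    }
  }
  expect_equal(w$weight, best, tolerance = 0.01)
})

test_that("KKT: components anti-correlated with the residual get weight zero", {
  set.seed(10)
  models <- make_models(3, 16, 20, seed = 10)
  comps <- component_set(setNames(models, c("a", "b", "neg")))
  ref <- generate_mixture(component_set(setNames(models[1:2], c("a", "b"))),
                          c(0.5, 0.5))
  w <- nnls_weights(comps, ref)
  A <- sapply(comps$rdms, utv_for_test)
  resid <- utv_for_test(ref) - drop(A %*% w$weight)
  for (k in which(w$weight == 0)) {
    expect_lte(sum(A[, k] * resid), 1e-8)   # gradient must be non-positive
  }
  for (k in which(w$weight > 0)) {
    expect_lt(abs(sum(A[, k] * resid)), 1e-6)
  }
})

test_that("weighted-feature RDM equals the weighted sum of component RDMs", {
  # concatenating sqrt(w_k)-scaled normalized feature blocks and taking the
  # squared Euclidean distance must reproduce sum_k w_k RDM_k
  set.seed(11)
  for (case in 1:10) {
    n <- sample(8:16, 1)
    K <- sample(2:4, 1)
    models <- make_models(K, n, 12, seed = 100 + case)
    w <- runif(K, 0, 2)
    comps <- component_set(setNames(models, sprintf("m%d", 1:K)))
    weighted_sum <- Reduce(`+`, Map(function(r, wk) wk * unclass(r),
                                    comps$rdms, w))
    norm_block <- function(m) {
      x <- unclass(m)
      ctr <- x - rowMeans(x)
      ctr / sqrt(rowSums(ctr^2))
    }
    concat <- do.call(cbind, Map(function(m, wk) sqrt(wk) * norm_block(m),
                                 models, w))
    direct <- as.matrix(dist(concat))^2
    expect_lt(max(abs(direct - weighted_sum)), 1e-8)
  }
})

test_that("crossvalidated assembly reproduces a single-component reference", {
  models <- make_models(2, 16, 20, seed = 12)
  comps <- component_set(setNames(models, c("a", "b")))
  ref <- comps$rdms[["a"]]
  ss <- default_stimulus_set(16)
  cv <- crossvalidated_weighted_rdm(comps, ref, holdout_size = 4,
                                    strata = ss$animate, seed = 13)
  expect_equal(unclass(cv), unclass(ref), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(cv, "coverage"), 1)
  expect_gte(attr(cv, "n_folds"), 1)
})

test_that("every 8-stimulus holdout contributes exactly 28 predicted cells", {
  # structural: C(8,2) = 28 holdout-internal pairs per fold
  expect_equal(choose(8, 2), 28)
  models <- make_models(2, 24, 20, seed = 14)
  comps <- component_set(setNames(models, c("a", "b")))
  ref <- generate_mixture(comps, c(0.5, 0.5))
  ss <- default_stimulus_set(24)
  cv <- crossvalidated_weighted_rdm(comps, ref, holdout_size = 8,
                                    strata = ss$animate, seed = 15,
                                    max_folds = 5000)
  fw <- attr(cv, "fold_weights")
  expect_equal(ncol(fw), 2)
  expect_true(all(fw >= 0))
})

test_that("weight recovery stays accurate under cell noise", {
  set.seed(16)
  rel_err <- replicate(30, {
    models <- make_models(5, 20, 15, seed = sample.int(1e6, 1))
    comps <- component_set(setNames(models, sprintf("c%d", 1:5)))
    w_true <- runif(5, 0.2, 1)
    ref_clean <- generate_mixture(comps, w_true)
    sd_ref <- sd(utv_for_test(ref_clean))
    ref <- generate_mixture(comps, w_true, cell_noise_sd = 0.1 * sd_ref,
                            seed = sample.int(1e6, 1))
    w_hat <- nnls_weights(comps, ref)$weight
    median(abs(w_hat - w_true) / w_true)
  })
  expect_lt(median(rel_err), 0.25)
})
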