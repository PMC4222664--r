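test_that("the category design has ten predictors plus a constant", {
  ss <- default_stimulus_set(96)
  cm <- build_category_model(ss)
  expect_equal(ncol(cm$design), 11)
  expect_equal(colnames(cm$design)[11], "constant")
  expect_true(all(cm$design[, 11] == 1))
  # a category with k members marks exactly k(k-1)/2 pairs
  for (k in category_names()) {
    nk <- sum(ss[[k]])
    expect_equal(sum(cm$design[, k] != 0), choose(nk, 2))
    expect_true(all(cm$design[, k] %in% c(-1, 0)))
  }
  # complementary categories mark disjoint cells
  expect_equal(sum(cm$design[, "animate"] != 0 & cm$design[, "inanimate"] != 0), 0)
})

test_that("an RDM built from the predictors is recovered exactly", {
  ss <- default_stimulus_set(24)
  cm <- build_category_model(ss)
  beta_true <- c(0.5, 0.2, 0.3, 0, 0, 0.1, 0, 0, 0.15, 0.05, 1.2)
  v <- drop(cm$design %*% beta_true)
  r <- unvectorize(tibble::tibble(
    i = ss$id[rep(1:23, times = 23:1)],
    j = unlist(lapply(1:23, function(k) ss$id[(k + 1):24])),
    value = v
  ))
  fit <- fit_category_model(r, cm)
  expect_equal(fit$cci, 1, tolerance = 1e-10)
  expect_lt(max(abs(utv_for_test(fit$residual))), 1e-10)
  expect_equal(unclass(fit$fitted) + unclass(fit$residual), unclass(r),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a two-category block RDM loads on the animacy predictors only", {
  ss <- default_stimulus_set(24)
  r <- block_rdm(ss, "animate", within = 0.4, between = 1.0)
  fit <- fit_category_model(r, build_category_model(ss))
  # with the -1 coding, tighter cluster -> larger positive beta
  expect_gt(fit$betas["animate"], 0.1)
  expect_gt(fit$betas["inanimate"], 0.1)
  expect_lt(abs(fit$betas["human_face"]), 1e-8)
  expect_lt(abs(fit$betas["nonhuman_face"]), 1e-8)
  expect_equal(fit$cci, 1, tolerance = 1e-10)
})

test_that("cci lies in [0,1] and noise RDMs have cci near zero", {
  ss <- default_stimulus_set(96)
  cm <- build_category_model(ss)
  set.seed(20)
  ccis <- replicate(200, {
    v <- rnorm(choose(96, 2))
    A <- cm$design
    f <- drop(A %*% qr.coef(qr(A), v))
    stats::cor(f, v)^2
  })
  expect_lt(mean(ccis), 0.05)

  r <- random_rdm(24, seed = 21)
  r <- rdm(unclass(r), ids = default_stimulus_set(24)$id)
  fit <- fit_category_model(r, build_category_model(default_stimulus_set(24)))
  expect_gte(fit$cci, 0)
  expect_lte(fit$cci, 1)
})

test_that("fit residuals are orthogonal to the predictors on valid cells", {
  ss <- default_stimulus_set(24)
  cm <- build_category_model(ss)
  r <- random_rdm(24, seed = 22)
  r <- rdm(unclass(r), ids = ss$id)
  fit <- fit_category_model(r, cm)
  res <- utv_for_test(fit$residual)
  for (k in seq_len(ncol(cm$design))) {
    expect_lt(abs(sum(res * cm$design[, k])), 1e-8)
  }
})

test_that("adding feature noise does not raise expected cci", {
  ss <- default_stimulus_set(24)
  cm <- build_category_model(ss)
  set.seed(23)
  cci_clean <- numeric(60)
  cci_noisy <- numeric(60)
  for (run in 1:60) {
    spec <- synthetic_spec(24, tightness = c(animate = 1.2), n_features = 40,
                           seed = 400 + run)
    fm <- generate_model_features(spec)
    cci_clean[run] <- fit_category_model(compute_rdm(fm), cm)$cci
    noisy <- feature_matrix(unclass(fm) + matrix(rnorm(length(fm), sd = 2),
                                                 nrow(fm), ncol(fm)),
                            ids = rownames(fm))
    cci_noisy[run] <- fit_category_model(compute_rdm(noisy), cm)$cci
  }
  expect_lt(mean(cci_noisy), mean(cci_clean))
})

test_that("categoricality randomization test separates blocked from random RDMs", {
  ss <- default_stimulus_set(24)
  blocked <- block_rdm(ss, "animate")
  res <- categoricality_test(blocked, ss, n_rand = 199, seed = 24)
  expect_equal(res$p_value, 1 / 200)

  # label permutation leaves the constant predictor untouched
  set.seed(25)
  cm1 <- build_category_model(ss)
  cm2 <- build_category_model(permute_labels(ss))
  expect_equal(cm1$design[, "constant"], cm2$design[, "constant"])
})

test_that("categoricality p-values are calibrated under label independence", {
  ss <- default_stimulus_set(16)
  set.seed(26)
  ps <- replicate(60, {
    r <- random_rdm(16, seed = sample.int(1e6, 1))
    r <- rdm(unclass(r), ids = ss$id)
    categoricality_test(r, ss, n_rand = 99, seed = sample.int(1e6, 1))$p_value
  })
  # uniform-ish: no pile-up at the low end
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 1 / 200)
})

test_that("clustering-strength CIs exclude zero for truly blocked categories", {
  ss <- default_stimulus_set(24)
  blocked <- block_rdm(ss, "animate")
  ci <- clustering_strength_ci(blocked, ss, n_boot = 300, seed = 27)
  an <- ci[ci$category == "animate", ]
  expect_gt(an$ci_low, 0)
  hf <- ci[ci$category == "human_face", ]
  expect_lte(hf$ci_low, 0)
  expect_gte(hf$ci_high, 0)
  # bonferroni scaling
  ci2 <- clustering_strength_ci(blocked, ss, n_boot = 300, seed = 27,
                                bonferroni = 10)
  expect_equal(ci2$p_adjusted, pmin(1, ci2$p_value * 10))
})

test_that("CI width shrinks with more stimuli", {
  width_at <- function(n) {
    ss <- default_stimulus_set(n)
    set.seed(n + 1)
    spec <- synthetic_spec(n, tightness = c(animate = 1), n_features = 60,
                           seed = n)
    r <- compute_rdm(generate_model_features(spec))
    ci <- clustering_strength_ci(r, ss, n_boot = 300, seed = 28)
    an <- ci[ci$category == "animate", ]
    an$ci_high - an$ci_low
  }
  expect_lt(width_at(64), width_at(16))
})

test_that("noise equating hits its target and degrades categoricality", {
  spec <- synthetic_spec(24, tightness = c(animate = 1.5), n_features = 50,
                         seed = 30)
  fm <- generate_model_features(spec)
  # target 1 -> no noise added
  eq1 <- equate_noise(fm, target_q = 1)
  expect_equal(attr(eq1, "alpha"), 0)
  expect_equal(unclass(eq1), unclass(compute_rdm(fm)), ignore_attr = TRUE)

  eq <- equate_noise(fm, target_q = 0.5, seed = 31)
  expect_lte(abs(attr(eq, "achieved_q") - 0.5), 0.01)

  cm <- build_category_model(spec$stimuli)
  cci_clean <- fit_category_model(compute_rdm(fm), cm)$cci
  cci_eq <- fit_category_model(eq, cm)$cci
  expect_lt(cci_eq, cci_clean)
})

test_that("instantiation agreement falls monotonically with the noise scale", {
  spec <- synthetic_spec(16, tightness = c(animate = 1), n_features = 30,
                         seed = 32)
  fm <- generate_model_features(spec)
  qs <- vapply(c(0.9, 0.6, 0.35), function(tq) {
    attr(equate_noise(fm, target_q = tq, seed = 33), "alpha")
  }, numeric(1))
  expect_true(all(diff(qs) > 0))  # lower target q needs more noise
})
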