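test_that("correlation-distance RDM matches an independent per-pair Pearson computation", {
  set.seed(11)
  x <- matrix(c(
    0.2, 1.4, -0.7, 2.1,
    -1.0, 0.3, 0.9, -0.4,
    1.1, -2.2, 0.5, 0.8
  ), nrow = 3, byrow = TRUE)
  fm <- feature_matrix(x, ids = c("a", "b", "c"))
  r <- compute_rdm(fm)
  expect_lt(max(abs(unclass(r) - brute_corr_rdm(x))), 1e-12)
})

test_that("identical and anticorrelated patterns hit the metric's endpoints", {
  base <- c(1, 3, 2, 5)
  x <- rbind(base, base, -(base - mean(base)) + 7)
  r <- compute_rdm(feature_matrix(x, ids = c("a", "b", "c")))
  expect_equal(r["a", "b"], 0)
  expect_equal(r["a", "c"], 2)
})

test_that("RDMs are symmetric with zero diagonal for random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    fm <- feature_matrix(matrix(rnorm(n * 8), n, 8))
    for (metric in c("correlation", "sqeuclidean")) {
      r <- compute_rdm(fm, metric = metric)
      expect_equal(unclass(r), t(unclass(r)))
      expect_equal(diag(r), setNames(rep(0, n), rownames(r)))
      expect_true(all(r >= 0))
    }
  }
})

test_that("the two metrics agree after the factor-2 rescaling", {
  for (seed in 1:10) {
    set.seed(seed)
    fm <- feature_matrix(matrix(rnorm(60), 10, 6))
    r1 <- compute_rdm(fm, metric = "correlation")
    r2 <- compute_rdm(fm, metric = "sqeuclidean")
    expect_lt(max(abs(unclass(r2) - 2 * unclass(r1))), 1e-10)
  }
})

test_that("degenerate feature inputs produce informative errors", {
  x <- matrix(rnorm(12), 4, 3)
  x[2, ] <- 5  # constant pattern
  fm <- feature_matrix(x, ids = c("a", "b", "c", "d"))
  expect_error(compute_rdm(fm), "stimulus b")
  one_col <- feature_matrix(matrix(rnorm(4), 4, 1), ids = letters[1:4])
  expect_error(compute_rdm(one_col, metric = "correlation"), "single-feature")
  expect_s3_class(compute_rdm(one_col, metric = "sqeuclidean"), "rdm")
})

test_that("vectorize yields the canonical upper triangle and round-trips", {
  r <- random_rdm(4, seed = 1)
  v <- vectorize(r)
  expect_equal(nrow(v), 6)
  ids <- rownames(r)
  expect_equal(v$i, ids[c(1, 1, 1, 2, 2, 3)])
  expect_equal(v$j, ids[c(2, 3, 4, 3, 4, 4)])
  back <- unvectorize(v, metric = "correlation")
  expect_equal(unclass(back), unclass(r))

  # symmetric missing cells mask exactly one pair
  m <- unclass(r)
  m[1, 3] <- m[3, 1] <- NA
  r2 <- rdm(m)
  v2 <- vectorize(r2)
  expect_equal(sum(!v2$valid), 1)
  expect_equal(unclass(unvectorize(v2)), unclass(r2))
})

test_that("embedding into a larger id set fills absent cells with missings", {
  r <- random_rdm(3, seed = 2)
  target <- c(rownames(r), "x1", "x2")
  big <- embed_rdm(r, target)
  expect_equal(nrow(big), 5)
  v <- vectorize(big)
  expect_equal(sum(v$valid), 3)   # 3 of the 10 pairs survive
  expect_equal(unclass(subset_rdm(big, rownames(r))), unclass(r))

  # identity embedding
  expect_equal(unclass(embed_rdm(r, rownames(r))), unclass(r))
  # unknown id in the rdm -> error
  expect_error(embed_rdm(r, c("x1", "x2", "x3")), "absent")
})

test_that("a 92-stimulus RDM embeds into a 96-id set with all new-id cells missing", {
  full <- default_stimulus_set(96)
  r92 <- random_rdm(96, seed = 3)
  drop_ids <- full$id[c(5, 20, 60, 90)]
  r_sub <- subset_rdm(r92, setdiff(full$id, drop_ids))
  big <- embed_rdm(r_sub, full$id)
  expect_equal(dim(big), c(96, 96))
  miss <- is.na(unclass(big))
  expect_true(all(miss[drop_ids, setdiff(full$id, drop_ids)]))
  v <- vectorize(big)
  expect_equal(sum(v$valid), choose(92, 2))
  expect_equal(sum(!v$valid), choose(96, 2) - choose(92, 2))
})

test_that("subsetting keeps the principal submatrix", {
  ss <- default_stimulus_set(96)
  r <- random_rdm(96, seed = 4)
  ids <- stimulus_set(rownames(r), ss$leaf)  # align labels to generated ids
  anim <- subset_rdm(r, ids$id[ids$animate])
  expect_equal(nrow(anim), 48)
  expect_equal(unclass(subset_rdm(r, rownames(r))), unclass(r))
  trip <- rownames(r)[c(2, 9, 40)]
  expect_equal(unclass(subset_rdm(r, trip)),
               unclass(r)[trip, trip], ignore_attr = TRUE)
  expect_error(subset_rdm(r, rownames(r)[1:2]), "fewer than 3")
})

test_that("rank transform uses average ranks and is idempotent", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 0.3
  d[1, 3] <- d[3, 1] <- 0.9
  d[2, 3] <- d[3, 2] <- 0.5
  r <- rank_transform(rdm(d))
  expect_equal(utv_for_test(r), c(1, 3, 2))

  # ties share the average rank
  d[2, 3] <- d[3, 2] <- 0.3
  r2 <- rank_transform(rdm(d))
  expect_equal(utv_for_test(r2), c(1.5, 3, 1.5))

  # idempotence on a random RDM
  rr <- random_rdm(10, seed = 5)
  once <- rank_transform(rr)
  expect_equal(unclass(rank_transform(once)), unclass(once))

  # missing cells stay missing
  m <- unclass(rr)
  m[1, 2] <- m[2, 1] <- NA
  rt <- rank_transform(rdm(m))
  expect_true(is.na(unclass(rt)[1, 2]))
  expect_equal(sort(utv_for_test(rt)[!is.na(utv_for_test(rt))]),
               seq_len(choose(10, 2) - 1))
})

test_that("RDM and feature files round-trip through delimited text", {
  r <- random_rdm(6, seed = 6)
  m <- unclass(r)
  m[2, 5] <- m[5, 2] <- NA
  r <- rdm(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdm(r, path)
  back <- read_rdm(path)
  expect_equal(unclass(back), unclass(r), tolerance = 1e-12)

  fm <- feature_matrix(matrix(rnorm(20), 5, 4), model_name = "toy")
  fpath <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, fpath)
  fback <- read_features(fpath, model_name = "toy")
  expect_equal(unclass(fback), unclass(fm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(fback), rownames(fm))
})
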