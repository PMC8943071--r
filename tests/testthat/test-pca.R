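test_that("unfolding keeps shapes and refolding round-trips exactly", {
  set.seed(41)
  cubes <- list(random_cube(8L, 6L, 20L), random_cube(8L, 6L, 20L))
  unf <- unfold_cubes(cubes, 20L)
  expect_equal(dim(unf$matrix), c(96L, 20L))
  expect_equal(nrow(unf$index), 96L)
  back <- refold_cubes(unf)
  for (l in 1:2)
    expect_equal(back[[l]]$values, cubes[[l]]$values, tolerance = 1e-14)
  # constant cube gives constant rows
  cc <- profile_cube(rep(2.5, 20), m = 8L, n = 6L)
  u2 <- unfold_cubes(list(cc), 20L)
  expect_true(all(u2$matrix == 2.5))
  expect_error(unfold_cubes(list(cubes[[1]], random_cube(4L, 3L, 20L))),
               "lateral shape")
})

test_that("PCA recovers rank-1 structure and centers scores", {
  set.seed(42)
  d <- rnorm(10)
  x <- outer(rnorm(15), d)              # rank 1
  m <- fit_pca(x)
  expect_equal(m$ratios[1], 1, tolerance = 1e-12)
  expect_true(all(m$ratios[-1] < 1e-12))
  # score of the mean row is the zero vector
  sc <- sweep(matrix(colMeans(x), 1), 2, m$mean) %*% m$loadings
  expect_lt(max(abs(sc)), 1e-10)
  expect_error(fit_pca(matrix(3, 5, 4)), "zero variance")
})

test_that("PCA matches a covariance eigendecomposition up to column sign", {
  set.seed(43)
  x <- matrix(rnorm(15), 5, 3) %*% diag(c(3, 1, 0.3))
  m <- fit_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(m$ratios, ev$values / sum(ev$values), tolerance = 1e-12)
  for (k in 1:3) {
    dot <- abs(sum(m$loadings[, k] * ev$vectors[, k]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  # orthonormal loadings, nonincreasing ratios in [0, 1]
  expect_lt(max(abs(crossprod(m$loadings) - diag(3))), 1e-8)
  expect_true(all(diff(m$ratios) <= 1e-15))
  expect_true(all(m$ratios >= 0 & m$ratios <= 1))
})

test_that("component selection follows the strict cumulative-ratio rule", {
  expect_equal(select_components(c(0.6, 0.3, 0.1), 0.8), 2L)
  # spectrum whose first six ratios sum to 0.83
  ratios <- c(0.20, 0.15, 0.14, 0.12, 0.11, 0.11, 0.09, 0.08)
  expect_equal(sum(ratios[1:6]), 0.83, tolerance = 1e-12)
  expect_equal(select_components(ratios, 0.80), 6L)
  expect_equal(select_components(rep(0.25, 4), 0.999), 4L)
  expect_error(select_components(c(0.6, 0.4), 1.2), "threshold")
})

test_that("two-stage features separate well-separated classes", {
  src <- small_cohort_source(contrast = 0.5, seed = 44L, nb = 6L, nm = 6L)
  model <- extract_features(src$cubes, k_final = 4L)
  expect_equal(dim(model$features), c(12L, 4L))
  fit <- MASS::lda(model$features, grouping = src$labels)
  acc <- mean(predict(fit)$class == src$labels)
  expect_equal(acc, 1)
})

test_that("projection applies training statistics only and is exact on training data", {
  src <- small_cohort_source(contrast = 0.3, seed = 45L, nb = 5L, nm = 5L)
  model <- extract_features(src$cubes, k_final = 3L)
  reproj <- project_features(model, src$cubes)
  expect_equal(reproj, model$features, tolerance = 1e-10)
  # the composed two-stage map is linear: held-out projection equals the
  # explicit matrix algebra done independently
  unf <- unfold_cubes(src$cubes[1], model$target_depth_samples)
  s1 <- sweep(unf$matrix, 2, model$stage1$mean) %*%
    model$stage1$loadings[, seq_len(model$k1), drop = FALSE]
  row <- matrix(as.vector(t(s1)), 1)
  s2 <- sweep(row, 2, model$stage2$mean) %*%
    model$stage2$loadings[, seq_len(model$k_final), drop = FALSE]
  expect_equal(unname(project_features(model, src$cubes[1])), unname(s2),
               tolerance = 1e-10)
})

test_that("feature extraction is equivariant under lesion permutation", {
  src <- small_cohort_source(contrast = 0.3, seed = 46L, nb = 4L, nm = 4L)
  model <- extract_features(src$cubes, k_final = 3L)
  perm <- c(3L, 1L, 4L, 2L, 7L, 5L, 8L, 6L)
  model_p <- extract_features(src$cubes[perm], k_final = 3L)
  expect_equal(model_p$features, model$features[perm, ], tolerance = 1e-8)
})

test_that("degenerate cohorts surface errors", {
  cc <- profile_cube(rep(1, 20), m = 4L, n = 3L)
  expect_error(extract_features(list(cc, cc, cc), k_final = 2L),
               "zero variance")
  set.seed(47)
  cubes <- lapply(1:4, function(i) random_cube(4L, 3L, 10L))
  expect_error(extract_features(cubes, k_final = 4L), "rank")
})
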