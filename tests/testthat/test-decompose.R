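test_that("standardization gives population mean 0 / variance 1 and is idempotent", {
  x <- matrix(c(0, 1), 1, 2)
  s <- standardize(x)
  expect_equal(mean(s$Z), 0)
  expect_equal(mean(s$Z^2), 1)

  x <- random_channels(7, 200, seed = 2)
  z1 <- standardize(x)$Z
  z2 <- standardize(z1)$Z
  expect_equal(z2, z1, tolerance = 1e-12)
  expect_equal(cor(t(z1)), cor(t(x)), tolerance = 1e-12)

  bad <- x; bad["LD", ] <- 1
  expect_error(standardize(bad), "LD")
})

test_that("PCA matches a brute-force eigendecomposition oracle", {
  for (seed in 1:5) {
    x <- random_channels(7, 500, seed = seed)
    d <- decompose_trial(x, "pca", k = 7)
    oracle <- pca_oracle(x)
    expect_equal(sum(d$eigenvalues), 7, tolerance = 1e-9)
    expect_equal(d$eigenvalues, oracle$eigenvalues, tolerance = 1e-8)
    expect_equal(unname(d$loadings_full), unname(oracle$loadings),
                 tolerance = 1e-8)
    # loading columns have norm sqrt(lambda)
    expect_equal(colSums(d$loadings_full^2), d$eigenvalues,
                 tolerance = 1e-9)
  }
})

test_that("two perfectly correlated channels give eigenvalues (2, 0)", {
  set.seed(8)
  base <- rnorm(100)
  x <- rbind(base, 2 * base + 5)
  d <- decompose_trial(x, "pca", k = 2)
  expect_equal(d$eigenvalues, c(2, 0), tolerance = 1e-9)
  expect_equal(unname(d$loadings_full[, 1]), c(1, 1), tolerance = 1e-9)
})

test_that("independent channels give flat eigenvalues and 3/7 retained variance", {
  x <- random_channels(7, 20000, seed = 3)
  d <- decompose_trial(x, "pca")
  expect_lt(max(abs(d$eigenvalues - 1)), 0.1)
  expect_equal(d$variance_explained, 3 / 7, tolerance = 0.05)
})

test_that("retention bookkeeping is exact", {
  x <- random_channels(7, 300, seed = 4)
  expect_equal(decompose_trial(x, "pca", k = 7)$variance_explained, 1,
               tolerance = 1e-12)
  expect_error(decompose_trial(x, "pca", k = 0), "k must")

  # rank-3 noise-free data: 3 components explain everything
  kin <- pad_rest(make_figure_eight("vertical", "DR"))
  m <- make_synergy_model(noise_sd = 0)
  act <- make_activations(kin, m)
  env <- 0.05 + m$weights %*% act   # linear mixture of 3 sources
  d3 <- decompose_trial(env + 1e-9 * random_channels(7, ncol(env)), "pca")
  expect_gt(d3$variance_explained, 0.999)
})

test_that("varimax rotation preserves communalities and never decreases the criterion", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- matrix(rnorm(21), 7, 3)
    vr <- varimax_rotate(L)
    expect_equal(rowSums(vr$loadings^2), rowSums(L^2), tolerance = 1e-9)
    expect_gte(varimax_criterion(normalize_rows(vr$loadings)),
               varimax_criterion(normalize_rows(L)) - 1e-12)
    expect_equal(crossprod(vr$rotation), diag(3), tolerance = 1e-9)
    expect_equal(L %*% vr$rotation, vr$loadings, tolerance = 1e-9)
  }
})

test_that("varimax agrees with the reference implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    L <- matrix(rnorm(21), 7, 3)
    mine <- varimax_rotate(L)
    ref <- stats::varimax(L, normalize = TRUE, eps = 1e-10)
    expect_equal(varimax_criterion(normalize_rows(mine$loadings)),
                 varimax_criterion(normalize_rows(unclass(ref$loadings))),
                 tolerance = 1e-6)
  }
})

test_that("perfect simple structure is a varimax fixed point up to permutation and sign", {
  L <- matrix(0, 7, 3)
  L[1:3, 1] <- 0.9
  L[4:5, 2] <- 0.8
  L[6:7, 3] <- 0.7
  vr <- varimax_rotate(L)
  recovered <- abs(t(vr$loadings) %*% L)  # 3x3, should be a scaled permutation
  best <- apply(recovered, 1, max)
  expect_equal(sort(best), sort(colSums(L^2)), tolerance = 1e-8)
  expect_lt(sum(recovered) - sum(best), 1e-8)
})

test_that("scores are unit-variance, uncorrelated, and track a rank-1 source", {
  env <- preprocess_trial(fixture_dataset$trials[[1]])
  d <- decompose_trial(env, "pca")
  n <- ncol(d$scores)
  expect_equal(unname(rowSums(d$scores^2) / n), rep(1, 3), tolerance = 1e-9)
  cc <- tcrossprod(d$scores) / n
  expect_equal(cc, diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(11)
  wave <- sin(seq(0, 6 * pi, length.out = 300))
  gains <- runif(7, 0.5, 2)
  x <- outer(gains, wave) + 1e-8 * matrix(rnorm(2100), 7)
  d1 <- decompose_trial(x, "pca", k = 1)
  expect_gt(abs(cor(d1$scores[1, ], wave)), 0.999)
})

test_that("time courses for new data reproduce the fitted scores", {
  env <- preprocess_trial(fixture_dataset$trials[[2]])
  for (fl in c("pca", "varimax")) {
    d <- decompose_trial(env, fl)
    expect_equal(time_courses(d, env), d$scores, tolerance = 1e-9)
  }
  d <- decompose_trial(env, "pca")
  expect_error(time_courses(d, env$values[1:5, ]), "channel count")
})

test_that("reconstruction is exact with all components and obeys the variance identity", {
  env <- preprocess_trial(fixture_dataset$trials[[3]])
  d <- decompose_trial(env, "pca")
  full <- predict(d, components = 1:7)
  expect_lt(max(abs(full - env$values)), 1e-8)

  part <- predict(d, components = 1:3)
  resid_std <- (env$values - part) / d$sds
  expect_equal(sum(rowSums(resid_std^2) / ncol(resid_std)),
               7 * (1 - d$variance_explained), tolerance = 1e-8)

  dv <- decompose_trial(env, "varimax")
  expect_equal(predict(dv, 1:3), part, tolerance = 1e-9)
})

test_that("varimax explains exactly the variance of the first three PCs", {
  env <- preprocess_trial(fixture_dataset$trials[[4]])
  d <- decompose_trial(env, "pca")
  dv <- rotate_varimax(d)
  expect_equal(sum(dv$loadings^2), sum(d$loadings^2), tolerance = 1e-10)
  expect_equal(dv$variance_explained, d$variance_explained,
               tolerance = 1e-10)
})

test_that("channel permutation permutes loading rows identically", {
  x <- abs(random_channels(7, 300, seed = 13))
  perm <- c(2, 5, 1, 7, 3, 6, 4)
  d1 <- decompose_trial(x, "pca")
  d2 <- decompose_trial(x[perm, ], "pca")
  expect_equal(unname(d2$loadings), unname(d1$loadings[perm, ]),
               tolerance = 1e-8)
})

test_that("canonical sign rule makes the largest-magnitude loading positive", {
  env <- preprocess_trial(fixture_dataset$trials[[5]])
  for (fl in c("pca", "varimax")) {
    d <- decompose_trial(env, fl)
    for (j in seq_len(ncol(d$loadings))) {
      col <- d$loadings[, j]
      expect_gt(col[which.max(abs(col))], 0)
    }
  }
})
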