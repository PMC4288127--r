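test_that("normality screen accepts Gaussian and rejects uniform samples", {
  set.seed(31)
  accept <- vapply(1:30, function(i)
    ks_normality(rnorm(1000))$p_value > 0.05, TRUE)
  expect_gte(mean(accept), 0.9)

  set.seed(32)
  expect_lt(ks_normality(runif(1000))$p_value, 0.01)

  r <- ks_normality(rnorm(50))
  expect_gte(r$statistic, 0)
  expect_lte(r$statistic, 1)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
  # plain (uncorrected) mode is available and less conservative
  set.seed(33)
  x <- rnorm(200)
  expect_gte(ks_normality(x, correct = FALSE)$p_value,
             ks_normality(x)$p_value - 1e-12)
})

test_that("identical groups give Wilks lambda 1, F 0, p 1", {
  set.seed(41)
  X <- matrix(rnorm(20 * 7), 20, 7)
  r <- manova_wilks(list(X, X), follow_up = FALSE)
  expect_equal(r$wilks_lambda, 1, tolerance = 1e-9)
  expect_equal(r$f_stat, 0, tolerance = 1e-9)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
})

test_that("two-group MANOVA uses the exact F(p, N-p-1) special case", {
  set.seed(42)
  g1 <- matrix(rnorm(31 * 7), 31, 7)
  g2 <- matrix(rnorm(31 * 7, mean = 0.3), 31, 7)
  r <- manova_wilks(list(g1, g2))
  expect_equal(r$df1, 7)
  expect_equal(r$df2, 54)
  expect_equal(nrow(r$per_muscle), 7)
  # cross-check against the reference MANOVA implementation
  y <- rbind(g1, g2)
  gr <- factor(rep(1:2, each = 31))
  ref <- summary(stats::manova(y ~ gr), test = "Wilks")$stats
  expect_equal(r$wilks_lambda, ref[1, "Wilks"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r$f_stat, ref[1, "approx F"], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("multi-group MANOVA matches Rao's approximation in the reference", {
  set.seed(43)
  groups <- lapply(1:4, function(i) matrix(rnorm(15 * 5, mean = 0.1 * i),
                                           15, 5))
  r <- manova_wilks(groups, follow_up = FALSE)
  y <- do.call(rbind, groups)
  gr <- factor(rep(1:4, each = 15))
  ref <- summary(stats::manova(y ~ gr), test = "Wilks")$stats
  expect_equal(r$wilks_lambda, ref[1, "Wilks"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r$f_stat, ref[1, "approx F"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r$df2, ref[1, "den Df"], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("1-dimensional MANOVA collapses to the one-way ANOVA F", {
  set.seed(44)
  g1 <- matrix(rnorm(12), 12, 1)
  g2 <- matrix(rnorm(12, 0.5), 12, 1)
  g3 <- matrix(rnorm(12, 1), 12, 1)
  r <- manova_wilks(list(g1, g2, g3), follow_up = FALSE)
  a <- anova_oneway(c(g1, g2, g3), rep(1:3, each = 12))
  expect_equal(r$f_stat, a$f_stat, tolerance = 1e-9)
  expect_equal(r$p_value, a$p_value, tolerance = 1e-9)
})

test_that("MANOVA is invariant to rescaling all observations", {
  set.seed(45)
  g1 <- matrix(rnorm(15 * 3), 15, 3)
  g2 <- matrix(rnorm(15 * 3, 0.4), 15, 3)
  r1 <- manova_wilks(list(g1, g2), follow_up = FALSE)
  r2 <- manova_wilks(list(7.3 * g1, 7.3 * g2), follow_up = FALSE)
  expect_equal(r1$wilks_lambda, r2$wilks_lambda, tolerance = 1e-9)
  expect_equal(r1$f_stat, r2$f_stat, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("one-way ANOVA equals the squared pooled t for two groups", {
  set.seed(46)
  a <- rnorm(20)
  b <- rnorm(25, 0.4)
  r <- anova_oneway(c(a, b), rep(1:2, c(20, 25)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$f_stat, unname(tt$statistic^2), tolerance = 1e-9)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-9)

  r0 <- anova_oneway(c(a, a), rep(1:2, c(20, 20)))
  expect_lt(r0$f_stat, 1e-9)
  expect_error(anova_oneway(1:5, c(1, 1, 1, 1, 2)), "n >= 2")
})

test_that("the planned PCA-vs-varimax contrast detects a dispersion shift", {
  set.seed(47)
  comp <- rep(c(paste0("PC", 1:3), paste0("VM", 1:3)), each = 50)
  y_null <- rnorm(300, mean = 1, sd = 0.1)
  d0 <- distance_anova(data.frame(component = comp, distance = y_null))
  expect_equal(sum(d0$contrast$weights), 0)
  expect_equal(d0$contrast$df1, 1)
  expect_equal(d0$contrast$df2, 294)

  shift <- ifelse(grepl("^PC", comp), -0.5, 0)
  y_alt <- rnorm(300, mean = 1 + shift, sd = 0.1)
  d1 <- distance_anova(data.frame(component = comp, distance = y_alt))
  expect_lt(d1$contrast$p_value, 1e-6)
  expect_lt(d1$contrast$estimate, 0)

  expect_error(distance_anova(data.frame(component = rep("PC1", 10),
                                         distance = rnorm(10))),
               "n >= 2")
})

test_that("two-way ANOVA on absolute loadings decomposes the variance", {
  set.seed(48)
  muscles <- rep(emg_muscles(), each = 9)
  comps <- rep(rep(paste0("PC", 1:3), each = 3), 7)
  y <- abs(rnorm(63, mean = 0.5, sd = 0.1))
  tab <- two_way_anova_absloadings(y, muscles, comps)
  expect_setequal(tab$term, c("muscle", "component", "muscle:component",
                              "Residuals"))
  total_ss <- sum((y - mean(y))^2)
  expect_equal(sum(tab$sum_sq), total_ss, tolerance = 1e-9)

  expect_error(two_way_anova_absloadings(y[-(1:3)], muscles[-(1:3)],
                                         comps[-(1:3)]), "empty")
})
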