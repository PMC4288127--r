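#' Kolmogorov-Smirnov normality screen
#'
#' One-sample K-S test of normality with mean and standard deviation
#' estimated from the sample. Because the parameters are estimated, the
#' default p-value uses the Lilliefors correction; `correct = FALSE` gives
#' the plain K-S p-value (anti-conservative with estimated parameters, kept
#' for replication of analyses that used it).
#'
#' @param x Numeric sample, n >= 5, non-constant.
#' @param correct Apply the Lilliefors correction (default `TRUE`).
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_normality <- function(x, correct = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 5) stopf("need at least 5 observations")
  if (stats::sd(x) == 0) stopf("constant sample")
  if (correct) {
    res <- nortest::lillie.test(x)
    list(statistic = unname(res$statistic), p_value = res$p.value)
  } else {
    res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    list(statistic = unname(res$statistic), p_value = res$p.value)
  }
}

#' MANOVA on loading vectors via Wilks' lambda
#'
#' Compares mean multivariate observations (7-dimensional loading vectors)
#' across groups. Wilks' lambda is `det(E) / det(E + H)` with `E` the
#' within-group and `H` the between-group cross-product matrices; the F
#' statistic uses Rao's approximation, which for two groups is exact with
#' `F(p, N - p - 1)` degrees of freedom.
#'
#' @param groups List (>= 2) of n_g x p matrices, one per group.
#' @param contrast Optional label describing the condition contrast.
#' @param follow_up Run per-variable one-way ANOVAs (default `TRUE`).
#' @return A `synergy_manova` object with `wilks_lambda`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `per_muscle` (data frame of per-variable F tests),
#'   `n_per_group`.
#' @export
manova_wilks <- function(groups, contrast = NULL, follow_up = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1L]])
  if (!all(vapply(groups, ncol, 0L) == p))
    stopf("all groups must have the same number of variables")
  ns <- vapply(groups, nrow, 0L)
  g <- length(groups)
  N <- sum(ns)
  if (N <= p + g)
    stopf("too few observations (%d) for %d variables and %d groups",
          N, p, g)
  grand <- colSums(do.call(rbind, groups)) / N
  E <- matrix(0, p, p)
  H <- matrix(0, p, p)
  for (i in seq_len(g)) {
    Xi <- groups[[i]]
    mi <- colMeans(Xi)
    E <- E + crossprod(Xi - rep(mi, each = ns[i]))
    H <- H + ns[i] * tcrossprod(mi - grand)
  }
  detE <- det(E)
  detT <- det(E + H)
  if (!is.finite(detE) || detE <= 0)
    stopf("singular within-group matrix: too few observations per dimension")
  lambda <- max(min(detE / detT, 1), .Machine$double.xmin)
  q <- g - 1
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  m <- N - 1 - (p + q + 1) / 2
  df1 <- p * q
  df2 <- m * s - (p * q) / 2 + 1
  lam_s <- lambda^(1 / s)
  f_stat <- ((1 - lam_s) / lam_s) * (df2 / df1)
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  per_muscle <- NULL
  if (follow_up) {
    values <- do.call(rbind, groups)
    labels <- factor(rep(seq_len(g), ns))
    per_muscle <- do.call(rbind, lapply(seq_len(p), function(j) {
      a <- anova_oneway(values[, j], labels)
      data.frame(muscle = colnames(values)[j] %||% paste0("V", j),
                 F = a$f_stat, df1 = a$df1, df2 = a$df2, p = a$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(contrast = contrast, wilks_lambda = lambda,
                 f_stat = f_stat, df1 = df1, df2 = df2, p_value = p_value,
                 per_muscle = per_muscle, n_per_group = ns),
            class = "synergy_manova")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synergy_manova <- function(x, ...) {
  if (!is.null(x$contrast)) cat("Contrast:", x$contrast, "\n")
  cat(sprintf("Wilks lambda = %.4f, F(%g, %.2f) = %.4f, p = %.4g\n",
              x$wilks_lambda, x$df1, x$df2, x$f_stat, x$p_value))
  if (!is.null(x$per_muscle)) {
    cat("Per-muscle one-way ANOVAs:\n")
    pm <- x$per_muscle
    pm$sig <- ifelse(pm$p < 0.01, "**", ifelse(pm$p < 0.05, "*", ""))
    print(pm, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' One-way ANOVA
#'
#' Classical between/within decomposition, fitted with `stats::aov`.
#'
#' @param values Numeric response.
#' @param group_labels Factor (or coercible) of group membership; >= 2
#'   groups, each with n >= 2.
#' @return List with `f_stat`, `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(values, group_labels) {
  f <- droplevels(as.factor(group_labels))
  if (nlevels(f) < 2) stopf("need at least 2 groups")
  if (any(table(f) < 2)) stopf("every group needs n >= 2")
  tab <- summary(stats::aov(values ~ f))[[1L]]
  list(f_stat = tab$`F value`[1L], df1 = tab$Df[1L], df2 = tab$Df[2L],
       p_value = tab$`Pr(>F)`[1L])
}

#' Cluster-dispersion ANOVA with the planned PCA-vs-varimax contrast
#'
#' One-way ANOVA of centroid distances over the six component levels
#' (PC1-PC3, VM1-VM3), plus a single planned contrast with weights
#' (+1, +1, +1, -1, -1, -1)/3 on the level means — the overall
#' principal-component vs varimax dispersion comparison — tested as an F on
#' 1 and N - 6 degrees of freedom.
#'
#' @param distance_table Data frame with columns `component` (6-level
#'   factor) and `distance`, as produced by [stability_census()].
#' @return List with `main` (F, df, p of the 6-level main effect),
#'   `contrast` (F, df, p, estimate of the planned contrast), and
#'   `level_means`.
#' @export
distance_anova <- function(distance_table) {
  comp <- factor(distance_table$component,
                 levels = c(paste0("PC", 1:3), paste0("VM", 1:3)))
  y <- distance_table$distance
  if (anyNA(comp)) stopf("component must use levels PC1-PC3, VM1-VM3")
  counts <- table(comp)
  if (any(counts < 2)) stopf("every component level needs n >= 2")
  main <- anova_oneway(y, comp)
  means <- tapply(y, comp, mean)
  w <- c(1, 1, 1, -1, -1, -1) / 3
  est <- sum(w * means)
  ss_contrast <- est^2 / sum(w^2 / as.numeric(counts))
  N <- length(y)
  mse <- sum((y - means[comp])^2) / (N - 6)
  f_c <- ss_contrast / mse
  p_c <- stats::pf(f_c, 1, N - 6, lower.tail = FALSE)
  list(main = list(f_stat = main$f_stat, df1 = main$df1, df2 = main$df2,
                   p_value = main$p_value),
       contrast = list(f_stat = f_c, df1 = 1, df2 = N - 6, p_value = p_c,
                       estimate = est, weights = w),
       level_means = means)
}

#' Two-way ANOVA on absolute loadings
#'
#' Fixed-effects two-way ANOVA with interaction on |loading| values with
#' muscle and component as crossed factors (trials as replicates),
#' quantifying whether muscles participate differently across components.
#'
#' @param abs_loadings Numeric response (absolute loading values).
#' @param muscle,component Factors of equal length.
#' @return Data frame with one row per term (`muscle`, `component`,
#'   `muscle:component`, `Residuals`): `df`, `sum_sq`, `F`, `p`.
#' @export
two_way_anova_absloadings <- function(abs_loadings, muscle, component) {
  muscle <- droplevels(as.factor(muscle))
  component <- droplevels(as.factor(component))
  cells <- table(muscle, component)
  if (any(cells == 0)) stopf("empty muscle x component cell")
  if (all(cells < 2)) stopf("need >= 2 replicates per cell")
  tab <- summary(stats::aov(abs_loadings ~ muscle * component))[[1L]]
  data.frame(term = trimws(rownames(tab)), df = tab$Df,
             sum_sq = tab$`Sum Sq`, F = tab$`F value`, p = tab$`Pr(>F)`,
             stringsAsFactors = FALSE)
}
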