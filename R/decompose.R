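#' Standardize a channel matrix
#'
#' Removes each channel's mean and scales to unit variance, using the
#' population convention (denominator T), and returns the standardization
#' record so reconstructions can be mapped back to original units.
#'
#' @param x Channel matrix (channels in rows) or `emg_envelope`.
#' @return List with `Z` (standardized matrix), `means`, `sds`.
#' @export
standardize <- function(x) {
  if (inherits(x, "emg_envelope")) x <- x$values
  check_finite_matrix(x, "input")
  n <- ncol(x)
  means <- rowMeans(x)
  centered <- x - means
  sds <- sqrt(rowSums(centered^2) / n)
  if (any(sds == 0)) {
    bad <- rownames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stopf("zero-variance channel(s): %s", paste(bad, collapse = ", "))
  }
  list(Z = centered / sds, means = means, sds = sds)
}

#' Per-trial component analysis of an EMG envelope
#'
#' Fits the component model of one movement: channels are standardized
#' (population convention), the correlation matrix `R = Z Z' / T` is formed
#' explicitly and eigendecomposed, and loadings are reported as
#' variable-component correlations, `loading_j = eigvec_j * sqrt(lambda_j)`
#' (the factor-analysis convention; raw unit-norm eigenvectors are kept for
#' diagnostics). Component time courses are unit-variance scores
#' `s_j = (v_j' Z) / sqrt(lambda_j)`. The first `k` components (default 3)
#' are retained; for `flavor = "varimax"` they are further rotated with
#' [varimax_rotate()] and the scores are rotated accordingly (which keeps
#' them unit-variance, since the rotation is orthogonal). In every loading
#' column the entry of largest magnitude is made positive (canonical sign).
#'
#' @param x An `emg_envelope` (normally normalized to \[0, 1\]) or a plain
#'   channel matrix with channels in rows and `T > channels` samples.
#' @param flavor `"pca"` (unrotated) or `"varimax"`.
#' @param k Number of retained components (default 3).
#' @param ... Passed to [varimax_rotate()].
#' @return An `emg_decomp` object with fields `flavor`, `loadings` (7 x k),
#'   `loadings_full`, `eigvec`, `eigenvalues`, `means`, `sds`, `scores`
#'   (k x T), `scores_full`, `variance_explained`, `rotation` (varimax
#'   only), `converged`, `trial_id`, `condition`.
#' @export
decompose_trial <- function(x, flavor = c("pca", "varimax"), k = 3, ...) {
  flavor <- match.arg(flavor)
  trial_id <- if (inherits(x, "emg_envelope")) x$trial_id else NULL
  condition <- if (inherits(x, "emg_envelope")) x$condition else NULL
  std <- standardize(x)
  Z <- std$Z
  p <- nrow(Z)
  n <- ncol(Z)
  if (n <= p) stopf("need more samples (%d) than channels (%d)", n, p)
  if (k < 1 || k > p) stopf("k must lie in [1, %d]", p)
  R <- tcrossprod(Z) / n
  eg <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  V <- eg$vectors
  L_full <- V * rep(sqrt(lambda), each = p)
  # canonical sign: largest-|loading| channel positive in every column
  flip <- apply(L_full, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  V <- sweep(V, 2L, flip, "*")
  L_full <- sweep(L_full, 2L, flip, "*")
  pos <- lambda > 1e-12
  scores_full <- matrix(0, p, n)
  scores_full[pos, ] <- crossprod(V[, pos, drop = FALSE], Z) /
    sqrt(lambda[pos])
  rownames(L_full) <- rownames(Z)
  obj <- list(flavor = "pca",
              loadings = L_full[, seq_len(k), drop = FALSE],
              loadings_full = L_full, eigvec = V, eigenvalues = lambda,
              means = std$means, sds = std$sds,
              scores = scores_full[seq_len(k), , drop = FALSE],
              scores_full = scores_full,
              variance_explained = sum(lambda[seq_len(k)]) / sum(lambda),
              rotation = NULL, converged = TRUE,
              trial_id = trial_id, condition = condition)
  class(obj) <- "emg_decomp"
  if (flavor == "varimax") obj <- rotate_varimax(obj, ...) else obj
}

#' Varimax rotation of a fitted decomposition
#'
#' Rotates the retained loading columns to maximize the varimax criterion
#' (the sum over components of the variance of squared loadings), favoring
#' simple structure. Row communalities and total explained variance are
#' unchanged by the orthogonal rotation; scores are rotated with the same
#' matrix and remain unit-variance.
#'
#' @param decomp An `emg_decomp` with `flavor = "pca"`.
#' @param ... Passed to [varimax_rotate()].
#' @return An `emg_decomp` with `flavor = "varimax"` and the 3 x 3 (k x k)
#'   `rotation` matrix recorded.
#' @export
rotate_varimax <- function(decomp, ...) {
  stopifnot(inherits(decomp, "emg_decomp"))
  if (decomp$flavor != "pca") stopf("decomposition is already rotated")
  vr <- varimax_rotate(decomp$loadings, ...)
  out <- decomp
  out$flavor <- "varimax"
  out$loadings <- vr$loadings
  out$rotation <- vr$rotation
  out$converged <- vr$converged
  # the rotation matrix already carries the canonical sign flips, so the
  # rotated scores stay consistent with the sign-fixed loadings
  out$scores <- crossprod(vr$rotation, decomp$scores)
  out
}

#' Varimax rotation of a loading matrix
#'
#' Kaiser's iterative pairwise planar-rotation algorithm with optional
#' Kaiser row-normalization (rows scaled to unit communality during the
#' optimization). Convergence is declared when one full sweep changes the
#' criterion by less than `tol`; if `max_iter` sweeps pass without
#' convergence the result is still returned with `converged = FALSE`.
#' The canonical sign rule (largest-magnitude entry positive) is applied to
#' the rotated columns.
#'
#' @param loadings p x k loading matrix with linearly independent columns.
#' @param kaiser_normalize Use Kaiser row-normalization (default `TRUE`).
#' @param tol Convergence tolerance on the criterion (default 1e-8).
#' @param max_iter Maximum number of sweeps (default 500).
#' @return List with `loadings` (rotated, sign-canonical), `rotation`
#'   (k x k orthogonal, including the sign flips), `sign_flip`, `converged`,
#'   `criterion`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE, tol = 1e-8,
                           max_iter = 500) {
  L <- as.matrix(loadings)
  p <- nrow(L)
  k <- ncol(L)
  if (k < 2) stopf("varimax needs at least 2 columns")
  if (qr(L)$rank < k) stopf("loading columns must be linearly independent")
  h <- sqrt(rowSums(L^2))
  W <- if (kaiser_normalize) L / h else L
  Rot <- diag(k)
  crit_old <- varimax_criterion(W)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        x <- W[, i]; y <- W[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        C <- sum(u^2 - v^2); D <- sum(2 * u * v)
        num <- D - 2 * A * B / p
        den <- C - (A^2 - B^2) / p
        phi <- atan2(num, den) / 4
        # the stationary angles of the pair criterion are spaced pi/4 apart;
        # pick the maximizing one (guarantees monotone ascent)
        cand <- c(0, phi, phi + pi / 4, phi - pi / 4)
        gains <- vapply(cand, function(a) {
          xr <- x * cos(a) + y * sin(a)
          yr <- -x * sin(a) + y * cos(a)
          varimax_criterion(cbind(xr, yr))
        }, 0)
        a <- cand[which.max(gains)]
        if (abs(a) < 1e-14) next
        G <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
        W[, c(i, j)] <- W[, c(i, j)] %*% G
        Rot[, c(i, j)] <- Rot[, c(i, j)] %*% G
      }
    }
    crit <- varimax_criterion(W)
    if (abs(crit - crit_old) < tol) { converged <- TRUE; break }
    crit_old <- crit
  }
  out <- (if (kaiser_normalize) W * h else W)
  flip <- apply(out, 2L, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  out <- sweep(out, 2L, flip, "*")
  Rot <- sweep(Rot, 2L, flip, "*")
  dimnames(out) <- dimnames(L)
  list(loadings = out, rotation = Rot, sign_flip = flip,
       converged = converged, criterion = varimax_criterion(out))
}

#' Varimax simplicity criterion
#'
#' Sum over columns of the variance of the squared loadings,
#' `sum_j [ mean(l_j^4) - mean(l_j^2)^2 ]`.
#'
#' @param loadings p x k loading matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  L2 <- as.matrix(loadings)^2
  sum(apply(L2, 2L, function(c2) mean(c2^2) - mean(c2)^2))
}

#' Component time courses for new data
#'
#' Projects, at each time step, the standardized vector of the 7 muscle
#' envelopes onto the component axes, using the fit's own standardization
#' record: `s_j(t) = sum_m Z_m(t) v_mj / sqrt(lambda_j)` for PCA, with the
#' corresponding orthogonal score rotation for varimax.
#'
#' @param decomp An `emg_decomp`.
#' @param x Channel matrix or `emg_envelope` with the same channels as the
#'   fit (defaults to the fitted scores when omitted).
#' @return k x T score matrix.
#' @export
time_courses <- function(decomp, x = NULL) {
  stopifnot(inherits(decomp, "emg_decomp"))
  if (is.null(x)) return(decomp$scores)
  if (inherits(x, "emg_envelope")) x <- x$values
  if (nrow(x) != length(decomp$means))
    stopf("channel count mismatch: fit has %d, data has %d",
          length(decomp$means), nrow(x))
  Z <- (x - decomp$means) / decomp$sds
  k <- ncol(decomp$loadings)
  lam <- decomp$eigenvalues[seq_len(k)]
  s <- crossprod(decomp$eigvec[, seq_len(k), drop = FALSE], Z) / sqrt(lam)
  if (decomp$flavor == "varimax")
    s <- crossprod(decomp$rotation, s)
  s
}

#' Reconstruct EMG from selected components
#'
#' Maps component scores back to envelope units:
#' `xhat_m(t) = mean_m + sd_m * sum_{j in K} loading_mj s_j(t)`.
#' With all 7 PCA components the input is reproduced exactly.
#'
#' @param object An `emg_decomp`.
#' @param components Component indices to use (default all retained).
#' @param ... Unused.
#' @return 7 x T matrix in original envelope units.
#' @export
predict.emg_decomp <- function(object, components = seq_len(ncol(object$loadings)),
                               ...) {
  k_ret <- ncol(object$loadings)
  full_ok <- object$flavor == "pca" &&
    all(components %in% seq_along(object$eigenvalues))
  if (!all(components %in% seq_len(k_ret)) && !full_ok)
    stopf("components must be among the retained set")
  if (object$flavor == "pca" && any(components > k_ret)) {
    L <- object$loadings_full[, components, drop = FALSE]
    S <- object$scores_full[components, , drop = FALSE]
  } else {
    L <- object$loadings[, components, drop = FALSE]
    S <- object$scores[components, , drop = FALSE]
  }
  object$means + object$sds * (L %*% S)
}

#' @export
fitted.emg_decomp <- function(object, ...) predict(object)

#' @export
coef.emg_decomp <- function(object, ...) object$loadings

#' @export
print.emg_decomp <- function(x, ...) {
  cat(sprintf("EMG component decomposition (%s)%s\n", x$flavor,
              if (is.null(x$trial_id)) "" else paste0(": ", x$trial_id)))
  cat(sprintf("  %d retained components, %.1f%% of variance\n",
              ncol(x$loadings), 100 * x$variance_explained))
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
summary.emg_decomp <- function(object, ...) {
  communality <- rowSums(object$loadings^2)
  out <- list(flavor = object$flavor, loadings = object$loadings,
              eigenvalues = object$eigenvalues,
              variance_explained = object$variance_explained,
              communality = communality, trial_id = object$trial_id)
  class(out) <- "summary.emg_decomp"
  out
}

#' @export
print.summary.emg_decomp <- function(x, ...) {
  cat(sprintf("Component decomposition (%s), variance explained %.1f%%\n",
              x$flavor, 100 * x$variance_explained))
  cat("Eigenvalues:", paste(round(x$eigenvalues, 3), collapse = ", "), "\n")
  cat("Loadings (communalities in last column):\n")
  print(round(cbind(x$loadings, h2 = x$communality), 3))
  invisible(x)
}

#' @export
plot.emg_decomp <- function(x, ...) {
  k <- ncol(x$loadings)
  old <- graphics::par(mfrow = c(k, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  lab <- toupper(substr(x$flavor, 1, 2))
  for (j in seq_len(k)) {
    graphics::barplot(x$loadings[, j], ylim = c(-1, 1),
                      main = sprintf("%s%d", ifelse(lab == "VA", "VM", "PC"), j),
                      ylab = "loading", ...)
    graphics::abline(h = 0)
  }
  invisible(x)
}
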