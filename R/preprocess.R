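#' Full-wave rectification
#'
#' @param raw Signed channel matrix (channels in rows).
#' @return Elementwise absolute value, shape preserved.
#' @export
rectify <- function(raw) {
  check_finite_matrix(raw, "raw EMG")
  abs(raw)
}

#' Third-order averaging envelope filter
#'
#' Smooths rectified EMG with a cascade of three identical first-order
#' exponential averagers, each with the given time constant — the standard
#' reading of an n-th order averaging filter with a stated time constant.
#' Each stage has unit DC gain. By default the cascade is applied forward
#' and then backward (zero phase), so envelope peaks are not delayed
#' relative to the kinematics; set `causal = TRUE` for a single forward
#' pass.
#'
#' @param rectified Non-negative channel matrix (channels in rows).
#' @param rate_hz Sampling rate in Hz.
#' @param time_constant_s Time constant of each first-order stage
#'   (default 0.020 s).
#' @param causal Single forward pass instead of forward-backward.
#' @return Smoothed matrix of the same shape.
#' @export
smooth_envelope <- function(rectified, rate_hz, time_constant_s = 0.020,
                            causal = FALSE) {
  check_finite_matrix(rectified, "rectified EMG")
  if (rate_hz * time_constant_s < 1)
    stopf("time constant (%g s) is shorter than one sample at %g Hz",
          time_constant_s, rate_hz)
  a <- exp(-1 / (rate_hz * time_constant_s))
  one_pass <- function(x) {
    for (k in 1:3)   # steady-state initialization avoids a startup transient
      x <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                                    init = x[1L]))
    x
  }
  out <- t(apply(rectified, 1L, function(x) {
    y <- one_pass(x)
    if (!causal) y <- rev(one_pass(rev(y)))
    y
  }))
  dimnames(out) <- dimnames(rectified)
  out
}

#' Align an EMG envelope to the kinematic clock
#'
#' Decimates by averaging within each target-rate bin; the EMG rate must be
#' an integer multiple of the target rate. Output length is
#' `floor(T * target / emg_rate)`.
#'
#' @param envelope Channel matrix at `emg_rate_hz`.
#' @param emg_rate_hz Input sampling rate.
#' @param target_rate_hz Output rate (default 100 Hz).
#' @return An `emg_envelope` object: `values` (7 x T'), `rate_hz`,
#'   `norm_params` (`NULL` until normalization).
#' @export
align_to_kinematics <- function(envelope, emg_rate_hz, target_rate_hz = 100) {
  check_finite_matrix(envelope, "envelope")
  factor <- emg_rate_hz / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stopf("emg_rate_hz must be an integer multiple of target_rate_hz")
  factor <- as.integer(round(factor))
  n_out <- ncol(envelope) %/% factor
  idx <- seq_len(n_out * factor)
  values <- t(apply(envelope[, idx, drop = FALSE], 1L, function(x) {
    colMeans(matrix(x, nrow = factor))
  }))
  rownames(values) <- rownames(envelope)
  structure(list(values = values, rate_hz = target_rate_hz,
                 norm_params = NULL),
            class = "emg_envelope")
}

#' Per-movement min/max normalization
#'
#' For each channel, subtracts the minimum over the whole movement and
#' divides by the range, so every channel spans exactly \[0, 1\]. The
#' normalization is always per movement (one trial, or one concatenated
#' movement set), never across a session. A constant channel is rejected by
#' name rather than silently zeroed, because it would break the
#' unit-variance standardization downstream.
#'
#' @param envelope An `emg_envelope` or plain channel matrix.
#' @return An `emg_envelope` with `norm_params` recording the subtracted
#'   minimum and the range divisor per channel.
#' @export
normalize_per_movement <- function(envelope) {
  rate <- 100
  if (inherits(envelope, "emg_envelope")) {
    rate <- envelope$rate_hz
    envelope <- envelope$values
  }
  check_finite_matrix(envelope, "envelope")
  if (is.null(rownames(envelope)))
    rownames(envelope) <- if (nrow(envelope) == 7) emg_muscles() else
      paste0("ch", seq_len(nrow(envelope)))
  mins <- apply(envelope, 1L, min)
  maxs <- apply(envelope, 1L, max)
  ranges <- maxs - mins
  if (any(ranges <= 0)) {
    bad <- rownames(envelope)[ranges <= 0]
    if (is.null(bad)) bad <- which(ranges <= 0)
    stopf("degenerate (constant) channel(s): %s", paste(bad, collapse = ", "))
  }
  values <- (envelope - mins) / ranges
  dimnames(values) <- dimnames(envelope)
  structure(list(values = values, rate_hz = rate,
                 norm_params = data.frame(channel = rownames(envelope),
                                          min_subtracted = mins,
                                          max_divisor = ranges,
                                          row.names = NULL)),
            class = "emg_envelope")
}

#' Velocity by local fifth-degree polynomial differentiation
#'
#' Differentiates position digitally by fitting a fifth-degree polynomial by
#' least squares over a sliding centered window (Savitzky-Golay style) and
#' taking the fitted first derivative at the window center; near the edges
#' the same-degree fit uses one-sided windows evaluated at the boundary
#' sample.
#'
#' @param position T x d matrix (or vector) of positions.
#' @param rate_hz Sampling rate in Hz.
#' @param window_samples Odd window length >= 7 (default 11, i.e. 110 ms at
#'   100 Hz).
#' @return Matrix (or vector) of velocities, same shape as `position`.
#' @export
differentiate_position <- function(position, rate_hz, window_samples = 11) {
  vec <- is.null(dim(position))
  pos <- if (vec) matrix(position, ncol = 1) else as.matrix(position)
  if (window_samples %% 2 != 1 || window_samples < 7)
    stopf("window_samples must be odd and >= 7")
  n <- nrow(pos)
  if (n < window_samples)
    stopf("trace length (%d) shorter than window (%d)", n, window_samples)
  half <- (window_samples - 1L) %/% 2L
  # fits are done on a sample-unit abscissa for conditioning; the derivative
  # is rescaled by the sampling rate afterwards
  trel <- -half:half
  V <- outer(trel, 0:5, "^")
  coef_mat <- solve(crossprod(V), t(V))     # 6 x window, rows = poly coefs
  dfilt <- coef_mat[2L, ]                   # first-derivative weights
  vel <- apply(pos, 2L, function(x) {
    v <- as.numeric(stats::filter(x, rev(dfilt), sides = 2))
    for (i in seq_len(half)) {              # one-sided edge fits
      v[i] <- onesided_deriv(x[1:window_samples], i - 1L)
      v[n - i + 1L] <- onesided_deriv(x[(n - window_samples + 1L):n],
                                      window_samples - i)
    }
    v * rate_hz
  })
  dimnames(vel) <- dimnames(pos)
  if (vec) as.numeric(vel) else vel
}

# Fit a quintic to one window (sample-unit abscissa) and return the
# derivative at sample `at` (0-based within the window).
onesided_deriv <- function(x, at) {
  trel <- seq_along(x) - 1L - at
  V <- outer(trel, 0:5, "^")
  fit <- qr.coef(qr(V), x)
  fit[2L]
}

#' Preprocess one trial into a normalized envelope
#'
#' The fixed pipeline order: rectify, smooth with the third-order averaging
#' filter, decimate to the kinematic clock, then (optionally) min/max
#' normalize per movement. Velocity is recomputed from position with
#' [differentiate_position()] when the trace does not already carry one.
#'
#' @param trial An `emg_trial`.
#' @param time_constant_s,causal Passed to [smooth_envelope()].
#' @param target_rate_hz Alignment rate (default the kinematic rate).
#' @param normalize Apply [normalize_per_movement()] (default `TRUE`; the
#'   discrete-movement path normalizes after concatenation instead).
#' @return An `emg_envelope` with the trial's id and condition attached.
#' @export
preprocess_trial <- function(trial, time_constant_s = 0.020, causal = FALSE,
                             target_rate_hz = trial$kinematics$rate_hz,
                             normalize = TRUE) {
  stopifnot(inherits(trial, "emg_trial"))
  env <- smooth_envelope(rectify(trial$emg), trial$emg_rate_hz,
                         time_constant_s, causal)
  out <- align_to_kinematics(env, trial$emg_rate_hz, target_rate_hz)
  if (normalize) out <- normalize_per_movement(out)
  out$trial_id <- trial$trial_id
  out$subject_id <- trial$subject_id
  out$condition <- trial$condition
  out
}

#' Concatenate aligned envelopes of a movement set
#'
#' Joins the un-normalized envelopes of several movements (the eight
#' point-to-point directions of one subject) in time, then applies one
#' min/max normalization over the whole concatenated set, which is analyzed
#' as a single movement unit.
#'
#' @param envelopes List of un-normalized `emg_envelope`s at a common rate.
#' @param normalize Normalize the concatenated set (default `TRUE`).
#' @return A single `emg_envelope`.
#' @export
concatenate_envelopes <- function(envelopes, normalize = TRUE) {
  stopifnot(length(envelopes) >= 1,
            all(vapply(envelopes, inherits, TRUE, "emg_envelope")))
  rates <- vapply(envelopes, function(e) e$rate_hz, 0)
  if (length(unique(rates)) != 1L) stopf("envelopes have mixed rates")
  values <- do.call(cbind, lapply(envelopes, function(e) e$values))
  out <- structure(list(values = values, rate_hz = rates[1L],
                        norm_params = NULL),
                   class = "emg_envelope")
  if (normalize) out <- normalize_per_movement(out)
  ids <- vapply(envelopes, function(e)
    if (is.null(e$trial_id)) NA_character_ else e$trial_id, "")
  out$trial_id <- paste(ids, collapse = "+")
  out$subject_id <- envelopes[[1L]]$subject_id
  out$condition <- envelopes[[1L]]$condition
  out
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("EMG envelope: %d x %d at %g Hz (%s)\n", nrow(x$values),
              ncol(x$values), x$rate_hz,
              if (is.null(x$norm_params)) "un-normalized" else "normalized [0,1]"))
  invisible(x)
}
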