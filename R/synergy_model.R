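#' Ground-truth three-module synergy model
#'
#' Builds the generative synergy model used by the simulator: a 7 x 3 weight
#' matrix `W` over the muscles [AD, MD, PD, PMS, PMI, LD, TM] whose columns
#' are the three modules the analysis is expected to recover:
#'
#' * column 1, *co-contraction*: all seven weights positive — a module that
#'   stiffens the limb over the whole movement;
#' * column 2, *horizontal reciprocal*: MD, PD and TM (rightward action) carry
#'   one sign, AD, PMS and PMI (leftward action) the opposite sign, and LD
#'   stays near zero (|weight| <= 0.15);
#' * column 3, *vertical reciprocal*: AD and MD (upward) oppose PMI and TM
#'   (downward), with PD, PMS and LD near zero (|weight| <= 0.15).
#'
#' Columns are renormalized to unit Euclidean norm. The default magnitudes
#' follow the characteristic per-muscle loading pattern of the three modules
#' (e.g. LD loading largest on the co-contraction module, near zero on the
#' reciprocal ones). Weight overrides are validated against the sign
#' template, which is the model's contract.
#'
#' @param weights Optional 7 x 3 numeric matrix overriding the default
#'   template (rows in canonical muscle order).
#' @param tonic_gain Gain of the tonic co-contraction command (>= 0).
#' @param noise_sd Additive noise level as a fraction of each channel's
#'   signal RMS (>= 0).
#' @param muscle_gains Seven positive per-muscle amplitude gains.
#' @param baseline Seven non-negative resting levels.
#' @param seed Integer seed for reproducible EMG synthesis.
#' @return A `synergy_model` object.
#' @export
make_synergy_model <- function(weights = NULL, tonic_gain = 1,
                               noise_sd = 0.05,
                               muscle_gains = rep(1, 7),
                               baseline = rep(0.05, 7),
                               seed = 1L) {
  if (tonic_gain < 0) stopf("tonic_gain must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(muscle_gains) != 7 || any(muscle_gains <= 0))
    stopf("muscle_gains must be 7 positive scalars")
  if (length(baseline) != 7 || any(baseline < 0))
    stopf("baseline must be 7 non-negative scalars")
  W <- if (is.null(weights)) default_synergy_weights() else as.matrix(weights)
  if (!all(dim(W) == c(7, 3)) || !all(is.finite(W)))
    stopf("weights must be a finite 7 x 3 matrix")
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  dimnames(W) <- list(emg_muscles(),
                      c("cocontraction", "horizontal", "vertical"))
  validate_synergy_weights(W)
  structure(list(weights = W, tonic_gain = tonic_gain, noise_sd = noise_sd,
                 muscle_gains = as.numeric(muscle_gains),
                 baseline = as.numeric(baseline), seed = as.integer(seed)),
            class = "synergy_model")
}

# Default magnitudes per module, rows [AD, MD, PD, PMS, PMI, LD, TM].
default_synergy_weights <- function() {
  W <- cbind(cocontraction = c(0.53, 0.75, 0.74, 0.53, 0.65, 0.86, 0.58),
             horizontal    = c(-0.52, 0.46, 0.59, -0.75, -0.50, 0.05, 0.21),
             vertical      = c(0.54, 0.35, 0.04, 0.10, -0.39, 0.11, -0.67))
  rownames(W) <- emg_muscles()
  W
}

# Sign-template contract for a unit-norm 7 x 3 synergy weight matrix.
validate_synergy_weights <- function(W) {
  m <- emg_muscles()
  w <- function(mu, j) W[match(mu, m), j]
  if (any(W[, 1L] <= 0))
    stopf("co-contraction column must have all 7 weights > 0")
  s_a <- sign(w(c("MD", "PD", "TM"), 2L))
  s_b <- sign(w(c("AD", "PMS", "PMI"), 2L))
  if (length(unique(s_a)) != 1L || length(unique(s_b)) != 1L ||
      s_a[1L] == s_b[1L])
    stopf("horizontal column: {MD, PD, TM} must oppose {AD, PMS, PMI} in sign")
  if (abs(w("LD", 2L)) > 0.15)
    stopf("horizontal column: |weight(LD)| must be <= 0.15")
  s_up <- sign(w(c("AD", "MD"), 3L))
  s_dn <- sign(w(c("PMI", "TM"), 3L))
  if (length(unique(s_up)) != 1L || length(unique(s_dn)) != 1L ||
      s_up[1L] == s_dn[1L])
    stopf("vertical column: {AD, MD} must oppose {PMI, TM} in sign")
  if (any(abs(w(c("PD", "PMS", "LD"), 3L)) > 0.15))
    stopf("vertical column: |weight| must be <= 0.15 for {PD, PMS, LD}")
  invisible(W)
}

#' @export
print.synergy_model <- function(x, ...) {
  cat("Three-module synergy model (7 muscles)\n")
  cat(sprintf("  tonic_gain = %g, noise_sd = %g, seed = %d\n",
              x$tonic_gain, x$noise_sd, x$seed))
  print(round(x$weights, 3))
  invisible(x)
}

#' Module activation time courses for a movement
#'
#' Maps kinematics to the three module commands: the co-contraction command
#' is the tonic gain times the movement's on/off activity envelope (positive
#' during movement, near zero at rest); the two reciprocal commands are the
#' horizontal and vertical endpoint velocity components, each scaled to unit
#' peak absolute value. For a vertical figure eight the horizontal command
#' therefore oscillates at twice the frequency of the vertical one.
#'
#' @param kin A `kin_trace`.
#' @param model A `synergy_model`.
#' @return A 3 x T matrix with rows `cocontraction`, `horizontal`,
#'   `vertical`.
#' @export
make_activations <- function(kin, model) {
  stopifnot(inherits(kin, "kin_trace"), inherits(model, "synergy_model"))
  if (length(kin$time) == 0L) stopf("zero-length kinematics trace")
  if (!all(is.finite(kin$velocity))) stopf("kinematics velocity must be finite")
  unit_peak <- function(x) {
    m <- max(abs(x))
    if (m == 0) x else x / m
  }
  rbind(cocontraction = model$tonic_gain * kin$envelope,
        horizontal = unit_peak(kin$velocity[, "h"]),
        vertical = unit_peak(kin$velocity[, "v"]))
}
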