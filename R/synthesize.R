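#' Synthesize one raw surface-EMG trial
#'
#' Forward model from kinematics to signed raw EMG. The per-muscle activity
#' envelope is `e_m(t) = baseline_m + gain_m * max(0, [W c(t)]_m)` — the
#' module commands mixed by the synergy weights, half-wave rectified because
#' muscle activity cannot be negative. The envelope (at the kinematic rate)
#' is linearly upsampled to the EMG rate and amplitude-modulates a band-limited
#' zero-mean unit-variance Gaussian carrier (nominal 10-450 Hz band at the
#' 1 kHz default rate), the simplest generative stand-in for the surface-EMG
#' interference pattern. White measurement noise with standard deviation
#' `noise_sd * RMS(e_m)` is added per channel. Output is reproducible for a
#' fixed seed.
#'
#' @param kin A `kin_trace` (pad with [pad_rest()] to include rest).
#' @param model A `synergy_model`.
#' @param emg_rate_hz EMG sampling rate in Hz; must be an integer multiple of
#'   `kin$rate_hz` (default 1000).
#' @param seed Seed for the carrier and measurement noise; defaults to the
#'   model's seed.
#' @param trial_id,subject_id Identifiers stored with the trial.
#' @return An `emg_trial`: list with `emg` (signed 7 x T matrix, muscles in
#'   rows), `emg_rate_hz`, `kinematics`, `envelope_true` (the noise-free
#'   7 x T_kin envelope, kept for validation), ids and `condition` metadata.
#' @export
synthesize_trial <- function(kin, model, emg_rate_hz = 1000,
                             seed = model$seed,
                             trial_id = "trial", subject_id = "S1") {
  stopifnot(inherits(kin, "kin_trace"), inherits(model, "synergy_model"))
  factor <- emg_rate_hz / kin$rate_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stopf("emg_rate_hz must be an integer multiple of the kinematic rate")
  factor <- as.integer(round(factor))
  act <- make_activations(kin, model)
  env <- model$baseline +
    model$muscle_gains * pmax(model$weights %*% act, 0)  # 7 x T_kin
  t_kin <- kin$time
  n_emg <- length(t_kin) * factor
  t_emg <- seq(t_kin[1L], by = 1 / emg_rate_hz, length.out = n_emg)
  t_emg <- pmin(t_emg, t_kin[length(t_kin)])
  emg <- with_seed(seed, {
    out <- matrix(0, nrow = 7, ncol = n_emg)
    for (m in seq_len(7)) {
      e_hi <- stats::approx(t_kin, env[m, ], xout = t_emg)$y
      carrier <- band_limited_noise(n_emg, emg_rate_hz)
      noise <- stats::rnorm(n_emg, sd = model$noise_sd * rms(e_hi))
      out[m, ] <- e_hi * carrier + noise
    }
    out
  })
  rownames(emg) <- emg_muscles()
  structure(list(emg = emg, emg_rate_hz = emg_rate_hz, kinematics = kin,
                 envelope_true = env, trial_id = trial_id,
                 subject_id = subject_id,
                 condition = list(movement_type = kin$movement_type,
                                  initial_direction = kin$initial_direction,
                                  orientation = kin$orientation,
                                  plane = kin$plane)),
            class = "emg_trial")
}

# Zero-mean unit-variance Gaussian noise band-passed to the nominal
# surface-EMG band (10 Hz to just below Nyquist).
band_limited_noise <- function(n, rate_hz, band = c(10, 450)) {
  hi <- min(band[2L], 0.45 * rate_hz)
  x <- stats::rnorm(n)
  bf <- signal::butter(2, c(band[1L], hi) / (rate_hz / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  (y - mean(y)) / stats::sd(y)
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("EMG trial '%s' (subject %s): 7 x %d at %g Hz\n",
              x$trial_id, x$subject_id, ncol(x$emg), x$emg_rate_hz))
  print(x$kinematics)
  invisible(x)
}
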