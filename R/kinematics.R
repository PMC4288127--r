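#' Figure-eight endpoint kinematics from two coupled oscillators
#'
#' A figure eight traced "as fast as possible" is modelled as a Lissajous
#' curve: two perpendicular sinusoids with a 2:1 frequency ratio (two cycles
#' along the short axis for one cycle along the long axis). The low-frequency
#' oscillator (`f0 = 1/duration_s`) runs along the long axis of the figure —
#' vertical for the upright orientation, horizontal for the figure rotated by
#' 90 degrees. A raised-cosine on/off envelope brings the speed smoothly from
#' and back to zero so the gesture is a discrete movement in the sense of
#' Hogan and Sternad: finite duration, zero start and end velocity.
#'
#' Phases are 0 or pi on each axis, chosen so the trajectory leaves the
#' figure's center into the requested quadrant (`UR`, `UL`, `DR`, `DL`).
#' Velocity is analytic (product rule on envelope times sinusoid).
#'
#' @param orientation `"vertical"` (long axis vertical) or `"horizontal"`.
#' @param initial_direction One of `"UR"`, `"UL"`, `"DR"`, `"DL"`.
#' @param duration_s Movement duration in seconds (> 0).
#' @param amplitude_m Peak displacement along the long axis in meters; the
#'   short-axis amplitude is half of it, keeping mean speed comparable across
#'   axes given the 2:1 frequency ratio.
#' @param rate_hz Sampling rate in Hz (>= 20; kinematic default 100).
#' @param envelope_rise_s Rise/fall time of the on/off envelope in seconds
#'   (default 10% of the duration).
#' @return A `kin_trace` object: list with `time`, `position` (T x 2 matrix,
#'   columns `h`, `v`, meters), `velocity` (T x 2, m/s), `envelope` (unit-peak
#'   activity profile), `rate_hz`, and condition metadata.
#' @export
make_figure_eight <- function(orientation = c("vertical", "horizontal"),
                              initial_direction = c("UR", "UL", "DR", "DL"),
                              duration_s = 1.5, amplitude_m = 0.3,
                              rate_hz = 100,
                              envelope_rise_s = 0.1 * duration_s) {
  orientation <- check_token(orientation[1L], c("vertical", "horizontal"),
                             "orientation")
  initial_direction <- check_token(initial_direction[1L],
                                   c("UR", "UL", "DR", "DL"),
                                   "initial_direction")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (amplitude_m <= 0) stopf("amplitude_m must be > 0")
  if (rate_hz < 20) stopf("rate_hz must be >= 20")
  if (envelope_rise_s <= 0 || envelope_rise_s > duration_s / 2)
    stopf("envelope_rise_s must lie in (0, duration_s/2]")

  t <- seq(0, duration_s, by = 1 / rate_hz)
  f0 <- 1 / duration_s
  w_long <- 2 * pi * f0
  w_short <- 2 * w_long
  a_long <- amplitude_m
  a_short <- amplitude_m / 2

  # phase 0 starts the sinusoid moving positive, phase pi negative
  right <- initial_direction %in% c("UR", "DR")
  up <- initial_direction %in% c("UR", "UL")
  ph_h <- if (right) 0 else pi
  ph_v <- if (up) 0 else pi

  env <- raised_cosine_envelope(t, duration_s, envelope_rise_s)
  if (orientation == "vertical") {
    h <- a_short * sin(w_short * t + ph_h); dh <- a_short * w_short * cos(w_short * t + ph_h)
    v <- a_long * sin(w_long * t + ph_v);  dv <- a_long * w_long * cos(w_long * t + ph_v)
  } else {
    h <- a_long * sin(w_long * t + ph_h);  dh <- a_long * w_long * cos(w_long * t + ph_h)
    v <- a_short * sin(w_short * t + ph_v); dv <- a_short * w_short * cos(w_short * t + ph_v)
  }
  pos <- cbind(h = env$e * h, v = env$e * v)
  vel <- cbind(h = env$de * h + env$e * dh, v = env$de * v + env$e * dv)

  new_kin_trace(t, pos, vel, env$e, rate_hz,
                movement_type = "figure8",
                initial_direction = initial_direction,
                orientation = orientation, plane = "frontal")
}

# Raised-cosine on/off envelope and its analytic derivative.
raised_cosine_envelope <- function(t, duration_s, rise_s) {
  e <- rep(1, length(t))
  de <- rep(0, length(t))
  head_idx <- t < rise_s
  tail_idx <- t > duration_s - rise_s
  e[head_idx] <- 0.5 * (1 - cos(pi * t[head_idx] / rise_s))
  de[head_idx] <- (pi / (2 * rise_s)) * sin(pi * t[head_idx] / rise_s)
  tt <- duration_s - t[tail_idx]
  e[tail_idx] <- 0.5 * (1 - cos(pi * tt / rise_s))
  de[tail_idx] <- -(pi / (2 * rise_s)) * sin(pi * tt / rise_s)
  list(e = e, de = de)
}

#' Point-to-point reaching kinematics with a minimum-jerk profile
#'
#' Straight-line reach from the origin in a given direction with the
#' minimum-jerk position profile `s(tau) = d (10 tau^3 - 15 tau^4 + 6 tau^5)`,
#' the standard model for rapid discrete reaching: bell-shaped speed, zero
#' velocity and acceleration at both ends, peak speed `1.875 d / T`.
#'
#' @param direction_deg Movement direction in degrees (0 = rightward,
#'   90 = upward, measured in the movement plane).
#' @param distance_m Movement extent in meters (> 0).
#' @param duration_s Movement duration in seconds (> 0).
#' @param rate_hz Sampling rate in Hz.
#' @return A `kin_trace` object (see [make_figure_eight()]); the `envelope`
#'   field is the unit-peak speed profile.
#' @export
make_point_to_point <- function(direction_deg, distance_m = 0.2,
                                duration_s = 0.8, rate_hz = 100) {
  if (distance_m <= 0) stopf("distance_m must be > 0")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (rate_hz < 20) stopf("rate_hz must be >= 20")
  t <- seq(0, duration_s, by = 1 / rate_hz)
  tau <- t / duration_s
  s <- distance_m * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  ds <- (distance_m / duration_s) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  u <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
  u[abs(u) < 1e-15] <- 0
  pos <- cbind(h = s * u[1L], v = s * u[2L])
  vel <- cbind(h = ds * u[1L], v = ds * u[2L])
  env <- ds / max(ds)
  new_kin_trace(t, pos, vel, env, rate_hz,
                movement_type = "discrete",
                initial_direction = direction_deg,
                orientation = NA_character_, plane = "frontal")
}

new_kin_trace <- function(time, position, velocity, envelope, rate_hz,
                          movement_type, initial_direction, orientation,
                          plane) {
  structure(list(time = time, position = position, velocity = velocity,
                 envelope = envelope, rate_hz = rate_hz,
                 movement_type = movement_type,
                 initial_direction = initial_direction,
                 orientation = orientation, plane = plane),
            class = "kin_trace")
}

#' Pad a kinematics trace with stationary rest
#'
#' Adds rest periods before and after the movement, holding the boundary
#' positions with zero velocity and zero activity envelope. Rest padding
#' makes the co-contraction module's "active during movement, silent at
#' rest" signature a testable contrast.
#'
#' @param kin A `kin_trace`.
#' @param pre_s,post_s Rest durations in seconds (default 0.5 each).
#' @return A `kin_trace` with extended time axis.
#' @export
pad_rest <- function(kin, pre_s = 0.5, post_s = 0.5) {
  stopifnot(inherits(kin, "kin_trace"))
  if (pre_s < 0 || post_s < 0) stopf("rest durations must be >= 0")
  dt <- 1 / kin$rate_hz
  n_pre <- round(pre_s * kin$rate_hz)
  n_post <- round(post_s * kin$rate_hz)
  n <- nrow(kin$position)
  hold <- function(row, k) matrix(rep(row, each = k), nrow = k)
  pos <- rbind(hold(kin$position[1L, ], n_pre), kin$position,
               hold(kin$position[n, ], n_post))
  zeros <- function(k) matrix(0, nrow = k, ncol = 2)
  vel <- rbind(zeros(n_pre), kin$velocity, zeros(n_post))
  env <- c(rep(0, n_pre), kin$envelope, rep(0, n_post))
  time <- seq(0, by = dt, length.out = nrow(pos))
  out <- kin
  out$time <- time
  out$position <- pos
  out$velocity <- vel
  out$envelope <- env
  colnames(out$position) <- colnames(out$velocity) <- c("h", "v")
  out
}

#' @export
print.kin_trace <- function(x, ...) {
  dirlab <- if (is.numeric(x$initial_direction))
    sprintf("%g deg", x$initial_direction) else x$initial_direction
  cat(sprintf("Kinematics trace: %s (%s), %d samples at %g Hz (%.2f s)\n",
              x$movement_type, dirlab, length(x$time), x$rate_hz,
              length(x$time) / x$rate_hz))
  if (!is.na(x$orientation))
    cat(sprintf("  orientation: %s, plane: %s\n", x$orientation, x$plane))
  invisible(x)
}
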