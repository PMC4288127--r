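#' Default simulation protocol
#'
#' The factorial layout of the study conditions: `n_subjects` subjects each
#' tracing figure eights in 4 initial directions with `repetitions` repeats
#' (7 x 4 x 2 = 56 trials by default, vertical figure in the frontal plane)
#' plus, when `discrete = TRUE`, one set of eight point-to-point movements
#' per subject (directions every 45 degrees).
#'
#' @param n_subjects,repetitions Protocol sizes.
#' @param directions Figure-eight initial directions.
#' @param orientation,plane Figure-eight condition.
#' @param discrete Include the eight-direction point-to-point set?
#' @param duration_s,amplitude_m,rate_hz,rest_s Kinematic parameters.
#' @param discrete_duration_s,discrete_distance_m Point-to-point parameters.
#' @param emg_rate_hz Raw EMG sampling rate.
#' @param noise_sd,tonic_gain Generative model parameters.
#' @param subject_jitter_sd Standard deviation of the per-subject weight
#'   magnitude jitter (sign template preserved); 0 gives identical weights
#'   for all subjects.
#' @param seed Master seed; all per-subject and per-trial seeds derive from
#'   it.
#' @return A named list understood by [make_dataset()].
#' @export
default_protocol <- function(n_subjects = 7, repetitions = 2,
                             directions = c("UR", "UL", "DR", "DL"),
                             orientation = "vertical", plane = "frontal",
                             discrete = TRUE,
                             duration_s = 1.5, amplitude_m = 0.3,
                             rate_hz = 100, rest_s = 0.5,
                             discrete_duration_s = 0.8,
                             discrete_distance_m = 0.2,
                             emg_rate_hz = 1000,
                             noise_sd = 0.05, tonic_gain = 1,
                             subject_jitter_sd = 0.05, seed = 1L) {
  list(n_subjects = n_subjects, repetitions = repetitions,
       directions = directions, orientation = orientation, plane = plane,
       discrete = discrete, duration_s = duration_s,
       amplitude_m = amplitude_m, rate_hz = rate_hz, rest_s = rest_s,
       discrete_duration_s = discrete_duration_s,
       discrete_distance_m = discrete_distance_m,
       emg_rate_hz = emg_rate_hz, noise_sd = noise_sd,
       tonic_gain = tonic_gain, subject_jitter_sd = subject_jitter_sd,
       seed = as.integer(seed))
}

#' Generate a full synthetic dataset
#'
#' One `emg_trial` per protocol cell. Each subject receives a jittered copy
#' of the ground-truth weight matrix (small zero-mean perturbation of the
#' weight magnitudes; the sign template is preserved and columns are
#' renormalized), emulating inter-subject variability. Every trial's noise
#' is seeded from the master seed and the trial id, so the dataset is fully
#' reproducible.
#'
#' @param protocol A protocol list from [default_protocol()].
#' @return An `emg_dataset`: list with `trials` (list of `emg_trial`),
#'   `subject_models` (per-subject `synergy_model`), and the `protocol`.
#' @export
make_dataset <- function(protocol = default_protocol()) {
  p <- protocol
  required <- c("n_subjects", "repetitions", "directions", "seed")
  if (!all(required %in% names(p)) || p$n_subjects < 1)
    stopf("protocol must list at least one subject, repetitions, directions and a seed")
  base_model <- make_synergy_model(noise_sd = p$noise_sd,
                                   tonic_gain = p$tonic_gain, seed = p$seed)
  subjects <- paste0("S", seq_len(p$n_subjects))
  models <- lapply(seq_along(subjects), function(i) {
    jitter_model(base_model, p$subject_jitter_sd,
                 stage_seed(p$seed, paste0("subject", i)))
  })
  names(models) <- subjects
  trials <- list()
  for (i in seq_along(subjects)) {
    for (dir in p$directions) {
      for (r in seq_len(p$repetitions)) {
        id <- sprintf("%s_fig8_%s_%s_r%d", subjects[i], p$orientation, dir, r)
        kin <- pad_rest(make_figure_eight(p$orientation, dir, p$duration_s,
                                          p$amplitude_m, p$rate_hz),
                        p$rest_s, p$rest_s)
        kin$plane <- p$plane
        trials[[id]] <- synthesize_trial(kin, models[[i]], p$emg_rate_hz,
                                         seed = stage_seed(p$seed, id),
                                         trial_id = id,
                                         subject_id = subjects[i])
      }
    }
    if (isTRUE(p$discrete)) {
      for (ang in seq(0, 315, by = 45)) {
        id <- sprintf("%s_discrete_%03d", subjects[i], ang)
        kin <- pad_rest(make_point_to_point(ang, p$discrete_distance_m,
                                            p$discrete_duration_s, p$rate_hz),
                        p$rest_s, p$rest_s)
        kin$plane <- p$plane
        trials[[id]] <- synthesize_trial(kin, models[[i]], p$emg_rate_hz,
                                         seed = stage_seed(p$seed, id),
                                         trial_id = id,
                                         subject_id = subjects[i])
      }
    }
  }
  structure(list(trials = trials, subject_models = models, protocol = p),
            class = "emg_dataset")
}

# Jitter weight magnitudes, keep the sign template, renormalize, validate.
jitter_model <- function(model, sd, seed) {
  if (sd == 0) return(model)
  W <- model$weights
  Wj <- with_seed(seed, {
    mag <- pmax(0.02, abs(W) + matrix(stats::rnorm(21, sd = sd), 7, 3))
    # entries the template constrains to be near zero stay near zero
    small <- abs(W) <= 0.15 / max(sqrt(colSums(W^2)), 1)
    mag[small] <- pmin(mag[small], 0.12)
    sign(W) * mag
  })
  make_synergy_model(weights = Wj, tonic_gain = model$tonic_gain,
                     noise_sd = model$noise_sd,
                     muscle_gains = model$muscle_gains,
                     baseline = model$baseline, seed = model$seed)
}

#' @export
print.emg_dataset <- function(x, ...) {
  tab <- table(vapply(x$trials, function(tr) tr$condition$movement_type, ""))
  cat(sprintf("Synthetic EMG dataset: %d trials, %d subjects (seed %d)\n",
              length(x$trials), length(x$subject_models), x$protocol$seed))
  print(tab)
  invisible(x)
}

#' Small canned dataset for tests and examples
#'
#' 2 subjects x 4 figure-eight directions x 1 repetition at the default
#' noise level, regenerated deterministically from the seed.
#'
#' @param seed Master seed.
#' @param discrete Include the discrete sets (default `FALSE`).
#' @return An `emg_dataset` with 8 figure-eight trials.
#' @export
make_fixtures <- function(seed = 1L, discrete = FALSE) {
  make_dataset(default_protocol(n_subjects = 2, repetitions = 1,
                                discrete = discrete, seed = seed))
}

#' Write / read a dataset as plain tabular files
#'
#' One wide CSV per trial (time, the 7 EMG channels in canonical order,
#' and the h/v endpoint position interpolated onto the EMG clock) plus a
#' `manifest.csv` with trial metadata and rates. Channel order is normative
#' and checked on read. On read-back, kinematic position is decimated to the
#' kinematic rate and velocity is recomputed by polynomial differentiation,
#' as for real recordings.
#'
#' @param dataset An `emg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset` returns the manifest data frame invisibly;
#'   `read_dataset` returns a list of `emg_trial`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "emg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$trials, function(tr) {
    kin <- tr$kinematics
    n <- ncol(tr$emg)
    t_emg <- seq(0, by = 1 / tr$emg_rate_hz, length.out = n)
    t_kin <- kin$time
    h <- stats::approx(t_kin, kin$position[, "h"], xout = pmin(t_emg, max(t_kin)))$y
    v <- stats::approx(t_kin, kin$position[, "v"], xout = pmin(t_emg, max(t_kin)))$y
    df <- data.frame(time = t_emg, t(tr$emg), h = h, v = v,
                     check.names = FALSE)
    f <- file.path(dir, paste0(tr$trial_id, ".csv"))
    utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    data.frame(trial_id = tr$trial_id, subject = tr$subject_id,
               movement_type = tr$condition$movement_type,
               direction = as.character(tr$condition$initial_direction),
               orientation = as.character(tr$condition$orientation),
               plane = as.character(tr$condition$plane),
               emg_rate_hz = tr$emg_rate_hz, kin_rate_hz = kin$rate_hz,
               file = basename(f), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$seed <- dataset$protocol$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    df <- utils::read.csv(file.path(dir, row$file), check.names = FALSE)
    need <- c("time", emg_muscles(), "h", "v")
    if (!identical(names(df)[seq_along(need)], need))
      stopf("trial file %s violates the canonical column order", row$file)
    emg <- t(as.matrix(df[, emg_muscles()]))
    step <- as.integer(round(row$emg_rate_hz / row$kin_rate_hz))
    idx <- seq(1L, nrow(df), by = step)
    pos <- cbind(h = df$h[idx], v = df$v[idx])
    vel <- differentiate_position(pos, row$kin_rate_hz)
    kin <- new_kin_trace(df$time[idx], pos, vel,
                         envelope = rep(NA_real_, length(idx)),
                         rate_hz = row$kin_rate_hz,
                         movement_type = row$movement_type,
                         initial_direction = row$direction,
                         orientation = row$orientation, plane = row$plane)
    structure(list(emg = emg, emg_rate_hz = row$emg_rate_hz,
                   kinematics = kin, envelope_true = NULL,
                   trial_id = row$trial_id, subject_id = row$subject,
                   condition = list(movement_type = row$movement_type,
                                    initial_direction = row$direction,
                                    orientation = row$orientation,
                                    plane = row$plane)),
              class = "emg_trial")
  })
  names(trials) <- manifest$trial_id
  trials
}
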