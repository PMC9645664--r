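#' Synthetic-cohort profile
#'
#' Ground-truth description of a simulated cohort of reaching trials recorded
#' KINARM-style (1 kHz position and force sampling, 15 cm forward reaches).
#' Lateral deviations carry an anticipatory component whose amplitude decays
#' across trials with a single slow rate, and a later within-trial corrective
#' component whose contribution to path length decays with an additional
#' fast rate; catch trials show the mirror image of the anticipatory
#' component, and the measured force channel has sign opposite to the
#' commanded background load.
#'
#' Angle amplitudes are in degrees, path amplitudes in metres, rates per
#' trial. Defaults give a cohort whose initial-angle series starts near
#' 20 deg and settles near 6 deg over 75 trials, with a fast-to-slow rate
#' ratio of 40 — the qualitative regime the analysis pipeline is meant to
#' resolve.
#'
#' @param n_participants cohort size (default 18).
#' @param fs sampling rate, Hz.
#' @param reach_distance start-to-goal distance, m.
#' @param move_duration movement time, s.
#' @param trial_duration recorded trial length, s.
#' @param pre_onset stationary hold before movement, s.
#' @param angle_amplitude decaying part of the anticipatory angle, deg.
#' @param angle_asymptote asymptotic anticipatory angle, deg.
#' @param lambda_slow slow (across-trial) decay rate, per trial.
#' @param lambda_fast fast (corrective) decay rate, per trial.
#' @param path_slow_amp,path_fast_amp path-length decay amplitudes, m.
#' @param path_base_margin corrective headroom added to the asymptotic path
#'   length, m.
#' @param angle_noise_sd trial-to-trial angle noise SD, deg.
#' @param path_noise_sd trial-to-trial path-length noise SD, m.
#' @param angle_intercept_sd between-participant SD of the anticipatory
#'   angle offset, deg.
#' @param position_noise_sd band-limited positional noise SD, m (0 disables).
#' @param force_noise_sd measured-force noise SD, N.
#' @param start_radius start-target radius used for the onset convention, m.
#' @return list of class \code{cohort_profile}.
#' @export
cohort_profile <- function(n_participants = 18, fs = 1000,
                           reach_distance = 0.15, move_duration = 0.5,
                           trial_duration = 0.8, pre_onset = 0.06,
                           angle_amplitude = 14, angle_asymptote = 6,
                           lambda_slow = 0.02, lambda_fast = 0.8,
                           path_slow_amp = 0.03, path_fast_amp = 0.035,
                           path_base_margin = 0.002,
                           angle_noise_sd = 1.5, path_noise_sd = 0.004,
                           angle_intercept_sd = 1.5,
                           position_noise_sd = 0, force_noise_sd = 0.05,
                           start_radius = 0.005) {
  stopifnot(n_participants >= 1, fs > 0, reach_distance > 0,
            move_duration > 0, trial_duration >= move_duration + pre_onset,
            lambda_slow >= 0, lambda_fast >= 0,
            angle_amplitude >= 0, path_slow_amp >= 0, path_fast_amp >= 0,
            angle_noise_sd >= 0, path_noise_sd >= 0, angle_intercept_sd >= 0,
            position_noise_sd >= 0, force_noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_profile")
}

# minimum-jerk position fraction and its s-derivative
min_jerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5
min_jerk_d <- function(s) 30 * s^2 - 60 * s^3 + 30 * s^4

# anticipatory lateral lobe: scaled derivative of the forward speed profile,
# zero at both movement endpoints, peak normalized to 1 (early peak)
lobe_anticipatory <- function(s) {
  g <- 2 * s * (1 - s) * (1 - 2 * s)
  s_pk <- (3 - sqrt(3)) / 6
  g / (2 * s_pk * (1 - s_pk) * (1 - 2 * s_pk))
}

# corrective lobe: smooth bump confined to the second half of the movement,
# after the initial-angle threshold crossing
lobe_corrective <- function(s) {
  out <- numeric(length(s))
  act <- s > 0.45 & s < 1
  out[act] <- sin(pi * (s[act] - 0.45) / 0.55)^2
  out
}

# fraction of movement time at which the hand crosses one third of the reach
crossing_fraction <- function() {
  stats::uniroot(function(s) min_jerk(s) - 1 / 3, c(0.1, 0.9),
                 tol = 1e-12)$root
}

# construct the x/y series for given lobe scales (no noise)
synth_xy <- function(profile, c_scale, d_scale) {
  n <- round(profile$trial_duration * profile$fs)
  t <- seq_len(n) / profile$fs
  s <- pmin(pmax((t - profile$pre_onset) / profile$move_duration, 0), 1)
  y <- profile$reach_distance * min_jerk(s)
  x <- c_scale * lobe_anticipatory(s) + d_scale * lobe_corrective(s)
  list(t = t, x = x, y = y)
}

# path length of a constructed trial under the pipeline's onset convention
synth_path_length <- function(profile, c_scale, d_scale) {
  xy <- synth_xy(profile, c_scale, d_scale)
  onset <- reach_onset(xy$x, xy$y, profile$start_radius)
  vx <- differentiate(xy$x, profile$fs)
  vy <- differentiate(xy$y, profile$fs)
  path_length(vx, vy, onset, profile$fs, 0.6)
}

# lobe scale that yields the requested initial angle (deg, CCW positive)
angle_to_scale <- function(profile, angle_deg) {
  s_star <- crossing_fraction()
  x_c <- -tan(angle_deg * pi / 180) * profile$reach_distance / 3
  x_c / lobe_anticipatory(s_star)
}

#' Generate one synthetic trial
#'
#' Builds a 1 kHz trial whose measured initial angle equals
#' \code{target_angle_deg} exactly (by construction of the anticipatory
#' lobe) and, when \code{target_path_m} is given, whose measured path length
#' equals it too (the corrective-lobe scale is solved by root finding; it is
#' clamped at zero if the anticipatory lobe alone already exceeds the
#' target). Draws any configured positional/force noise from the current RNG
#' stream.
#'
#' @param profile a [cohort_profile()].
#' @param spec one schedule row (needs \code{phi_N}).
#' @param target_angle_deg planted initial angle (deg).
#' @param target_path_m planted path length (m) or \code{NA} to skip the
#'   corrective lobe.
#' @return tibble: t_ms, x_m, y_m, fx_N, fy_N.
#' @export
generate_trial_kinematics <- function(profile, spec, target_angle_deg,
                                      target_path_m = NA_real_) {
  c_scale <- angle_to_scale(profile, target_angle_deg)
  d_scale <- 0
  if (is.finite(target_path_m)) {
    base <- synth_path_length(profile, c_scale, 0)
    if (target_path_m > base) {
      sgn <- if (c_scale == 0) 1 else -sign(c_scale)  # corrective overshoot
      f <- function(d) synth_path_length(profile, c_scale, sgn * d) - target_path_m
      hi <- 0.02
      while (f(hi) < 0 && hi < 0.3) hi <- hi * 2
      d_scale <- sgn * stats::uniroot(f, c(0, hi), tol = 1e-10)$root
    }
  }
  xy <- synth_xy(profile, c_scale, d_scale)
  n <- length(xy$t)
  if (profile$position_noise_sd > 0) {
    xy$x <- xy$x + lowpass(stats::rnorm(n, 0, profile$position_noise_sd),
                           profile$fs, fc = 25)
    xy$y <- xy$y + lowpass(stats::rnorm(n, 0, profile$position_noise_sd),
                           profile$fs, fc = 25)
  }
  fx <- -spec$phi_N + stats::rnorm(n, 0, profile$force_noise_sd)
  fy <- stats::rnorm(n, 0, profile$force_noise_sd)
  tibble::tibble(t_ms = xy$t * 1000, x_m = xy$x, y_m = xy$y,
                 fx_N = fx, fy_N = fy)
}

# sign of the field a cue announces: field trials carry their own theta;
# catch (and washout) trials inherit the sign implied by context and cue
assoc_field_sign <- function(context, phi, theta, is_catch) {
  if (!is_catch && theta != 0) return(sign(theta))
  if (context != 0 && phi != 0) return(context * sign(phi))
  if (phi != 0) return(sign(phi))
  0
}

#' Generate a synthetic cohort over a trial schedule
#'
#' Plays a trial schedule for every participant, planting per-trial metric
#' targets with known ground truth: the anticipatory angle magnitude decays
#' across field trials of each cue at the slow rate (plus a per-participant
#' random offset), path length carries both the slow and the fast decay
#' component, catch trials show the mirror-image anticipatory deviation, and
#' field-trial deviations point in the field's push direction. Decay
#' counters are kept per cue (context, background direction and magnitude).
#'
#' @param profile a [cohort_profile()].
#' @param schedule a schedule tibble ([experiment1_schedule()] etc.).
#' @param seed integer seed.
#' @return list of class \code{synthetic_cohort}: \code{trials} (long tibble:
#'   participant, trial, t_ms, x_m, y_m, fx_N, fy_N), \code{trial_truth}
#'   (per trial: planted targets and decay index), \code{ground_truth}
#'   (per participant: intercept and the profile's decay parameters),
#'   \code{schedule}, \code{seed}.
#' @export
generate_cohort <- function(profile, schedule, seed = 1L) {
  stopifnot(nrow(schedule) >= 1)
  set.seed(seed)
  intercepts <- stats::rnorm(profile$n_participants, 0, profile$angle_intercept_sd)
  all_trials <- vector("list", profile$n_participants)
  all_truth <- vector("list", profile$n_participants)
  slow_amps <- numeric(profile$n_participants)
  epl <- function(angle_deg) {
    synth_path_length(profile, angle_to_scale(profile, abs(angle_deg)), 0)
  }
  for (j in seq_len(profile$n_participants)) {
    a_off <- intercepts[j]
    # anticipatory path lengths at the asymptotic and initial angle levels;
    # the slow path amplitude must cover the anticipatory excess (convex in
    # the angle, so the trial-1 excess bounds it at every trial)
    base_inf <- epl(profile$angle_asymptote + a_off)
    excess_1 <- epl(profile$angle_asymptote + a_off + profile$angle_amplitude) -
      base_inf
    p_slow <- max(profile$path_slow_amp, excess_1)
    slow_amps[j] <- p_slow
    L0 <- base_inf + profile$path_base_margin
    counters <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(schedule))
    truth <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      sp <- schedule[i, ]
      key <- paste(sp$context, sign(sp$phi_N), abs(sp$phi_N), sep = ":")
      kk <- counters[[key]] %||% 0L
      if (!sp$is_catch && sp$theta_Nspm != 0) kk <- kk + 1L
      counters[[key]] <- kk
      k_idx <- max(kk, 1L)
      level <- profile$angle_asymptote + a_off +
        profile$angle_amplitude * exp(-profile$lambda_slow * (k_idx - 1))
      level <- level + stats::rnorm(1, 0, profile$angle_noise_sd)
      sgn <- assoc_field_sign(sp$context, sp$phi_N, sp$theta_Nspm, sp$is_catch)
      if (sp$is_catch || sp$theta_Nspm == 0) {
        ang <- sgn * level       # mirror image of the anticipated push
        pl <- NA_real_
      } else {
        ang <- -sgn * level      # deviation in the field's push direction
        pl <- L0 +
          p_slow * exp(-profile$lambda_slow * (k_idx - 1)) +
          profile$path_fast_amp * exp(-profile$lambda_fast * (k_idx - 1)) +
          stats::rnorm(1, 0, profile$path_noise_sd)
      }
      tr <- generate_trial_kinematics(profile, sp, ang, pl)
      rows[[i]] <- dplyr::mutate(tr, participant = j, trial = sp$trial,
                                 .before = 1)
      truth[[i]] <- tibble::tibble(participant = j, trial = sp$trial,
                                   cue = key, k_index = k_idx,
                                   target_angle_deg = ang,
                                   target_path_m = pl)
    }
    all_trials[[j]] <- dplyr::bind_rows(rows)
    all_truth[[j]] <- dplyr::bind_rows(truth)
  }
  structure(
    list(trials = dplyr::bind_rows(all_trials),
         trial_truth = dplyr::bind_rows(all_truth),
         ground_truth = tibble::tibble(
           participant = seq_len(profile$n_participants),
           angle_intercept = intercepts,
           lambda_slow = profile$lambda_slow,
           lambda_fast = profile$lambda_fast,
           angle_amplitude = profile$angle_amplitude,
           angle_asymptote = profile$angle_asymptote,
           path_slow_amp = slow_amps,
           path_fast_amp = profile$path_fast_amp,
           seed = seed),
         schedule = schedule, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", max(x$trials$participant), "participants x",
      max(x$trials$trial), "trials\n")
  invisible(x)
}

#' Generate metric-space decay series for a cohort
#'
#' Draws per-participant series directly from a single- or dual-rate decay
#' curve with Gaussian trial noise and participant random intercepts — the
#' lightweight generator used to study parameter recovery of the decay
#' fitters themselves.
#'
#' @param n_participants cohort size.
#' @param x trial grid.
#' @param coef named vector: \code{a0, a1, b1} (single) or additionally
#'   \code{a2, b2} (dual), rates signed (negative = decay).
#' @param noise_sd trial noise SD.
#' @param intercept_sd participant random-intercept SD.
#' @param seed integer seed.
#' @return tibble: participant, x, y.
#' @export
generate_decay_cohort <- function(n_participants, x, coef, noise_sd = 0,
                                  intercept_sd = 0, seed = 1L) {
  set.seed(seed)
  mu <- coef["a0"] + coef["a1"] * exp(coef["b1"] * x)
  if (all(c("a2", "b2") %in% names(coef))) {
    mu <- mu + coef["a2"] * exp(coef["b2"] * x)
  }
  purrr::map_dfr(seq_len(n_participants), function(j) {
    tibble::tibble(
      participant = j,
      x = x,
      y = mu + stats::rnorm(1, 0, intercept_sd) +
        stats::rnorm(length(x), 0, noise_sd)
    )
  })
}
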