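#' Sensitivity of the one-step prediction to the field gain
#'
#' For the declared discretization the predicted next state is linear in the
#' believed field gain: \code{x_pred = A x + theta * G * vy + ...}, so the
#' derivative with respect to \code{theta} is the disturbance column \code{G}
#' scaled by the forward velocity of the state the prediction was made from.
#'
#' @param plant a [build_plant()] object.
#' @param state the (estimated) state the prediction used, length 6.
#' @return length-6 numeric vector, d(x_pred)/d(theta).
#' @export
theta_sensitivity <- function(plant, state) {
  stopifnot(all(is.finite(state)))
  drop(plant$G) * state[4]
}

#' Gradient update of the force-field estimate
#'
#' Least-squares identification step: the prediction error is projected onto
#' the sensitivity direction,
#' \deqn{\hat\theta \leftarrow \hat\theta + \gamma \, \langle s, e\rangle / c.}
#' The constant \code{scale} \eqn{c} fixes the units of the learning rate;
#' the simulator passes the squared sensitivity norm at a reference forward
#' speed, which makes \eqn{\gamma} a dimensionless fraction of the gain
#' error corrected per step at that speed, with the update strength growing
#' quadratically with forward speed below it. With \code{scale = 1} this is
#' the raw gradient rule.
#'
#' @param theta_hat current estimate (N·s/m).
#' @param sens sensitivity vector from [theta_sensitivity()].
#' @param e prediction error: measured minus predicted state.
#' @param gamma learning rate, >= 0.
#' @param scale positive normalization constant \eqn{c}.
#' @return updated estimate.
#' @export
update_theta <- function(theta_hat, sens, e, gamma, scale = 1) {
  stopifnot(gamma >= 0, length(sens) == length(e), scale > 0)
  theta_hat + gamma * sum(sens * e) / scale
}

#' Learning-rate schedule configuration
#'
#' The offline (trial-to-trial) rate gamma1 decays from its start value toward
#' its asymptote, and the online rate gamma2 rises from its start value toward
#' its asymptote, both with first-order (exponential) trial dynamics:
#' \code{gamma(k) = end + (start - end) * exp(-rate * (k - 1))}.
#' Defaults follow the model's standard operating range: gamma1 from 0.001
#' to 0 with rate constant 0.02 per trial, gamma2 from 0 to 0.2 with rate
#' constant 0.4 per trial.
#'
#' @param gamma1_start,gamma1_end,gamma1_rate offline-rate schedule.
#' @param gamma2_start,gamma2_end,gamma2_rate online-rate schedule.
#' @return list of class \code{learning_rates}.
#' @export
learning_rates <- function(gamma1_start = 0.001, gamma1_end = 0,
                           gamma1_rate = 0.02,
                           gamma2_start = 0, gamma2_end = 0.2,
                           gamma2_rate = 0.4) {
  vals <- c(gamma1_start, gamma1_end, gamma1_rate,
            gamma2_start, gamma2_end, gamma2_rate)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("invalid-config: learning-rate constants must be finite and >= 0", call. = FALSE)
  }
  structure(list(gamma1_start = gamma1_start, gamma1_end = gamma1_end,
                 gamma1_rate = gamma1_rate,
                 gamma2_start = gamma2_start, gamma2_end = gamma2_end,
                 gamma2_rate = gamma2_rate),
            class = "learning_rates")
}

#' Evaluate the learning-rate schedules at a trial index
#'
#' @param k trial index (>= 1).
#' @param cfg a [learning_rates()] object.
#' @return named numeric vector \code{c(gamma1, gamma2)}.
#' @export
learning_rate_schedule <- function(k, cfg = learning_rates()) {
  stopifnot(all(k >= 1))
  g1 <- cfg$gamma1_end + (cfg$gamma1_start - cfg$gamma1_end) * exp(-cfg$gamma1_rate * (k - 1))
  g2 <- cfg$gamma2_end + (cfg$gamma2_start - cfg$gamma2_end) * exp(-cfg$gamma2_rate * (k - 1))
  c(gamma1 = g1, gamma2 = g2)
}

#' Scale every learning-rate constant by a common factor
#'
#' Used for the sensitivity analysis in which all schedule constants (start
#' and asymptote values and rate constants) are doubled or halved.
#'
#' @param cfg a [learning_rates()] object.
#' @param factor positive multiplier.
#' @return a new [learning_rates()] object.
#' @export
scale_learning_rates <- function(cfg, factor) {
  stopifnot(factor > 0)
  do.call(learning_rates, lapply(unclass(cfg), function(v) v * factor))
}

# gain at step t of the finite-horizon problem, recomputed from the terminal
# condition down to t under the believed gain theta
lqg_gain_at <- function(plant, theta, weights, horizon, t) {
  A <- plant_A_theta(plant, theta)
  B <- plant$B
  Qs <- state_cost_matrix(weights)
  Qr <- running_cost_matrix(weights)
  Ru <- diag(2) * weights$effort
  hold_from <- max(1L, horizon - weights$hold_steps + 1L)
  S <- Qs
  for (s in seq(horizon, t)) {
    BtS <- crossprod(B, S)
    Ls <- solve(Ru + BtS %*% B, BtS %*% A)
    if (s == t) return(Ls)
    Qt <- if (s >= hold_from) Qs else Qr
    S <- Qt + crossprod(A, S %*% (A - B %*% Ls))
    S <- (S + t(S)) / 2
  }
  stop("index error: t outside horizon", call. = FALSE)
}

#' Simulate one reaching trial under an adaptive LQG controller
#'
#' Runs a single trial of the adaptive control loop. Two variants are
#' provided. \code{"offline"} (Model 1): the controller is synthesized once
#' from the trial-initial estimate \code{theta_hat_k} and never re-derived;
#' the estimate is still updated internally each step with the offline rate
#' \code{gamma1}, and its value at the final step becomes the next trial's
#' \code{theta_hat_k}. \code{"online_offline"} (Model 2): in addition, a
#' within-trial increment is updated with the online rate \code{gamma2}
#' (reset to zero at each trial's first step) and the controller is
#' re-synthesized before each command from \code{theta_hat_k} plus that
#' online increment; the gamma1 accumulation updates the parameter but never
#' the within-trial controller. The carried-over estimate uses only the
#' gamma1 accumulation, so the two variants coincide exactly when
#' \code{gamma2 = 0}.
#'
#' The velocity-dependent field switches on when the cursor leaves the start
#' target; the background load is on (ramp complete) throughout. Catch trials
#' (\code{is_catch}) run with the field off while the controller still
#' anticipates it.
#'
#' Adaptation operates on delayed sensory information: the update applied at
#' step t uses the prediction error from \code{adapt_delay_s} earlier
#' (default 0.07 s of sensorimotor loop delay). The delayed error is
#' corrected for the estimate changes already applied since that sample
#' (internal-model compensation of the self-generated delay, in the spirit
#' of a Smith predictor), so the update senses the current gain error and
#' the delayed loop does not overshoot. Together with the quadratic speed
#' weighting of the learning rule, the delay concentrates within-trial
#' adaptation after the initial-angle threshold crossing, so the initial
#' angle reflects the trial-initial estimate while path length also
#' benefits from within-trial corrections.
#'
#' @param variant \code{"offline"} or \code{"online_offline"}.
#' @param spec list or one-row data frame with \code{theta}, \code{phi},
#'   \code{is_catch}.
#' @param theta_hat_k trial-initial field estimate (N·s/m).
#' @param rates named vector \code{c(gamma1, gamma2)} for this trial.
#' @param plant a [build_plant()] object.
#' @param weights a [cost_weights()] object.
#' @param horizon steps per trial (default 80: 0.6 s movement + 0.2 s hold at
#'   dt = 0.01).
#' @param start_radius start-target radius (m) gating field onset.
#' @param noise logical; simulate with process/observation noise (uses the
#'   current RNG stream).
#' @param resynth_stride re-synthesize the online controller every this many
#'   steps (1 = every step).
#' @param adapt_delay_s sensory delay of the adaptation loop (s).
#' @param ref_speed reference forward speed (m/s) fixing the learning-rate
#'   units; see [update_theta()].
#' @return list with \code{trial} (tibble: t_s, px, py, vx, vy, fx, fy, ux,
#'   uy, theta_hat) and \code{theta_next}.
#' @export
simulate_trial <- function(variant, spec, theta_hat_k, rates, plant, weights,
                           horizon = 80L, start_radius = 0.005, noise = FALSE,
                           resynth_stride = 1L, adapt_delay_s = 0.07,
                           ref_speed = 0.6) {
  if (!variant %in% c("offline", "online_offline")) {
    stop("invalid-config: unknown variant '", variant, "'", call. = FALSE)
  }
  theta_true <- if (isTRUE(spec$is_catch)) 0 else spec$theta
  ctx_true <- force_context(theta = theta_true, phi = spec$phi, ramp_duration = 0)
  ref <- goal_state(force_context(phi = spec$phi))
  gains_k <- synthesize_controller(plant, theta_hat_k, weights, horizon)

  x <- c(0, 0, 0, 0, -spec$phi, 0)   # holding still against the background
  est <- list(x_hat = x, P = diag(6) * 1e-6)
  d1 <- 0   # gamma1 accumulation (carried over across trials)
  d2 <- 0   # gamma2 within-trial increment (online variant only)
  g1 <- unname(rates["gamma1"]); g2 <- unname(rates["gamma2"])
  online <- variant == "online_offline"
  scale <- sum(plant$G^2) * ref_speed^2
  delay <- max(0L, round(adapt_delay_s / plant$dt))

  n <- horizon
  out <- matrix(NA_real_, n + 1L, 9L)
  out[1L, ] <- c(x, 0, 0, theta_hat_k)
  sens_buf <- matrix(0, n, 6L)
  err_buf <- matrix(0, n, 6L)
  theta_buf <- numeric(n)
  field_on <- FALSE
  L_cur <- NULL
  for (t in seq_len(n)) {
    # the parameter evolves with both accumulators; the controller follows
    # only the online increment (gamma1 updates the parameter, never the
    # within-trial controller)
    theta_par <- theta_hat_k + d1 + d2
    theta_ctl <- theta_hat_k + d2
    if (online) {
      if (is.null(L_cur) || (t - 1L) %% resynth_stride == 0L) {
        L_cur <- lqg_gain_at(plant, theta_ctl, weights, n, t)
      }
      u <- drop(ref$u_star - L_cur %*% (est$x_hat - ref$x_star))
    } else {
      u <- control_command(gains_k, est$x_hat, t, ref)
    }
    if (!field_on && sqrt(x[1]^2 + x[2]^2) > start_radius) field_on <- TRUE
    x <- plant_step(plant, x, u, ctx_true, t = (t - 1) * plant$dt,
                    field_on = field_on, noise = noise)
    y <- x
    if (isTRUE(noise) && plant$obs_noise_scale > 0) {
      y <- x + stats::rnorm(6, 0, plant$obs_noise_scale)
    }
    stp <- estimate_step(plant, theta_par, est, u, y, bg_force = spec$phi)
    sens_buf[t, ] <- theta_sensitivity(plant, est$x_hat)
    err_buf[t, ] <- y - stp$x_pred
    theta_buf[t] <- theta_par
    td <- t - delay
    if (td >= 1L) {
      s_d <- sens_buf[td, ]
      # offline (consolidation) update: evidence referenced to the model the
      # trial was planned with, so online corrections are not double-credited
      e_k <- err_buf[td, ] + (theta_buf[td] - theta_hat_k) * s_d
      d1 <- d1 + update_theta(0, s_d, e_k, g1, scale = scale)
      if (online) {
        # online update: delayed error re-referenced to the current estimate
        # (internal-model compensation of the loop delay; no overshoot)
        e_now <- err_buf[td, ] - (theta_par - theta_buf[td]) * s_d
        d2 <- d2 + update_theta(0, s_d, e_now, g2, scale = scale)
      }
    }
    est <- stp
    out[t + 1L, ] <- c(x, u, theta_hat_k + d1 + d2)
  }
  trial <- tibble::tibble(
    t_s = seq(0, n) * plant$dt,
    px = out[, 1], py = out[, 2], vx = out[, 3], vy = out[, 4],
    fx = out[, 5], fy = out[, 6], ux = out[, 7], uy = out[, 8],
    theta_hat = out[, 9]
  )
  list(trial = trial, theta_next = theta_hat_k + d1)
}

#' Simulate a full session of trials
#'
#' Threads the trial-initial field estimate across an entire trial schedule.
#' By default a single signed estimate is shared across all trials (random
#' alternation of opposite fields then behaves as partial unlearning);
#' \code{estimate_by = "cue"} keeps one estimate per background-force cue
#' (signed direction and magnitude), modelling separate motor memories.
#'
#' @param schedule tibble of trial specs (see [experiment1_schedule()] or
#'   [constant_schedule()]); needs columns \code{phi_N}, \code{theta_Nspm},
#'   \code{is_catch}.
#' @param variant \code{"offline"} or \code{"online_offline"}.
#' @param plant,weights,horizon,start_radius,noise,resynth_stride,adapt_delay_s,ref_speed
#'   passed to [simulate_trial()].
#' @param rates_cfg a [learning_rates()] object.
#' @param theta0 initial estimate (N·s/m).
#' @param estimate_by \code{"single"} or \code{"cue"}.
#' @param seed optional integer seed (only relevant with \code{noise = TRUE}).
#' @return list of class \code{reach_session}: \code{trials} (long tibble with
#'   a \code{trial} column), \code{theta_k} (tibble: trial, theta_hat_k),
#'   \code{variant}, \code{rates_cfg}.
#' @export
simulate_session <- function(schedule, variant, plant = build_plant(),
                             weights = cost_weights(),
                             rates_cfg = learning_rates(), theta0 = 0,
                             horizon = 80L, start_radius = 0.005,
                             noise = FALSE, resynth_stride = 1L,
                             adapt_delay_s = 0.07, ref_speed = 0.6,
                             estimate_by = c("single", "cue"),
                             seed = NULL) {
  stopifnot(nrow(schedule) >= 1)
  estimate_by <- match.arg(estimate_by)
  if (!is.null(seed)) set.seed(seed)
  est_map <- new.env(parent = emptyenv())
  cue_key <- function(spec) {
    if (estimate_by == "single") "all" else paste0(sign(spec$phi), ":", abs(spec$phi))
  }
  trials <- vector("list", nrow(schedule))
  theta_k <- numeric(nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    spec <- list(theta = schedule$theta_Nspm[k], phi = schedule$phi_N[k],
                 is_catch = schedule$is_catch[k])
    key <- cue_key(spec)
    th <- if (is.null(est_map[[key]])) theta0 else est_map[[key]]
    theta_k[k] <- th
    rates <- learning_rate_schedule(k, rates_cfg)
    res <- simulate_trial(variant, spec, th, rates, plant, weights,
                          horizon = horizon, start_radius = start_radius,
                          noise = noise, resynth_stride = resynth_stride,
                          adapt_delay_s = adapt_delay_s, ref_speed = ref_speed)
    est_map[[key]] <- res$theta_next
    trials[[k]] <- dplyr::mutate(res$trial, trial = k, .before = 1)
  }
  structure(
    list(trials = dplyr::bind_rows(trials),
         theta_k = tibble::tibble(trial = seq_len(nrow(schedule)),
                                  theta_hat_k = theta_k),
         variant = variant, rates_cfg = rates_cfg,
         dt = plant$dt),
    class = "reach_session"
  )
}

#' @method print reach_session
#' @export
print.reach_session <- function(x, ...) {
  cat("<reach_session>", x$variant, "variant,",
      max(x$trials$trial), "trials\n")
  invisible(x)
}

#' Average metric series over replicate simulated sessions
#'
#' Runs \code{n_runs} independent noisy sessions of the same schedule and
#' averages the per-trial metrics across them — the model-side analogue of
#' averaging a metric series across participants before fitting decay
#' models, which is how group-level decay constants are estimated.
#'
#' @inheritParams simulate_session
#' @param n_runs number of replicate sessions (runs use seeds
#'   \code{seed + 1, ..., seed + n_runs}).
#' @param seed integer base seed.
#' @param ... passed to [simulate_session()].
#' @return tibble: trial, initial_angle_deg, path_length_m (averages across
#'   runs).
#' @export
average_session_metrics <- function(schedule, variant, n_runs = 3, seed = 1,
                                    plant = build_plant(),
                                    weights = cost_weights(),
                                    rates_cfg = learning_rates(), ...) {
  ms <- lapply(seq_len(n_runs), function(i) {
    s <- simulate_session(schedule, variant, plant = plant, weights = weights,
                          rates_cfg = rates_cfg, noise = TRUE,
                          seed = seed + i, ...)
    session_metrics(s)
  })
  tibble::tibble(
    trial = ms[[1]]$trial,
    initial_angle_deg = rowMeans(sapply(ms, function(m) m$initial_angle_deg)),
    path_length_m = rowMeans(sapply(ms, function(m) m$path_length_m))
  )
}

#' Reference study conditions for the model simulations
#'
#' Bundles the conditions under which the package's reference simulations of
#' the constant-field session are run: the default plant with calibrated
#' motor noise (process noise 0.5 N, observation noise 1e-4), the default
#' cost weights, a 75-trial constant-field schedule (phi = 4 N,
#' theta = 13 N·s/m) and the default learning-rate schedules. These are the
#' conditions used by the acceptance analyses and the vignette.
#'
#' @return list with \code{plant}, \code{weights}, \code{schedule},
#'   \code{rates_cfg}.
#' @export
reference_conditions <- function() {
  list(plant = build_plant(process_noise_scale = 0.5, obs_noise_scale = 1e-4),
       weights = cost_weights(),
       schedule = constant_schedule(75),
       rates_cfg = learning_rates())
}

#' Kinematic metrics for a simulated session
#'
#' Computes initial angle and path length for every trial of a
#' [simulate_session()] result, using the same metric definitions as the
#' recorded-data pipeline. The simulator's trajectories are already smooth and
#' sampled at 1/dt, so no low-pass filtering is applied.
#'
#' @param session a \code{reach_session}.
#' @param reach_distance start-to-goal distance (m).
#' @param start_radius start-target radius (m).
#' @param t_max path-length truncation after onset (s).
#' @return tibble: trial, is_catch flag columns absent; initial_angle_deg,
#'   path_length_m, vy_at_threshold.
#' @export
session_metrics <- function(session, reach_distance = 0.15,
                            start_radius = 0.005, t_max = 0.6) {
  fs <- 1 / session$dt
  session$trials |>
    dplyr::group_by(.data$trial) |>
    dplyr::group_modify(function(df, key) {
      trial_metrics_xy(df$px, df$py, fs = fs,
                       reach_distance = reach_distance,
                       start_radius = start_radius, t_max = t_max,
                       filter_cutoff_hz = NULL)
    }) |>
    dplyr::ungroup()
}
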