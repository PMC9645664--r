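#' Quadratic cost weights for the reach controller
#'
#' The controller minimizes accumulated command effort plus (i) a full state
#' cost applied over the final \code{hold_steps} of the horizon (including
#' the terminal step), which sets the arrival time and the stabilization at
#' the goal, and (ii) a running cost on lateral deviation from the straight
#' start-to-goal line applied at every step, which encodes the task
#' instruction to reach straight. Without the running lateral term the
#' effort-optimal reach under a known velocity-dependent field curves
#' substantially to exploit the field; with it, a controller that knows the
#' field produces near-straight trajectories, as adapted movements do.
#'
#' @param position weight on squared position error (per m^2), hold window.
#' @param velocity weight on squared velocity (per (m/s)^2), hold window.
#' @param force weight on squared actuator-force deviation (per N^2), hold
#'   window.
#' @param lateral_running running weight on squared lateral (x) deviation
#'   (per m^2), all steps.
#' @param effort command effort weight r > 0 (per N^2).
#' @param hold_steps number of final horizon steps over which the full state
#'   cost applies.
#' @return list of class \code{cost_weights}.
#' @export
cost_weights <- function(position = 2e4, velocity = 2e2, force = 1,
                         lateral_running = 1e4, effort = 1e-2,
                         hold_steps = 20L) {
  stopifnot(position >= 0, velocity >= 0, force >= 0, lateral_running >= 0,
            hold_steps >= 1)
  if (!is.finite(effort) || effort <= 0) {
    stop("invalid-config: effort weight must be > 0", call. = FALSE)
  }
  structure(list(position = position, velocity = velocity, force = force,
                 lateral_running = lateral_running, effort = effort,
                 hold_steps = as.integer(hold_steps)),
            class = "cost_weights")
}

state_cost_matrix <- function(weights) {
  diag(c(weights$position, weights$position,
         weights$velocity, weights$velocity,
         weights$force, weights$force))
}

running_cost_matrix <- function(weights) {
  diag(c(weights$lateral_running, 0, 0, 0, 0, 0))
}

#' Synthesize finite-horizon LQG feedback gains
#'
#' Solves the backward Riccati recursion for the plant augmented with the
#' believed velocity-dependent field gain \code{theta_hat}, returning one
#' feedback gain per time step. Gains map the goal-referenced estimated state
#' onto commanded force.
#'
#' @param plant a [build_plant()] object.
#' @param theta_hat believed force-field gain (N·s/m).
#' @param weights a [cost_weights()] object.
#' @param horizon number of steps (>= 1).
#' @return object of class \code{lqg_gains}: list with \code{L} (list of 2x6
#'   gains, one per step), \code{horizon}, \code{theta_hat}.
#' @export
synthesize_controller <- function(plant, theta_hat, weights, horizon) {
  stopifnot(horizon >= 1)
  A <- plant_A_theta(plant, theta_hat)
  B <- plant$B
  Qs <- state_cost_matrix(weights)
  Ru <- diag(2) * weights$effort
  Qr <- running_cost_matrix(weights)
  hold_from <- max(1L, horizon - weights$hold_steps + 1L)
  L <- vector("list", horizon)
  S <- Qs  # terminal cost
  for (t in seq(horizon, 1L)) {
    BtS <- crossprod(B, S)
    Lt <- solve(Ru + BtS %*% B, BtS %*% A)
    if (!all(is.finite(Lt))) stop("numerical-failure: Riccati iterate not finite", call. = FALSE)
    L[[t]] <- Lt
    Qt <- if (t >= hold_from) Qs else Qr
    S <- Qt + crossprod(A, S %*% (A - B %*% Lt))
    S <- (S + t(S)) / 2
  }
  structure(list(L = L, horizon = as.integer(horizon), theta_hat = theta_hat),
            class = "lqg_gains")
}

#' Goal-referenced state and feedforward command
#'
#' The goal state holds the hand at the target with zero velocity and an
#' actuator force that exactly cancels the background load; the feedforward
#' command maintains that actuator force.
#'
#' @param ctx a [force_context()].
#' @param goal numeric length-2 target position (m), default \code{c(0, 0.15)}.
#' @return list with \code{x_star} (length 6) and \code{u_star} (length 2).
#' @export
goal_state <- function(ctx, goal = c(0, 0.15)) {
  x_star <- c(goal[1], goal[2], 0, 0, -ctx$phi, 0)
  list(x_star = x_star, u_star = c(-ctx$phi, 0))
}

#' Feedback command at one time step
#'
#' \code{u_t = u* - L_t (x_hat - x*)}: linear state feedback around the
#' goal-referenced state plus the background-compensating feedforward.
#'
#' @param gains an [synthesize_controller()] object.
#' @param x_hat estimated state (length 6).
#' @param t step index, 1-based; must be <= horizon.
#' @param ref a [goal_state()] list.
#' @return commanded force, length 2 (N).
#' @export
control_command <- function(gains, x_hat, t, ref) {
  if (t < 1 || t > gains$horizon) {
    stop("index error: t outside the controller horizon", call. = FALSE)
  }
  drop(ref$u_star - gains$L[[t]] %*% (x_hat - ref$x_star))
}

#' One Kalman predict/update step
#'
#' Standard Kalman filtering with the dynamics augmented by the believed
#' field gain: predict with \code{A(theta_hat)}, command and known background
#' load, then update against the measurement. Returns the innovation
#' (measurement minus predicted observation) alongside the new estimator
#' state.
#'
#' @param plant a [build_plant()] object.
#' @param theta_hat believed force-field gain.
#' @param est list with \code{x_hat} (length 6) and \code{P} (6x6 covariance).
#' @param u commanded force (length 2).
#' @param y_meas observed state (length 6).
#' @param bg_force known background force (N) entering the disturbance channel.
#' @return list with \code{x_hat}, \code{P}, \code{innovation},
#'   \code{x_pred} (the prior prediction).
#' @export
estimate_step <- function(plant, theta_hat, est, u, y_meas, bg_force = 0) {
  A <- plant_A_theta(plant, theta_hat)
  x_pred <- drop(A %*% est$x_hat + plant$B %*% u + plant$G * bg_force)
  P_pred <- A %*% est$P %*% t(A) + plant$process_noise
  H <- plant$H
  S <- H %*% P_pred %*% t(H) + plant$obs_noise
  innov <- y_meas - drop(H %*% x_pred)
  if (max(plant$obs_noise) == 0 && plant$process_noise_scale == 0) {
    # noise-free filtering: the measurement is exact, adopt it
    K <- diag(6)
  } else {
    Sc <- tryCatch(chol(S + diag(6) * 1e-300), error = function(e) NULL)
    if (is.null(Sc)) stop("numerical-failure: singular innovation covariance", call. = FALSE)
    K <- t(backsolve(Sc, forwardsolve(t(Sc), t(P_pred %*% t(H)))))
  }
  x_hat <- x_pred + drop(K %*% innov)
  IKH <- diag(6) - K %*% H
  P <- IKH %*% P_pred %*% t(IKH) + K %*% plant$obs_noise %*% t(K)
  list(x_hat = x_hat, P = (P + t(P)) / 2, innovation = innov, x_pred = x_pred)
}
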