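#' Linear plant for planar reaching
#'
#' Builds the discrete-time biomechanical plant used throughout the package:
#' a planar point mass driven by a commanded force that passes through a
#' first-order actuator lag. The state is
#' \code{(px, py, vx, vy, fx, fy)} — position (m), velocity (m/s) and realized
#' actuator force (N). The continuous dynamics
#' \deqn{\dot p = v,\quad \dot v = (f + F_{ext})/m,\quad \dot f = (u - f)/\tau}
#' are discretized exactly with the matrix exponential. External lateral
#' forces (background load, velocity-dependent field) act directly on lateral
#' acceleration; their discrete effect is the exact zero-order-hold input
#' column \code{G} of that disturbance channel, with the force held at its
#' value at the start of the step. This keeps the field coupling linear in
#' its gain and makes a constant background load exactly compensable at
#' equilibrium.
#'
#' @param dt time step in seconds (default 0.01).
#' @param mass point mass in kg (default 1).
#' @param actuator_tau actuator low-pass time constant in seconds (default 0.1).
#' @param process_noise_scale standard deviation scale of additive process
#'   noise on the velocity states (N-equivalent impulse per step; 0 disables).
#' @param obs_noise_scale standard deviation scale of observation noise
#'   (0 disables).
#'
#' @return An object of class \code{reach_plant}: a list with \code{dt},
#'   \code{mass}, \code{actuator_tau}, discrete operators \code{A} (6x6),
#'   \code{B} (6x2), observation matrix \code{H} (identity), disturbance
#'   vector \code{G} mapping a lateral force (N) to the state, and the two
#'   noise covariance matrices.
#' @export
#' @examples
#' pl <- build_plant()
#' dim(pl$A)
build_plant <- function(dt = 0.01, mass = 1, actuator_tau = 0.1,
                        process_noise_scale = 0, obs_noise_scale = 0) {
  if (!is.finite(dt) || dt <= 0) stop("invalid-config: dt must be > 0", call. = FALSE)
  if (!is.finite(mass) || mass <= 0) stop("invalid-config: mass must be > 0", call. = FALSE)
  if (!is.finite(actuator_tau) || actuator_tau <= 0) {
    stop("invalid-config: actuator_tau must be > 0", call. = FALSE)
  }
  if (process_noise_scale < 0 || obs_noise_scale < 0) {
    stop("invalid-config: noise scales must be >= 0", call. = FALSE)
  }
  n <- 6L; m <- 2L
  Ac <- matrix(0, n, n)
  Ac[1, 3] <- 1; Ac[2, 4] <- 1            # \dot p = v
  Ac[3, 5] <- 1 / mass; Ac[4, 6] <- 1 / mass  # \dot v = f / m
  Ac[5, 5] <- -1 / actuator_tau; Ac[6, 6] <- -1 / actuator_tau
  Bc <- matrix(0, n, m)
  Bc[5, 1] <- 1 / actuator_tau; Bc[6, 2] <- 1 / actuator_tau
  # third input column: external lateral force acting directly on vx
  Dc <- matrix(0, n, 1)
  Dc[3, 1] <- 1 / mass
  # exact zero-order-hold discretization via the augmented exponential
  nin <- m + 1L
  aug <- rbind(cbind(Ac, Bc, Dc), matrix(0, nin, n + nin))
  Ead <- as.matrix(Matrix::expm(aug * dt))
  A <- Ead[seq_len(n), seq_len(n), drop = FALSE]
  B <- Ead[seq_len(n), n + seq_len(m), drop = FALSE]
  G <- Ead[seq_len(n), n + m + 1L, drop = FALSE]
  Q <- diag(c(0, 0, 1, 1, 0, 0)) * process_noise_scale^2
  R <- diag(n) * max(obs_noise_scale^2, 0)
  structure(
    list(dt = dt, mass = mass, actuator_tau = actuator_tau,
         A = A, B = B, H = diag(n), G = G,
         process_noise = Q, obs_noise = R,
         process_noise_scale = process_noise_scale,
         obs_noise_scale = obs_noise_scale),
    class = "reach_plant"
  )
}

#' @method print reach_plant
#' @export
print.reach_plant <- function(x, ...) {
  cat("<reach_plant> dt =", x$dt, "s, mass =", x$mass, "kg, tau =",
      x$actuator_tau, "s\n")
  invisible(x)
}

#' Force context for a trial
#'
#' Bundles the signed force-field gain \code{theta} (N·s/m; clockwise
#' positive), the signed lateral background load \code{phi} (N) and the
#' background ramp duration (s).
#'
#' @param theta force-field gain in N·s/m, lateral force = theta * forward velocity.
#' @param phi constant lateral background force in N.
#' @param ramp_duration linear ramp-up time of the background force in
#'   seconds (default 0.5).
#' @return A list of class \code{force_context}.
#' @export
force_context <- function(theta = 0, phi = 0, ramp_duration = 0.5) {
  if (ramp_duration < 0) stop("invalid-config: ramp_duration must be >= 0", call. = FALSE)
  structure(list(theta = theta, phi = phi, ramp_duration = ramp_duration),
            class = "force_context")
}

#' Background-load ramp
#'
#' The background force ramps linearly from 0 at t = 0 to \code{phi} at
#' \code{ramp_duration} and stays constant thereafter.
#'
#' @param phi signed lateral force in N.
#' @param t time since trial onset in seconds (>= 0).
#' @param ramp_duration ramp time in seconds.
#' @return force in N.
#' @export
background_ramp <- function(phi, t, ramp_duration = 0.5) {
  stopifnot(all(t >= 0))
  if (ramp_duration <= 0) return(rep_len(phi, length(t)))
  phi * pmin(t / ramp_duration, 1)
}

#' Total external lateral force on the hand
#'
#' Sum of the (possibly still ramping) background load and, when the field is
#' on, the velocity-dependent force-field component \code{theta * vy}.
#' Catch trials are simulated with \code{field_on = FALSE}.
#'
#' @param state numeric state vector (px, py, vx, vy, fx, fy) or a list with
#'   a \code{vy} element.
#' @param ctx a [force_context()].
#' @param t time since trial onset (s).
#' @param field_on logical; is the velocity-dependent field active?
#' @return lateral force in N.
#' @export
external_force <- function(state, ctx, t, field_on = TRUE) {
  vy <- if (is.list(state)) state$vy else state[4]
  bg <- background_ramp(ctx$phi, t, ctx$ramp_duration)
  bg + if (isTRUE(field_on)) ctx$theta * vy else 0
}

#' One simulation step of the plant
#'
#' Advances the state one \code{dt} under the commanded force \code{u},
#' the external lateral force (background + field) and, optionally, process
#' noise. With \code{noise = FALSE} the map is deterministic.
#'
#' @param plant a [build_plant()] object.
#' @param state numeric length-6 state vector.
#' @param u numeric length-2 commanded force (N).
#' @param ctx a [force_context()].
#' @param t time since trial onset (s) of the current state.
#' @param field_on logical; velocity-dependent field active.
#' @param noise logical; add process noise (uses the current RNG stream).
#' @return the next state vector.
#' @export
plant_step <- function(plant, state, u, ctx, t, field_on = TRUE, noise = FALSE) {
  stopifnot(length(state) == 6L, all(is.finite(u)))
  fext <- external_force(state, ctx, t, field_on)
  x1 <- drop(plant$A %*% state + plant$B %*% u + plant$G * fext)
  if (isTRUE(noise) && plant$process_noise_scale > 0) {
    x1[3:4] <- x1[3:4] + stats::rnorm(2, 0, plant$process_noise_scale * plant$dt / plant$mass)
  }
  x1
}

#' Discrete dynamics matrix under a believed field gain
#'
#' Returns \code{A(theta) = A + theta * G e4'}, coupling forward velocity into
#' the lateral disturbance channel — the plant as seen by a controller or
#' estimator that believes the velocity-dependent field has gain \code{theta}.
#'
#' @param plant a [build_plant()] object.
#' @param theta believed force-field gain (N·s/m).
#' @return 6x6 matrix.
#' @export
plant_A_theta <- function(plant, theta) {
  plant$A + theta * plant$G %*% matrix(c(0, 0, 0, 1, 0, 0), 1, 6)
}
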