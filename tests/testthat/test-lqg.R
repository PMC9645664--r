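test_that("the first feedback command solves the open-loop quadratic program", {
  # brute-force oracle: over a short horizon the noise-free cost is an exact
  # quadratic in the stacked command sequence; minimize it in closed form and
  # compare the optimal first command with the Riccati feedback
  pl <- build_plant()
  w <- cost_weights(hold_steps = 3)
  N <- 8
  theta <- 7
  A <- plant_A_theta(pl, theta); B <- pl$B
  Qs <- diag(c(w$position, w$position, w$velocity, w$velocity, w$force, w$force))
  Qr <- diag(c(w$lateral_running, 0, 0, 0, 0, 0))
  # oracle charges costs at the post-command states x_{t+1}; the recursion's
  # hold window opens at state index N - hold_steps + 1
  Qt <- lapply(seq_len(N), function(t) if (t + 1 >= N - w$hold_steps + 1) Qs else Qr)
  x0 <- c(0.01, -0.02, 0.05, 0.1, 0.2, -0.1)
  # x_t = A^t x0 + sum_s M[t,s] u_s  (block propagation)
  Apow <- Reduce(function(acc, i) acc %*% A, seq_len(N), accumulate = TRUE,
                 init = diag(6))
  H <- matrix(0, 2 * N, 2 * N); gvec <- numeric(2 * N)
  for (t in seq_len(N)) {
    xf <- Apow[[t + 1]] %*% x0   # free response after t steps
    Ms <- lapply(seq_len(t), function(s) Apow[[t - s + 1]] %*% B)
    for (s1 in seq_len(t)) {
      i1 <- (s1 - 1) * 2 + 1:2
      gvec[i1] <- gvec[i1] + t(Ms[[s1]]) %*% Qt[[t]] %*% xf
      for (s2 in seq_len(t)) {
        i2 <- (s2 - 1) * 2 + 1:2
        H[i1, i2] <- H[i1, i2] + t(Ms[[s1]]) %*% Qt[[t]] %*% Ms[[s2]]
      }
    }
  }
  H <- H + diag(2 * N) * w$effort
  u_star <- solve(H, -gvec)
  g <- synthesize_controller(pl, theta, w, N)
  ref <- list(x_star = rep(0, 6), u_star = c(0, 0))
  u_fb <- control_command(g, x0, 1, ref)
  expect_equal(unname(u_fb), unname(u_star[1:2]), tolerance = 1e-8)
})

test_that("a one-step horizon reduces to the single-stage LQR solution", {
  pl <- build_plant()
  w <- cost_weights()
  g1 <- synthesize_controller(pl, 0, w, horizon = 1)
  Qs <- diag(c(w$position, w$position, w$velocity, w$velocity, w$force, w$force))
  L_exp <- solve(diag(2) * w$effort + t(pl$B) %*% Qs %*% pl$B,
                 t(pl$B) %*% Qs %*% pl$A)
  expect_equal(g1$L[[1]], L_exp, tolerance = 1e-10)
})

test_that("finite-horizon gains satisfy the Riccati recursion step by step", {
  # dynamic-programming audit: recompute the recursion independently with
  # explicit cost-to-go matrices and compare every gain
  pl <- build_plant()
  w <- cost_weights()
  N <- 30
  g <- synthesize_controller(pl, 5, w, N)
  A <- plant_A_theta(pl, 5); B <- pl$B
  Qs <- diag(c(w$position, w$position, w$velocity, w$velocity, w$force, w$force))
  Qr <- diag(c(w$lateral_running, 0, 0, 0, 0, 0))
  R <- diag(2) * w$effort
  hold_from <- N - w$hold_steps + 1
  S <- Qs
  for (t in seq(N, 1)) {
    Lt <- solve(R + t(B) %*% S %*% B) %*% t(B) %*% S %*% A
    expect_equal(g$L[[t]], Lt, tolerance = 1e-10)
    Qt <- if (t >= hold_from) Qs else Qr
    S <- Qt + t(A) %*% S %*% (A - B %*% Lt)
    S <- (S + t(S)) / 2
  }
})

test_that("lateral/forward symmetry and command determinism hold", {
  pl <- build_plant()
  g <- synthesize_controller(pl, 0, cost_weights(), 40)
  ref <- goal_state(force_context(phi = 0))
  x1 <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.1)
  x1m <- c(-0.01, 0.05, -0.1, 0.2, -0.3, 0.1)  # lateral mirror
  u1 <- control_command(g, x1, 5, ref)
  u1m <- control_command(g, x1m, 5, ref)
  expect_equal(u1[1], -u1m[1], tolerance = 1e-8)
  expect_equal(u1[2], u1m[2], tolerance = 1e-8)
  expect_identical(u1, control_command(g, x1, 5, ref))
  expect_error(control_command(g, x1, 41, ref), "index error")
})

test_that("command magnitude is non-increasing in the effort weight", {
  pl <- build_plant()
  ref <- goal_state(force_context(phi = 0))
  x <- c(0.02, 0.03, 0, 0.1, 0, 0)
  g_lo <- synthesize_controller(pl, 0, cost_weights(effort = 1e-2), 40)
  g_hi <- synthesize_controller(pl, 0, cost_weights(effort = 2e-2), 40)
  u_lo <- control_command(g_lo, x, 1, ref)
  u_hi <- control_command(g_hi, x, 1, ref)
  expect_lte(sqrt(sum(u_hi^2)), sqrt(sum(u_lo^2)) + 1e-12)
})

test_that("setpoint command compensates the background only", {
  ctx <- force_context(phi = 4)
  ref <- goal_state(ctx)
  pl <- build_plant()
  g <- synthesize_controller(pl, 0, cost_weights(), 40)
  u <- control_command(g, ref$x_star, 10, ref)
  expect_equal(u, c(-4, 0), tolerance = 1e-10)
})

test_that("Kalman filtering beats open-loop prediction on a noisy system", {
  set.seed(42)
  pl <- build_plant(process_noise_scale = 1, obs_noise_scale = 0.01)
  ctx <- force_context(theta = 0, phi = 0)
  x <- rep(0, 6)
  est <- list(x_hat = rep(0, 6), P = diag(6) * 1e-4)
  x_open <- rep(0, 6)
  err_kf <- err_open <- 0
  for (t in 1:200) {
    u <- c(0.3 * sin(t / 20), 0.3 * cos(t / 15))
    x <- plant_step(pl, x, u, ctx, t = 0, noise = TRUE)
    y <- x + rnorm(6, 0, pl$obs_noise_scale)
    est <- estimate_step(pl, 0, est, u, y)
    x_open <- drop(pl$A %*% x_open + pl$B %*% u)
    err_kf <- err_kf + sum((est$x_hat - x)^2)
    err_open <- err_open + sum((x_open - x)^2)
  }
  expect_lt(err_kf, err_open)
})

test_that("zero innovation leaves the estimate at the model prediction", {
  pl <- build_plant(process_noise_scale = 0.1, obs_noise_scale = 0.01)
  est <- list(x_hat = c(0, 0.01, 0, 0.1, 0, 0.5), P = diag(6) * 1e-4)
  u <- c(0.2, 0.5)
  x_pred <- drop(plant_A_theta(pl, 3) %*% est$x_hat + pl$B %*% u)
  out <- estimate_step(pl, 3, est, u, y_meas = x_pred)
  expect_equal(out$innovation, rep(0, 6))
  expect_equal(out$x_hat, x_pred)
})

test_that("vanishing observation noise pulls the posterior onto the measurement", {
  pl <- build_plant(process_noise_scale = 0.1, obs_noise_scale = 1e-9)
  est <- list(x_hat = rep(0, 6), P = diag(6) * 1e-2)
  y <- c(0.01, 0.02, -0.1, 0.3, 1, -1)
  out <- estimate_step(pl, 0, est, c(0, 0), y)
  expect_equal(out$x_hat, y, tolerance = 1e-6)
})

test_that("a controller that knows the field reaches straight and lands on target", {
  pl <- build_plant()
  res <- simulate_trial("offline", field_spec(), 13, no_rates, pl, cost_weights())
  m <- sim_metrics(res)
  expect_lt(abs(m$initial_angle_deg), 1)
  endpoint <- c(utils::tail(res$trial$px, 1), utils::tail(res$trial$py, 1))
  expect_lt(sqrt(sum((endpoint - c(0, 0.15))^2)), 1e-3)
})

test_that("naive reaches under mirrored fields are mirror images", {
  pl <- build_plant()
  rA <- simulate_trial("offline", field_spec(13, 4), 0, no_rates, pl, cost_weights())
  rB <- simulate_trial("offline", field_spec(-13, -4), 0, no_rates, pl, cost_weights())
  expect_lt(max(abs(rA$trial$px + rB$trial$px)), 1e-6)
  expect_lt(max(abs(rA$trial$py - rB$trial$py)), 1e-6)
})

test_that("closed loop is stable in the long-horizon limit", {
  pl <- build_plant()
  g <- synthesize_controller(pl, 0, cost_weights(hold_steps = 200), 200)
  # early gains approximate the stationary solution; closed-loop eigenvalues
  # must be inside the unit circle
  Acl <- pl$A - pl$B %*% g$L[[1]]
  expect_lt(max(Mod(eigen(Acl, only.values = TRUE)$values)), 1)
})
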