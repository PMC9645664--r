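# shared fixtures, all generated in code

# straight 15 cm reach sampled at 1 kHz: minimum-jerk forward profile,
# short stationary pre-phase and hold tail
straight_reach <- function(fs = 1000, duration = 0.8, move = 0.5, pre = 0.06,
                           distance = 0.15, lateral = function(s) 0 * s) {
  t <- seq_len(round(duration * fs)) / fs
  s <- pmin(pmax((t - pre) / move, 0), 1)
  mj <- 10 * s^3 - 15 * s^4 + 6 * s^5
  tibble::tibble(t_ms = t * 1000, x_m = lateral(s), y_m = distance * mj)
}

# one-trial spec helpers
field_spec <- function(theta = 13, phi = 4) list(theta = theta, phi = phi, is_catch = FALSE)
catch_spec <- function(theta = 13, phi = 4) list(theta = theta, phi = phi, is_catch = TRUE)

no_rates <- c(gamma1 = 0, gamma2 = 0)

# metrics for a single simulated trial (simulator sampling, no filtering)
sim_metrics <- function(res, dt = 0.01) {
  reachadapt:::trial_metrics_xy(res$trial$px, res$trial$py, fs = 1 / dt,
                                filter_cutoff_hz = NULL)
}
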