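test_that("the zero-phase filter has unit DC gain and time-reversal symmetry", {
  x <- rep(2.5, 500)
  y <- lowpass(x, fs = 1000, fc = 50)
  expect_lt(max(abs(y[50:450] - 2.5)), 1e-9)
  set.seed(1)
  z <- cumsum(rnorm(400)) / 20
  expect_equal(lowpass(rev(z), 1000, 50), rev(lowpass(z, 1000, 50)), tolerance = 1e-6)
  expect_error(lowpass(z, fs = 100, fc = 50), "invalid-config")
})

test_that("sinusoid attenuation follows the squared Butterworth magnitude", {
  # analytic oracle: dual-pass digital Butterworth magnitude with bilinear
  # prewarping, |H(f)|^2 = (1 + (tan(pi f / fs) / tan(pi fc / fs))^{2n})^{-1}
  fs <- 1000; fc <- 50; n <- 4
  gain_theory <- function(f) {
    (1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * n))^-1
  }
  t <- seq(0, 1, by = 1 / fs)
  for (f in c(10, 200)) {
    x <- sin(2 * pi * f * t)
    y <- lowpass(x, fs, fc, n)
    mid <- 300:700
    amp <- sqrt(2 * mean(y[mid]^2))
    expect_equal(amp, gain_theory(f), tolerance = 0.01)
  }
})

test_that("differentiation is exact on polynomials through degree four", {
  fs <- 100
  t <- seq(0, 1, by = 1 / fs)
  lin <- 0.3 * t
  expect_equal(differentiate(lin, fs), rep(0.3, length(t)), tolerance = 1e-10)
  quart <- 2 + t - 0.5 * t^2 + 0.25 * t^3 - 0.1 * t^4
  d_exact <- 1 - t + 0.75 * t^2 - 0.4 * t^3
  v <- differentiate(quart, fs)
  expect_equal(v[3:(length(t) - 2)], d_exact[3:(length(t) - 2)], tolerance = 1e-10)
  expect_equal(differentiate(rep(1, 10), fs), rep(0, 10))
  expect_error(differentiate(1:4, fs), "length error")
})

test_that("reach onset is the first exit from the start target", {
  tr <- straight_reach()
  onset <- reach_onset(tr$x_m, tr$y_m, 0.005)
  # closed-form: minimum-jerk crossing of 0.005 m
  s_star <- uniroot(function(s) 0.15 * (10 * s^3 - 15 * s^4 + 6 * s^5) - 0.005,
                    c(0.01, 0.5))$root
  expect_equal(onset, 60 + ceiling(s_star * 0.5 * 1000), tolerance = 1)
  expect_error(reach_onset(rep(0, 100), rep(0.001, 100)), "no-onset")
})

test_that("initial angle follows the CCW-positive geometric convention", {
  tr <- straight_reach()
  ia <- initial_angle(tr$x_m, tr$y_m, fs = 1000)
  expect_equal(ia$angle_deg, 0, tolerance = 1e-8)
  # constructed 10-degree crossing: x = -tan(10 deg) * y
  tr10 <- straight_reach()
  tr10$x_m <- -tan(10 * pi / 180) * tr10$y_m
  ia10 <- initial_angle(tr10$x_m, tr10$y_m, fs = 1000)
  expect_equal(ia10$angle_deg, 10, tolerance = 1e-6)
  # mirrored trajectory negates the angle
  iam <- initial_angle(-tr10$x_m, tr10$y_m, fs = 1000)
  expect_equal(iam$angle_deg, -10, tolerance = 1e-6)
  expect_error(initial_angle(tr$x_m, tr$y_m / 10, fs = 1000), "no-crossing")
})

test_that("initial angle is invariant to uniform temporal resampling", {
  tr <- straight_reach()
  tr$x_m <- -tan(8 * pi / 180) * tr$y_m
  a1 <- initial_angle(tr$x_m, tr$y_m, fs = 1000)$angle_deg
  idx <- seq(1, nrow(tr), by = 4)  # 250 Hz resampling of the same path
  a2 <- initial_angle(tr$x_m[idx], tr$y_m[idx], fs = 250)$angle_deg
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("path length recovers analytic arc lengths", {
  fs <- 1000
  tr <- straight_reach()
  vx <- differentiate(tr$x_m, fs); vy <- differentiate(tr$y_m, fs)
  onset <- reach_onset(tr$x_m, tr$y_m, 1e-4)
  expect_equal(path_length(vx, vy, onset, fs), 0.15, tolerance = 1e-3)
  # semicircular detour of radius r traversed in 0.5 s with smooth
  # start/stop (minimum-jerk time course), parametrized at 1 kHz
  r <- 0.075
  s <- seq(0, 1, length.out = 500)
  ang <- pi * (10 * s^3 - 15 * s^4 + 6 * s^5)
  x <- r * cos(ang) - r; y <- r * sin(ang)
  x <- c(x, rep(x[500], 100)); y <- c(y, rep(y[500], 100))
  vx <- differentiate(x, fs); vy <- differentiate(y, fs)
  onset <- reach_onset(x - x[1], y, 1e-4)
  expect_equal(path_length(vx, vy, onset, fs), pi * r, tolerance = 1e-3)
  # stationary hand travels nowhere
  expect_equal(path_length(rep(0, 100), rep(0, 100), 1, fs), 0)
})

test_that("forward velocity at threshold scales with the kinematics", {
  tr <- straight_reach()
  m <- reachadapt:::trial_metrics_xy(tr$x_m, tr$y_m, fs = 1000,
                                     filter_cutoff_hz = NULL)
  # minimum-jerk speed at the crossing of 5 cm (closed form)
  s_star <- uniroot(function(s) (10 * s^3 - 15 * s^4 + 6 * s^5) - 1 / 3,
                    c(0.2, 0.6))$root
  v_exact <- 0.15 * (30 * s_star^2 - 60 * s_star^3 + 30 * s_star^4) / 0.5
  expect_equal(m$vy_at_threshold, v_exact, tolerance = 5e-3)
  # time dilation by 2 halves the threshold velocity
  tr2 <- straight_reach(move = 1.0, duration = 1.3)
  m2 <- reachadapt:::trial_metrics_xy(tr2$x_m, tr2$y_m, fs = 1000,
                                      filter_cutoff_hz = NULL)
  expect_equal(m2$vy_at_threshold, v_exact / 2, tolerance = 5e-3)
  # mirrored trajectory leaves the forward component unchanged
  trm <- tr; trm$x_m <- -tan(0.1) * trm$y_m
  m3 <- reachadapt:::trial_metrics_xy(trm$x_m, trm$y_m, fs = 1000,
                                      filter_cutoff_hz = NULL)
  m4 <- reachadapt:::trial_metrics_xy(-trm$x_m, trm$y_m, fs = 1000,
                                      filter_cutoff_hz = NULL)
  expect_equal(m3$vy_at_threshold, m4$vy_at_threshold)
})

test_that("the tidy metric wrapper handles cohorts and degenerate trials", {
  tr1 <- straight_reach(); tr1$x_m <- -tan(5 * pi / 180) * tr1$y_m
  tr2 <- straight_reach(); tr2$y_m <- tr2$y_m * 0  # never leaves the target
  trials <- dplyr::bind_rows(
    dplyr::mutate(tr1, participant = 1, trial = 1),
    dplyr::mutate(tr2, participant = 1, trial = 2)
  )
  met <- compute_trial_metrics(trials)
  expect_equal(nrow(met), 2)
  expect_equal(met$initial_angle_deg[1], 5, tolerance = 0.05)
  expect_true(is.na(met$initial_angle_deg[2]))
  expect_error(compute_trial_metrics(dplyr::select(trials, -x_m)), "x_m")
})

test_that("sign normalization maps both field directions onto positive decay", {
  k <- 1:30
  cw <- -(20 * exp(-0.05 * k) + rnorm(30, 0, 0.1))   # CW trials: negative angles
  ccw <- 20 * exp(-0.05 * k) + rnorm(30, 0, 0.1)     # CCW trials: positive
  vals <- c(cw, ccw)
  dirs <- rep(c("cw", "ccw"), each = 30)
  out <- normalize_angle_sign(vals, dirs)
  expect_true(mean(out[1:10]) > 0 && mean(out[31:40]) > 0)
  expect_equal(out[31:60], vals[31:60])  # already-positive direction untouched
})
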