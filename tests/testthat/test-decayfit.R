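test_that("single-rate parameters are recovered from noise-free data", {
  x <- 1:60
  y <- 6 + 20 * exp(-0.05 * x)
  f <- fit_single_rate(x, y)
  expect_true(f$converged)
  expect_equal(unname(f$coef), c(6, 20, -0.05), tolerance = 1e-6)
  expect_error(fit_single_rate(1:3, c(1, 2, 3)), "at least 4")
})

test_that("a constant series collapses to its mean with zero amplitude", {
  f <- fit_single_rate(1:20, rep(3.2, 20))
  expect_equal(unname(f$coef["a0"]), 3.2)
  expect_equal(unname(f$coef["a1"]), 0)
})

test_that("dual-rate parameters and component ordering are recovered", {
  x <- 1:75
  y <- 0.15 + 0.03 * exp(-0.02 * x) + 0.05 * exp(-0.8 * x)
  f <- fit_dual_rate(x, y)
  expect_true(f$converged)
  expect_equal(unname(f$coef[c("b1", "b2")]), c(-0.02, -0.8), tolerance = 1e-4)
  expect_equal(unname(f$coef[c("a1", "a2")]), c(0.03, 0.05), tolerance = 1e-4)
  # label symmetry: swapping the components at initialization changes nothing
  f2 <- fit_dual_rate(x, y, init = list(a0 = 0.15, a1 = 0.05, b1 = -0.8,
                                        a2 = 0.03, b2 = -0.02))
  expect_equal(f2$coef, f$coef, tolerance = 1e-6)
  expect_error(fit_dual_rate(1:5, rnorm(5)), "at least 6")
})

test_that("fitting a needless second exponential is rejected by BIC", {
  set.seed(7)
  x <- 1:75
  y <- 6 + 20 * exp(-0.05 * x) + rnorm(75, 0, 0.5)
  sel <- fit_decay_models(x, y)
  expect_equal(sel$selection, "single")
  expect_gt(sel$delta_bic, 0)
})

test_that("well-separated dual-rate data select the dual model", {
  set.seed(8)
  x <- 1:75
  y <- 5 + 10 * exp(-0.04 * x) + 15 * exp(-0.8 * x) + rnorm(75, 0, 0.3)
  sel <- fit_decay_models(x, y)
  expect_equal(sel$selection, "dual")
  expect_lt(sel$delta_bic, 0)
})

test_that("the BIC value follows the closed-form expression", {
  # N = 100, RSS = 100, k = 3 -> 3 ln(100)
  fake <- structure(list(residuals = rep(1, 100), N = 100L, k = 3L),
                    class = "decay_fit")
  expect_equal(bic(fake), 3 * log(100))
  # an extra parameter at equal RSS costs ln N
  fake5 <- fake; fake5$k <- 5L
  expect_equal(bic(fake5) - bic(fake), 2 * log(100))
  # halving the RSS at fixed N, k gains N ln 2
  half <- fake; half$residuals <- rep(sqrt(0.5), 100)
  expect_equal(bic(fake) - bic(half), 100 * log(2))
  # zero RSS is floored, not -Inf
  zero <- fake; zero$residuals <- rep(0, 100)
  expect_true(is.finite(bic(zero)))
})

test_that("model selection defers to parsimony and convergence", {
  x <- 1:40; y <- 4 + 8 * exp(-0.1 * x)
  s <- fit_single_rate(x, y)
  d <- fit_dual_rate(x, y)
  # identical-quality fits tie toward single
  tie <- select_model(s, s_dual_like <- d)
  if (abs(tie$delta_bic) < 1e-9) expect_equal(tie$selection, "single")
  bad_dual <- d; bad_dual$converged <- FALSE
  expect_equal(select_model(s, bad_dual)$selection, "single")
  bad_single <- s; bad_single$converged <- FALSE
  expect_equal(select_model(bad_single, d)$selection, "dual")
  expect_error(select_model(bad_single, bad_dual), "selection error")
})

test_that("Wald intervals are nested across levels and shrink with noise", {
  set.seed(9)
  x <- 1:75
  mkfit <- function(sd) fit_single_rate(x, 6 + 20 * exp(-0.05 * x) + rnorm(75, 0, sd))
  f_lo <- mkfit(0.05); f_hi <- mkfit(1)
  ci95 <- parameter_ci(f_lo, 0.95)
  ci99 <- parameter_ci(f_lo, 0.99)
  expect_true(all(ci99$lower <= ci95$lower & ci99$upper >= ci95$upper))
  w_lo <- ci95$upper - ci95$lower
  w_hi <- parameter_ci(f_hi, 0.95)$upper - parameter_ci(f_hi, 0.95)$lower
  expect_true(all(w_lo < w_hi))
})

test_that("Wald coverage of the decay rate is near nominal", {
  set.seed(10)
  x <- 1:75
  hits <- 0; n_rep <- 300
  for (r in seq_len(n_rep)) {
    y <- 6 + 20 * exp(-0.05 * x) + rnorm(75, 0, 0.8)
    f <- fit_single_rate(x, y)
    ci <- parameter_ci(f, 0.95)
    b <- ci[ci$term == "b1", ]
    if (b$lower <= -0.05 && -0.05 <= b$upper) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.90)
  expect_lt(hits / n_rep, 0.99)
})

test_that("the participant bootstrap is seeded, degenerate-safe and covering", {
  x <- 1:50
  mu <- 5 + 12 * exp(-0.06 * x)
  # identical participants: every draw equals the point fit
  cohort0 <- purrr::map_dfr(1:5, ~ tibble::tibble(participant = .x, x = x, y = mu))
  b0 <- bootstrap_decay(cohort0, n_iter = 30, seed = 4, model = "single")
  expect_equal(b0$n_retained, 30)
  expect_lt(diff(range(b0$draws$value[b0$draws$term == "b1"])), 1e-8)
  # reproducibility
  set.seed(123)
  cohort <- purrr::map_dfr(1:10, ~ tibble::tibble(
    participant = .x, x = x, y = mu + rnorm(1, 0, 1) + rnorm(50, 0, 0.6)))
  b1 <- bootstrap_decay(cohort, n_iter = 50, seed = 9, model = "single")
  b2 <- bootstrap_decay(cohort, n_iter = 50, seed = 9, model = "single")
  expect_identical(b1$draws, b2$draws)
  # percentile interval covers the true rate for a well-behaved cohort
  ci_b <- b1$ci[b1$ci$term == "b1", ]
  expect_true(ci_b$lower <= -0.06 && -0.06 <= ci_b$upper)
  expect_error(bootstrap_decay(cohort0[cohort0$participant == 1, ], 10, 1),
               ">= 2 participants")
})

test_that("tidy and glance expose the fit as tibbles", {
  x <- 1:40
  f <- fit_single_rate(x, 3 + 5 * exp(-0.1 * x) + rnorm(40, 0, 0.1))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("a0", "a1", "b1"))
  gl <- glance(f)
  expect_equal(gl$model, "single")
  expect_equal(gl$N, 40L)
  expect_true(gl$converged)
})
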