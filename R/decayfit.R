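#' Exponential decay models of trial series
#'
#' Single-rate (\code{y = a0 + a1 exp(b1 x)}) and dual-rate
#' (\code{y = a0 + a1 exp(b1 x) + a2 exp(b2 x)}) decay models fitted by
#' Gaussian maximum likelihood (equivalently nonlinear least squares). Rate
#' parameters are reported on the signed convention in which negative values
#' mean decay; fits constrain them to be non-positive. For the dual model the
#' components are ordered so that \code{b1} is the slow rate and \code{b2}
#' the fast one (\code{|b2| >= |b1|}).
#'
#' Dual-exponential likelihoods are multimodal, so the dual fit uses a
#' multi-start grid over fast rates \{-0.2, -0.5, -1, -2\} and slow rates
#' \{-0.005, -0.02, -0.05\} (amplitudes from range heuristics) and keeps the
#' best converged likelihood; explicit \code{init} values are tried first.
#'
#' @param x trial indices (strictly increasing).
#' @param y metric values (deg or m).
#' @param init optional named list of starting values
#'   (\code{a0, a1, b1[, a2, b2]}).
#' @return object of class \code{decay_fit}: list with \code{model},
#'   \code{coef} (named vector), \code{residuals}, \code{N}, \code{k},
#'   \code{bic}, \code{vcov}, \code{converged}.
#' @name decay_fitting
NULL

new_decay_fit <- function(model, coef, residuals, vcov, converged) {
  k <- length(coef)
  N <- length(residuals)
  fit <- structure(
    list(model = model, coef = coef, residuals = residuals,
         N = N, k = k, vcov = vcov, converged = converged, bic = NA_real_),
    class = "decay_fit"
  )
  fit$bic <- bic(fit)
  fit
}

#' @method print decay_fit
#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>", x$model, "rate model, N =", x$N,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$coef, 5))
  cat("BIC:", round(x$bic, 3), "\n")
  invisible(x)
}

check_series <- function(x, y, min_n) {
  stopifnot(length(x) == length(y))
  if (any(diff(x) <= 0)) stop("invalid series: x must be strictly increasing", call. = FALSE)
  if (sum(is.finite(y)) < min_n) {
    stop("precondition error: need at least ", min_n, " points", call. = FALSE)
  }
  keep <- is.finite(y) & is.finite(x)
  list(x = x[keep], y = y[keep])
}

nls_try <- function(formula, data, start, lower, upper) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                           ftol = 1e-12)
    )),
    error = function(e) NULL
  )
}

fit_vcov <- function(nls_fit) {
  v <- tryCatch(stats::vcov(nls_fit), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v))) return(NULL)
  v
}

#' @rdname decay_fitting
#' @export
fit_single_rate <- function(x, y, init = NULL) {
  s <- check_series(x, y, 4L)
  x <- s$x; y <- s$y
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1)) {
    # degenerate constant series: amplitude zero, rate unidentified at zero
    co <- c(a0 = mean(y), a1 = 0, b1 = 0)
    return(new_decay_fit("single", co, y - mean(y), NULL, TRUE))
  }
  dat <- data.frame(x = x, y = y)
  a0_0 <- mean(utils::tail(y, max(3, length(y) %/% 5)))
  amp <- y[1] - a0_0
  if (abs(amp) < 1e-8) amp <- diff(range(y)) * sign(stats::cor(x, y) * -1 + 1e-12)
  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(init[c("a0", "a1", "b1")]))
  for (l in c(0.005, 0.02, 0.05, 0.2, 0.5, 1, 2)) {
    starts <- c(starts, list(list(a0 = a0_0, a1 = amp, b1 = -l)))
  }
  best <- NULL
  for (st in starts) {
    f <- nls_try(y ~ a0 + a1 * exp(b1 * x), dat, st,
                 lower = c(-Inf, -Inf, -Inf), upper = c(Inf, Inf, 0))
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
  }
  if (is.null(best)) {
    co <- c(a0 = mean(y), a1 = 0, b1 = 0)
    return(new_decay_fit("single", co, y - mean(y), NULL, FALSE))
  }
  co <- stats::coef(best$fit)[c("a0", "a1", "b1")]
  v <- fit_vcov(best$fit)
  new_decay_fit("single", co, stats::resid(best$fit), v, !is.null(v))
}

#' @rdname decay_fitting
#' @export
fit_dual_rate <- function(x, y, init = NULL) {
  s <- check_series(x, y, 6L)
  x <- s$x; y <- s$y
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1)) {
    co <- c(a0 = mean(y), a1 = 0, b1 = 0, a2 = 0, b2 = 0)
    return(new_decay_fit("dual", co, y - mean(y), NULL, TRUE))
  }
  dat <- data.frame(x = x, y = y)
  a0_0 <- mean(utils::tail(y, max(3, length(y) %/% 5)))
  amp <- y[1] - a0_0
  if (abs(amp) < 1e-8) amp <- diff(range(y))
  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(init[c("a0", "a1", "b1", "a2", "b2")]))
  for (lf in c(0.2, 0.5, 1, 2)) {
    for (ls in c(0.005, 0.02, 0.05)) {
      starts <- c(starts, list(list(a0 = a0_0, a1 = amp / 2, b1 = -ls,
                                    a2 = amp / 2, b2 = -lf)))
    }
  }
  best <- NULL
  for (st in starts) {
    f <- nls_try(y ~ a0 + a1 * exp(b1 * x) + a2 * exp(b2 * x), dat, st,
                 lower = c(-Inf, -Inf, -Inf, -Inf, -Inf),
                 upper = c(Inf, Inf, 0, Inf, 0))
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = f, rss = rss)
  }
  if (is.null(best)) {
    co <- c(a0 = mean(y), a1 = 0, b1 = 0, a2 = 0, b2 = 0)
    return(new_decay_fit("dual", co, y - mean(y), NULL, FALSE))
  }
  co <- stats::coef(best$fit)[c("a0", "a1", "b1", "a2", "b2")]
  v <- fit_vcov(best$fit)
  # order components: b1 slow, b2 fast (|b2| >= |b1|)
  if (abs(co["b1"]) > abs(co["b2"])) {
    perm <- c(1L, 4L, 5L, 2L, 3L)
    co <- stats::setNames(co[perm], c("a0", "a1", "b1", "a2", "b2"))
    if (!is.null(v)) v <- v[perm, perm, drop = FALSE]
    if (!is.null(v)) dimnames(v) <- list(names(co), names(co))
  }
  new_decay_fit("dual", co, stats::resid(best$fit), v, !is.null(v))
}

#' Bayesian information criterion of a decay fit
#'
#' \code{BIC = N log(RSS / N) + k log N} with \code{RSS} the residual sum of
#' squares and \code{k} the number of parameters (3 single, 5 dual). A zero
#' RSS is floored at \code{.Machine$double.xmin} to keep the value finite.
#'
#' @param fit a \code{decay_fit}.
#' @return numeric BIC (smaller is better).
#' @export
bic <- function(fit) {
  rss <- max(sum(fit$residuals^2), .Machine$double.xmin)
  fit$N * log(rss / fit$N) + fit$k * log(fit$N)
}

#' Select between single- and dual-rate fits by BIC
#'
#' Returns the smaller-BIC model; a non-converged dual fit defers to the
#' single fit, and exact ties break toward the single (more parsimonious)
#' model. \code{delta_bic = BIC_dual - BIC_single}, so positive values favour
#' the single-rate model.
#'
#' @param single,dual \code{decay_fit} objects.
#' @return list of class \code{decay_selection}: \code{selection}
#'   (\code{"single"}/\code{"dual"}), \code{delta_bic}, and both fits.
#' @export
select_model <- function(single, dual) {
  if (!single$converged && !dual$converged) {
    stop("selection error: neither model converged", call. = FALSE)
  }
  delta <- dual$bic - single$bic
  sel <- if (!dual$converged) "single"
         else if (!single$converged) "dual"
         else if (delta < 0) "dual" else "single"
  structure(list(selection = sel, delta_bic = delta,
                 single = single, dual = dual),
            class = "decay_selection")
}

#' @method print decay_selection
#' @export
print.decay_selection <- function(x, ...) {
  cat("<decay_selection>", x$selection, "rate selected; BIC(dual) - BIC(single) =",
      round(x$delta_bic, 3), "\n")
  invisible(x)
}

#' Fit both decay models and select by BIC
#'
#' Convenience wrapper: fits the single- and dual-rate models to one series
#' and runs [select_model()].
#'
#' @inheritParams decay_fitting
#' @return a \code{decay_selection}.
#' @export
fit_decay_models <- function(x, y, init = NULL) {
  select_model(fit_single_rate(x, y, init), fit_dual_rate(x, y, init))
}

#' Wald confidence intervals for decay parameters
#'
#' Normal-approximation intervals from the estimated parameter covariance
#' (inverse observed information of the Gaussian likelihood). A missing or
#' singular covariance yields infinite-width intervals flagged in the
#' \code{wide} column.
#'
#' @param fit a converged \code{decay_fit}.
#' @param level confidence level, default 0.95.
#' @return tibble: term, estimate, se, lower, upper, level, wide.
#' @export
parameter_ci <- function(fit, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (!fit$converged) stop("precondition error: fit did not converge", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (is.null(fit$vcov)) {
    se <- rep(Inf, fit$k)
    wide <- TRUE
  } else {
    se <- sqrt(pmax(diag(fit$vcov), 0))
    wide <- any(!is.finite(se))
  }
  tibble::tibble(
    term = names(fit$coef),
    estimate = unname(fit$coef),
    se = se,
    lower = unname(fit$coef) - z * se,
    upper = unname(fit$coef) + z * se,
    level = level,
    wide = wide
  )
}

#' Participant-resampling bootstrap of a decay fit
#'
#' Resamples participants with replacement, averages the resampled cohort's
#' series per trial, refits the decay model, and collects the parameter
#' draws. Iterations whose refit does not converge are discarded and counted.
#' The point fit on the full-cohort average supplies starting values for the
#' refits.
#'
#' @param cohort tibble with columns \code{participant}, \code{x}, \code{y}:
#'   one decay series per participant on a shared trial grid.
#' @param n_iter number of bootstrap iterations (the reference analysis uses
#'   10,000; smaller values are fine for testing).
#' @param seed integer seed.
#' @param model \code{"single"} or \code{"dual"}.
#' @param level confidence level for the percentile intervals.
#' @return object of class \code{decay_boot}: \code{draws} (tibble iter x
#'   term x value), \code{point} (the full-cohort \code{decay_fit}),
#'   \code{ci} (percentile intervals), \code{n_requested}, \code{n_retained},
#'   \code{discarded_fraction}, \code{seed}.
#' @export
bootstrap_decay <- function(cohort, n_iter = 1000, seed = 1L,
                            model = c("single", "dual"), level = 0.95) {
  model <- match.arg(model)
  stopifnot(all(c("participant", "x", "y") %in% names(cohort)))
  participants <- unique(cohort$participant)
  n_p <- length(participants)
  if (n_p < 2) stop("precondition error: need >= 2 participants", call. = FALSE)
  wide <- cohort |>
    dplyr::arrange(.data$participant, .data$x) |>
    tidyr::pivot_wider(names_from = "participant", values_from = "y") |>
    dplyr::arrange(.data$x)
  xg <- wide$x
  ymat <- as.matrix(wide[, as.character(participants), drop = FALSE])
  fitter <- if (model == "single") fit_single_rate else fit_dual_rate
  point <- fitter(xg, rowMeans(ymat, na.rm = TRUE))
  init <- as.list(point$coef)
  set.seed(seed)
  draws <- vector("list", n_iter)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    pick <- sample.int(n_p, n_p, replace = TRUE)
    ybar <- rowMeans(ymat[, pick, drop = FALSE], na.rm = TRUE)
    f <- tryCatch(fitter(xg, ybar, init = init), error = function(e) NULL)
    if (is.null(f) || !f$converged) next
    kept <- kept + 1L
    draws[[it]] <- tibble::tibble(iter = it, term = names(f$coef),
                                  value = unname(f$coef))
  }
  if (kept == 0L) stop("bootstrap error: no iteration converged", call. = FALSE)
  draws <- dplyr::bind_rows(draws)
  alpha <- (1 - level) / 2
  ci <- draws |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(lower = stats::quantile(.data$value, alpha, names = FALSE),
                     upper = stats::quantile(.data$value, 1 - alpha, names = FALSE),
                     .groups = "drop") |>
    dplyr::mutate(level = level)
  structure(
    list(draws = draws, point = point, ci = ci,
         n_requested = n_iter, n_retained = kept,
         discarded_fraction = 1 - kept / n_iter, seed = seed),
    class = "decay_boot"
  )
}

#' @method print decay_boot
#' @export
print.decay_boot <- function(x, ...) {
  cat("<decay_boot>", x$n_retained, "of", x$n_requested,
      "iterations retained (", sprintf("%.2f%%", 100 * x$discarded_fraction),
      "discarded)\n")
  print(x$ci)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decay fit
#'
#' @param x a \code{decay_fit}.
#' @param level confidence level for the Wald intervals.
#' @param ... unused.
#' @return tibble with one row per parameter.
#' @export
tidy.decay_fit <- function(x, level = 0.95, ...) {
  if (x$converged) {
    parameter_ci(x, level)[, c("term", "estimate", "se", "lower", "upper")]
  } else {
    tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                   se = NA_real_, lower = NA_real_, upper = NA_real_)
  }
}

#' One-line summary of a decay fit
#'
#' @param x a \code{decay_fit}.
#' @param ... unused.
#' @return one-row tibble: model, N, k, rss, bic, converged.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(model = x$model, N = x$N, k = x$k,
                 rss = sum(x$residuals^2), bic = x$bic,
                 converged = x$converged)
}
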