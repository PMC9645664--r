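#' Paired t comparison from a difference vector
#'
#' Classical paired t-test computed from the per-participant difference
#' vector: \code{t = mean(d) / (sd(d)/sqrt(n))} with \code{n - 1} degrees of
#' freedom. Sidedness is always explicit.
#'
#' @param d numeric vector of per-participant differences.
#' @param sided \code{"two"}, \code{"greater"} (mean > 0) or \code{"less"}.
#' @param alpha significance level recorded with the result (default 0.005,
#'   the level used throughout the package's reference analyses).
#' @return one-row tibble: n, d_bar, sigma, t, df, p, sided, alpha.
#' @export
paired_t <- function(d, sided = c("two", "greater", "less"), alpha = 0.005) {
  sided <- match.arg(sided)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 2) stop("precondition error: need n >= 2", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("degenerate-test error: zero variance of differences", call. = FALSE)
  tval <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- switch(sided,
              two = 2 * stats::pt(-abs(tval), df),
              greater = stats::pt(tval, df, lower.tail = FALSE),
              less = stats::pt(tval, df))
  tibble::tibble(n = n, d_bar = mean(d), sigma = s, t = tval, df = df,
                 p = p, sided = sided, alpha = alpha)
}

#' Effect size with pooled standard deviation
#'
#' Mean difference between conditions divided by the standard deviation of
#' the pooled data (both conditions stacked).
#'
#' @param cond_a,cond_b numeric vectors of equal length (paired conditions).
#' @return numeric effect size.
#' @export
effect_size_pooled <- function(cond_a, cond_b) {
  stopifnot(length(cond_a) == length(cond_b))
  s <- stats::sd(c(cond_a, cond_b))
  if (s == 0) stop("degenerate error: zero pooled standard deviation", call. = FALSE)
  (mean(cond_a) - mean(cond_b)) / s
}

#' Normal-approximation power of a one-sided paired comparison
#'
#' \deqn{P(\mathrm{reject}\ H_0 \mid H_1) = 1 - \Phi\!\left(T - \frac{\bar d}{\sigma/\sqrt n}\right)}
#' with \eqn{T} the \eqn{1-\alpha} standard-normal quantile, \eqn{\bar d} the
#' mean difference, \eqn{\sigma} the standard deviation of the differences
#' and \eqn{n} the sample size. At \eqn{\bar d = 0} the power equals
#' \eqn{\alpha}.
#'
#' @param d_bar mean per-participant difference.
#' @param sigma standard deviation of the differences (> 0).
#' @param n sample size (>= 2).
#' @param alpha significance level in (0, 1), default 0.005.
#' @return numeric power in (0, 1).
#' @export
power_paired_normal <- function(d_bar, sigma, n, alpha = 0.005) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("invalid alpha", call. = FALSE)
  }
  stopifnot(sigma > 0, n >= 2)
  T_ <- stats::qnorm(1 - alpha)
  1 - stats::pnorm(T_ - d_bar / (sigma / sqrt(n)))
}

#' Epoch averages of a metric series
#'
#' Per-participant means over named trial windows (e.g. the last four catch
#' trials, the last 15 field trials, or the B1/B2 ten-trial windows around a
#' block boundary).
#'
#' @param metrics tibble with columns \code{participant}, a metric column,
#'   and a within-series trial order (rows are assumed ordered within
#'   participant).
#' @param value metric column name (string).
#' @param window either \code{c("last", k)} / \code{c("first", k)} or an
#'   integer vector of positions within each participant's series.
#' @return tibble: participant, epoch_mean.
#' @export
epoch_average <- function(metrics, value, window) {
  stopifnot("participant" %in% names(metrics), value %in% names(metrics))
  pick_idx <- function(n) {
    if (is.character(window[1])) {
      k <- as.integer(window[2])
      if (k > n) stop("window exceeds series length", call. = FALSE)
      if (window[1] == "last") seq(n - k + 1L, n) else seq_len(k)
    } else {
      w <- as.integer(window)
      if (any(w > n)) stop("window exceeds series length", call. = FALSE)
      w
    }
  }
  metrics |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      epoch_mean = mean(.data[[value]][pick_idx(dplyr::n())], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Random-intercept linear mixed model
#'
#' Fits \code{Y = X b + s_j + e} with a random intercept per participant, via
#' REML (default) or ML. The fixed-effect design is given as a one-sided
#' formula (e.g. \code{~ magnitude * trial} for the magnitude-cue design, or
#' \code{~ magnitude * experiment} for the between-experiment comparison).
#' t-statistics use Satterthwaite degrees of freedom.
#'
#' @param data tibble with the response, predictors, and a
#'   \code{participant} column.
#' @param response response column name (string).
#' @param fixed one-sided formula of fixed effects.
#' @param reml logical, default TRUE.
#' @return object of class \code{reach_lmm}: list with \code{fit} (the lmer
#'   fit), \code{coef} (tidy tibble: term, estimate, se, t, df, p),
#'   \code{var_random}, \code{var_residual}, \code{n_obs}, \code{n_groups},
#'   \code{df_method}.
#' @export
fit_random_intercept_lmm <- function(data, response, fixed, reml = TRUE) {
  stopifnot("participant" %in% names(data))
  if (length(unique(data$participant)) < 2) {
    stop("precondition error: need >= 2 participants", call. = FALSE)
  }
  rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  form <- stats::as.formula(paste0("`", response, "` ~ ", rhs, " + (1 | participant)"))
  X <- stats::model.matrix(fixed, data = data)
  if (qr(X)$rank < ncol(X)) stop("design error: rank-deficient fixed design", call. = FALSE)
  fit <- lmerTest::lmer(form, data = data, REML = reml)
  sm <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  coef_tbl <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    t = unname(sm[, "t value"]),
    df = unname(sm[, "df"]),
    p = unname(sm[, "Pr(>|t|)"])
  )
  structure(
    list(fit = fit, coef = coef_tbl,
         var_random = vc$vcov[vc$grp == "participant"],
         var_residual = vc$vcov[vc$grp == "Residual"],
         n_obs = nrow(data),
         n_groups = length(unique(data$participant)),
         df_method = "Satterthwaite"),
    class = "reach_lmm"
  )
}

#' @method print reach_lmm
#' @export
print.reach_lmm <- function(x, ...) {
  cat("<reach_lmm>", x$n_obs, "obs,", x$n_groups,
      "participants; random-intercept var =", signif(x$var_random, 4),
      ", residual var =", signif(x$var_residual, 4), "\n")
  print(x$coef)
  invisible(x)
}

#' @rdname fit_random_intercept_lmm
#' @param x a \code{reach_lmm}.
#' @param ... unused.
#' @export
tidy.reach_lmm <- function(x, ...) x$coef

#' @rdname fit_random_intercept_lmm
#' @export
glance.reach_lmm <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_groups = x$n_groups,
                 var_random = x$var_random, var_residual = x$var_residual,
                 df_method = x$df_method)
}
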