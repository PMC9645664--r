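#' Plot a decay-model selection
#'
#' Data with both fitted curves overlaid; the BIC-selected model is drawn
#' solid, the rejected one dashed.
#'
#' @param object a \code{decay_selection}.
#' @param x_data,y_data the fitted series (taken from the fits' residuals if
#'   omitted is not possible, so they must be supplied).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.decay_selection <- function(object, x_data, y_data, ...) {
  grid <- seq(min(x_data), max(x_data), length.out = 200)
  curve_of <- function(fit) {
    co <- fit$coef
    y <- co["a0"] + co["a1"] * exp(co["b1"] * grid)
    if (fit$model == "dual") y <- y + co["a2"] * exp(co["b2"] * grid)
    y
  }
  fits <- tibble::tibble(
    x = rep(grid, 2),
    y = c(curve_of(object$single), curve_of(object$dual)),
    model = rep(c("single", "dual"), each = length(grid))
  ) |>
    dplyr::mutate(selected = .data$model == object$selection)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = tibble::tibble(x = x_data, y = y_data),
      ggplot2::aes(x = .data$x, y = .data$y), alpha = 0.5, size = 1
    ) +
    ggplot2::geom_line(
      data = fits,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$model,
                   linetype = .data$selected)
    ) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "trial", y = "metric",
                  title = paste("BIC selects the", object$selection, "rate model")) +
    ggplot2::theme_minimal()
}

#' Plot hand paths of a simulated session
#'
#' @param session a \code{reach_session}.
#' @param trials which trial indices to draw (default: six spread over the
#'   session).
#' @return a ggplot object.
#' @export
plot_session_paths <- function(session, trials = NULL) {
  if (is.null(trials)) {
    n <- max(session$trials$trial)
    trials <- unique(round(seq(1, n, length.out = 6)))
  }
  df <- dplyr::filter(session$trials, .data$trial %in% trials)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                   colour = factor(.data$trial))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "trial") +
    ggplot2::theme_minimal()
}

#' Plot the trial-by-trial field estimate
#'
#' @param session a \code{reach_session}.
#' @param theta_true optional true field gain to draw as a reference line.
#' @return a ggplot object.
#' @export
plot_theta_series <- function(session, theta_true = NULL) {
  p <- ggplot2::ggplot(session$theta_k,
                       ggplot2::aes(x = .data$trial, y = .data$theta_hat_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "trial", y = "field estimate (N s/m)") +
    ggplot2::theme_minimal()
  if (!is.null(theta_true)) {
    p <- p + ggplot2::geom_hline(yintercept = theta_true, linetype = "dotted")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
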