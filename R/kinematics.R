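#' Zero-phase Butterworth low-pass filter
#'
#' Dual-pass (forward-backward) Butterworth filtering, the standard zero-phase
#' smoothing for kinematic recordings. The input is padded by reflection
#' (three times the filter order plus one, on each side) before filtering and
#' trimmed afterwards to suppress edge transients.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz); must exceed twice the cut-off.
#' @param fc cut-off frequency (Hz), default 50.
#' @param order filter order, default 4.
#' @return filtered signal, same length as \code{x}.
#' @export
lowpass <- function(x, fs = 1000, fc = 50, order = 4) {
  if (fc >= fs / 2) stop("invalid-config: fc must be below fs/2", call. = FALSE)
  n <- length(x)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # reflective padding sized to the filter's transient: the slowest pole of a
  # low-cut-off Butterworth decays like exp(-2*pi*fc/fs * t), so ten cut-off
  # periods reduce edge transients below 1e-9
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(10 * fs / fc)))
  idx_head <- seq(pad + 1L, 2L)
  idx_tail <- seq(n - 1L, n - pad)
  xp <- c(x[idx_head], x, x[idx_tail])
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)]
}

#' Fourth-order finite-difference velocity
#'
#' Differentiates a position series with the five-point, fourth-order centered
#' stencil at interior points; the first and last two samples use one-sided
#' fourth-order stencils. Exact for polynomials up to degree four.
#'
#' @param position numeric series (m); length >= 5.
#' @param fs sampling rate (Hz).
#' @return velocity series (m/s), same length.
#' @export
differentiate <- function(position, fs) {
  n <- length(position)
  if (n < 5L) stop("length error: need at least 5 samples", call. = FALSE)
  h <- 1 / fs
  v <- numeric(n)
  i <- 3:(n - 2)
  v[i] <- (-position[i + 2] + 8 * position[i + 1] -
             8 * position[i - 1] + position[i - 2]) / (12 * h)
  p5 <- position[1:5]
  v[1] <- sum(c(-25, 48, -36, 16, -3) * p5) / (12 * h)
  v[2] <- sum(c(-3, -10, 18, -6, 1) * p5) / (12 * h)
  q5 <- position[(n - 4):n]
  v[n - 1] <- sum(c(-1, 6, -18, 10, 3) * q5) / (12 * h)
  v[n] <- sum(c(3, -16, 36, -48, 25) * q5) / (12 * h)
  v
}

#' Reach onset sample
#'
#' First sample at which the hand is farther than \code{start_radius} from the
#' start-target centre (the coordinate origin). All trial metrics are
#' referenced to this sample.
#'
#' @param x,y position series (m), start-target-origin coordinates.
#' @param start_radius start-target radius (m), default 0.005.
#' @return integer onset index.
#' @export
reach_onset <- function(x, y, start_radius = 0.005) {
  idx <- which(sqrt(x^2 + y^2) > start_radius)
  if (!length(idx)) stop("no-onset error: hand never left the start target", call. = FALSE)
  idx[1]
}

# linear-interpolation crossing of y = thr at or after index from
threshold_crossing <- function(x, y, thr, from) {
  n <- length(y)
  idx <- which(y[from:n] >= thr)
  if (!length(idx)) stop("no-crossing error: threshold never crossed", call. = FALSE)
  i <- from + idx[1] - 1L
  if (i == 1L || y[i] == thr) {
    list(i = i, frac = 1, x = x[i], y = y[i])
  } else {
    w <- (thr - y[i - 1]) / (y[i] - y[i - 1])
    list(i = i, frac = w,
         x = x[i - 1] + w * (x[i] - x[i - 1]),
         y = thr)
  }
}

#' Initial reach angle
#'
#' Angle between the forward (+y) axis and the segment from the start target
#' to the hand at the crossing of a virtual threshold placed at one third of
#' the reach distance. Positive angles are counter-clockwise (leftward hand
#' positions give positive angles).
#'
#' @param x,y position series (m).
#' @param fs sampling rate (Hz).
#' @param reach_distance start-to-goal distance (m), default 0.15.
#' @param start_radius start-target radius for onset detection (m).
#' @return list: \code{angle_deg}, \code{crossing_time_s} (since onset),
#'   \code{onset}, \code{crossing_index}.
#' @export
initial_angle <- function(x, y, fs, reach_distance = 0.15, start_radius = 0.005) {
  onset <- reach_onset(x, y, start_radius)
  cr <- threshold_crossing(x, y, reach_distance / 3, onset)
  angle <- atan2(-cr$x, cr$y) * 180 / pi
  list(angle_deg = angle,
       crossing_time_s = (cr$i - 1 + cr$frac - onset) / fs,
       onset = onset, crossing_index = cr$i, frac = cr$frac)
}

#' Path length over a fixed window after onset
#'
#' Integral of hand speed (trapezoidal rule) from reach onset to
#' \code{t_max} seconds later (or the end of the series if shorter).
#'
#' @param vx,vy velocity series (m/s).
#' @param onset onset index.
#' @param fs sampling rate (Hz).
#' @param t_max truncation window (s), default 0.6.
#' @return path length (m).
#' @export
path_length <- function(vx, vy, onset, fs, t_max = 0.6) {
  last <- min(length(vx), onset + round(t_max * fs))
  sp <- sqrt(vx[onset:last]^2 + vy[onset:last]^2)
  sum((sp[-1] + sp[-length(sp)]) / 2) / fs
}

# full metric set from raw x/y series; the single place the pipeline order
# (filter -> differentiate -> onset -> metrics) is implemented
trial_metrics_xy <- function(x, y, fs, reach_distance = 0.15,
                             start_radius = 0.005, t_max = 0.6,
                             filter_cutoff_hz = 50, filter_order = 4) {
  if (!is.null(filter_cutoff_hz)) {
    x <- lowpass(x, fs, filter_cutoff_hz, filter_order)
    y <- lowpass(y, fs, filter_cutoff_hz, filter_order)
  }
  vx <- differentiate(x, fs)
  vy <- differentiate(y, fs)
  res <- tryCatch({
    ia <- initial_angle(x, y, fs, reach_distance, start_radius)
    # forward velocity at the (possibly fractional) crossing sample
    vy_thr <- stats::approx(seq_along(vy), vy,
                            xout = ia$crossing_index - 1 + ia$frac)$y
    tibble::tibble(
      initial_angle_deg = ia$angle_deg,
      path_length_m = path_length(vx, vy, ia$onset, fs, t_max),
      vy_at_threshold = vy_thr,
      onset_index = ia$onset,
      crossing_time_s = ia$crossing_time_s
    )
  }, error = function(e) {
    tibble::tibble(initial_angle_deg = NA_real_, path_length_m = NA_real_,
                   vy_at_threshold = NA_real_, onset_index = NA_integer_,
                   crossing_time_s = NA_real_)
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trial metrics from a long-format trial table
#'
#' Data-frame-first wrapper over the metric pipeline: filters, differentiates
#' and measures every (participant, trial) trajectory in a long trial table.
#' Trials whose hand never leaves the start target, or never crosses the
#' angle threshold, yield \code{NA} metrics.
#'
#' @param trials long tibble with columns \code{participant}, \code{trial},
#'   \code{t_ms}, \code{x_m}, \code{y_m} (force columns are carried but not
#'   required).
#' @param fs sampling rate (Hz), default 1000.
#' @param reach_distance,start_radius,t_max see [initial_angle()] and
#'   [path_length()].
#' @param filter_cutoff_hz Butterworth cut-off (Hz); \code{NULL} disables
#'   filtering (for already-smooth simulated trajectories).
#' @param filter_order Butterworth order.
#' @return tibble: participant, trial, initial_angle_deg, path_length_m,
#'   vy_at_threshold, onset_index, crossing_time_s.
#' @export
compute_trial_metrics <- function(trials, fs = 1000, reach_distance = 0.15,
                                  start_radius = 0.005, t_max = 0.6,
                                  filter_cutoff_hz = 50, filter_order = 4) {
  req <- c("participant", "trial", "x_m", "y_m")
  missing <- setdiff(req, names(trials))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials |>
    dplyr::group_by(.data$participant, .data$trial) |>
    dplyr::group_modify(function(df, key) {
      trial_metrics_xy(df$x_m, df$y_m, fs = fs,
                       reach_distance = reach_distance,
                       start_radius = start_radius, t_max = t_max,
                       filter_cutoff_hz = filter_cutoff_hz,
                       filter_order = filter_order)
    }) |>
    dplyr::ungroup()
}

#' Map both field directions onto a positive decay
#'
#' For grand averages across clockwise and counter-clockwise perturbations the
#' initial angles of one direction are negated so that both start positive and
#' decay toward zero. The direction to negate is the one whose mean angle over
#' the first \code{n_early} trials is negative.
#'
#' @param angles numeric initial angles (deg).
#' @param direction factor/vector labelling the field direction per trial.
#' @param n_early number of early trials used to decide each direction's sign.
#' @return numeric vector of sign-normalized angles.
#' @export
normalize_angle_sign <- function(angles, direction, n_early = 10) {
  out <- angles
  for (d in unique(direction)) {
    sel <- which(direction == d)
    early <- utils::head(sel, n_early)
    m <- mean(angles[early], na.rm = TRUE)
    if (is.finite(m) && m < 0) out[sel] <- -angles[sel]
  }
  out
}
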