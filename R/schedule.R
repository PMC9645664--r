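#' @importFrom rlang .data
NULL

new_trial_schedule <- function(rows, experiment, seed) {
  sched <- dplyr::bind_rows(rows)
  sched <- dplyr::mutate(sched,
                         experiment = experiment,
                         trial = dplyr::row_number(),
                         .before = 1)
  attr(sched, "seed") <- seed
  sched
}

# one block's trial multiset, randomly permuted
permute_block <- function(block_tbl) {
  block_tbl[sample.int(nrow(block_tbl)), , drop = FALSE]
}

block_rows <- function(block, context, phi, theta, is_catch, magnitude = NA_character_) {
  tibble::tibble(
    block = block,
    context = context,
    phi_N = phi,
    theta_Nspm = theta,
    is_catch = is_catch,
    magnitude = magnitude
  )
}

#' Trial schedule for the dual-context experiment (Experiment 1)
#'
#' Three blocks of 60 trials in one context — per block, 25 field trials per
#' background direction (|phi| = 4 N, |theta| = 13 N·s/m) and 5 catch trials
#' per direction, randomly interleaved — followed by a 30-trial washout
#' (background only, 15 per direction), three blocks of 60 in the opposite
#' context, and a final 30-trial control block of field trials without
#' background (15 per field direction). In the positive context the background
#' force and field gain share the same sign; in the negative context they are
#' opposite.
#'
#' @param order \code{"positive_first"} or \code{"negative_first"}.
#' @param seed integer seed controlling the within-block permutations.
#' @param phi_mag,theta_mag force magnitudes (N, N·s/m).
#' @return tibble with columns experiment, trial, block, context, phi_N,
#'   theta_Nspm, is_catch, magnitude.
#' @export
experiment1_schedule <- function(order = c("positive_first", "negative_first"),
                                 seed = 1L, phi_mag = 4, theta_mag = 13) {
  order <- match.arg(order)
  set.seed(seed)
  ctx_signs <- if (order == "positive_first") c(1, -1) else c(-1, 1)
  context_block <- function(block, ctx) {
    rows <- dplyr::bind_rows(
      block_rows(block, ctx, phi_mag, ctx * theta_mag, FALSE)[rep(1, 25), ],
      block_rows(block, ctx, -phi_mag, -ctx * theta_mag, FALSE)[rep(1, 25), ],
      block_rows(block, ctx, phi_mag, 0, TRUE)[rep(1, 5), ],
      block_rows(block, ctx, -phi_mag, 0, TRUE)[rep(1, 5), ]
    )
    permute_block(rows)
  }
  washout <- function(block) {
    rows <- dplyr::bind_rows(
      block_rows(block, 0, phi_mag, 0, TRUE)[rep(1, 15), ],
      block_rows(block, 0, -phi_mag, 0, TRUE)[rep(1, 15), ]
    )
    permute_block(rows)
  }
  control <- function(block) {
    rows <- dplyr::bind_rows(
      block_rows(block, 0, 0, theta_mag, FALSE)[rep(1, 15), ],
      block_rows(block, 0, 0, -theta_mag, FALSE)[rep(1, 15), ]
    )
    permute_block(rows)
  }
  blocks <- c(
    lapply(1:3, context_block, ctx = ctx_signs[1]),
    list(washout(4L)),
    lapply(5:7, context_block, ctx = ctx_signs[2]),
    list(control(8L))
  )
  new_trial_schedule(blocks, experiment = 1L, seed = seed)
}

#' Trial schedule for the magnitude-cue experiment (Experiment 2)
#'
#' Six blocks of 60 trials: per block, 25 light field trials
#' (phi = 2.5 N, theta = 7.5 N·s/m) and 25 heavy field trials
#' (phi = 5 N, theta = 15 N·s/m) plus 5 catch trials per magnitude, randomly
#' interleaved. All background forces point rightward.
#'
#' @param seed integer seed for the within-block permutations.
#' @return tibble as in [experiment1_schedule()], with \code{magnitude}
#'   \code{"light"}/\code{"heavy"}.
#' @export
experiment2_schedule <- function(seed = 1L) {
  set.seed(seed)
  blocks <- lapply(1:6, exp2_block)
  new_trial_schedule(blocks, experiment = 2L, seed = seed)
}

exp2_block <- function(block) {
  rows <- dplyr::bind_rows(
    block_rows(block, 1, 2.5, 7.5, FALSE, "light")[rep(1, 25), ],
    block_rows(block, 1, 5, 15, FALSE, "heavy")[rep(1, 25), ],
    block_rows(block, 1, 2.5, 0, TRUE, "light")[rep(1, 5), ],
    block_rows(block, 1, 5, 0, TRUE, "heavy")[rep(1, 5), ]
  )
  permute_block(rows)
}

#' Trial schedule for the sequential-introduction experiment (Experiment 3)
#'
#' Block 1 contains heavy trials only (50 field + 10 catch); blocks 2 and 3
#' are identical in composition to Experiment 2 blocks (light and heavy
#' randomly interleaved).
#'
#' @param seed integer seed for the within-block permutations.
#' @return tibble as in [experiment2_schedule()].
#' @export
experiment3_schedule <- function(seed = 1L) {
  set.seed(seed)
  b1 <- permute_block(dplyr::bind_rows(
    block_rows(1L, 1, 5, 15, FALSE, "heavy")[rep(1, 50), ],
    block_rows(1L, 1, 5, 0, TRUE, "heavy")[rep(1, 10), ]
  ))
  blocks <- c(list(b1), lapply(2:3, exp2_block))
  new_trial_schedule(blocks, experiment = 3L, seed = seed)
}

#' Constant-field schedule for model simulations
#'
#' A single uninterrupted series of field trials with one background/field
#' pairing — the setting used to expose the model's across- and within-trial
#' adaptation timescales over 75 trials.
#'
#' @param n_trials number of trials (default 75).
#' @param phi background force (N, default 4).
#' @param theta field gain (N·s/m, default 13).
#' @return tibble as in [experiment1_schedule()].
#' @export
constant_schedule <- function(n_trials = 75L, phi = 4, theta = 13) {
  stopifnot(n_trials >= 1)
  rows <- block_rows(1L, sign(phi * theta), phi, theta, FALSE)[rep(1, n_trials), ]
  new_trial_schedule(list(rows), experiment = 0L, seed = NA_integer_)
}

#' Write / read a trial schedule
#'
#' Plain CSV, one row per trial, columns \code{experiment, trial, block,
#' context, phi_N, theta_Nspm, is_catch, magnitude}.
#'
#' @param schedule a schedule tibble.
#' @param path file path.
#' @return \code{read_schedule} returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  cols <- readr::cols(
    experiment = readr::col_integer(),
    trial = readr::col_integer(),
    block = readr::col_integer(),
    context = readr::col_double(),
    phi_N = readr::col_double(),
    theta_Nspm = readr::col_double(),
    is_catch = readr::col_logical(),
    magnitude = readr::col_character()
  )
  sched <- suppressWarnings(readr::read_csv(path, col_types = cols))
  missing <- setdiff(names(cols$cols), names(sched))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sched
}
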