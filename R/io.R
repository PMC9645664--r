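trial_table_cols <- c("participant", "trial", "t_ms", "x_m", "y_m",
                      "fx_N", "fy_N")

#' Read / write long-format trial tables
#'
#' Plain CSV interchange for trial kinematics: one row per sample, columns
#' \code{participant, trial, t_ms, x_m, y_m, fx_N, fy_N} (positions in
#' metres, forces in newtons, time in milliseconds). Numeric values survive a
#' round trip at full precision.
#'
#' @param trials tibble of trial samples.
#' @param path file path.
#' @return \code{read_trials} returns the tibble; \code{write_trials}
#'   returns \code{path} invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_table_cols, names(trials))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # serialize doubles with 17 significant digits so every value survives the
  # text round trip bit-exactly
  out <- trials
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  )
  missing <- setdiff(trial_table_cols, names(tbl))
  if (length(missing)) {
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # base R numeric conversion is correctly rounded, preserving the written
  # 17-digit values bit-exactly
  tbl[] <- lapply(tbl, as.numeric)
  tbl
}

#' Write a run manifest
#'
#' Flat key-value text file recording what produced a set of outputs:
#' configuration values, the seed, and package/R versions.
#'
#' @param path file path.
#' @param config named list of configuration values (scalars).
#' @param seed integer seed used for the run.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), seed = NA_integer_) {
  kv <- c(
    list(package = "reachadapt",
         package_version = as.character(utils::packageVersion("reachadapt")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = seed),
    config
  )
  lines <- vapply(names(kv), function(k) paste0(k, " = ", format(kv[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}
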