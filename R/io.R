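check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

check_numeric_col <- function(df, col, what) {
  v <- df[[col]]
  bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
  if (length(bad))
    stopf("%s: non-numeric value in column `%s` at row %d", what, col, bad[1L])
  df[[col]] <- as.numeric(v)
  df
}

#' Read a long-format trace CSV
#'
#' Expects the documented schema `trace_id, cohort, t_s, value` (UTF-8,
#' header required). Each trace must be uniformly sampled in time;
#' the first offending trace is named on failure. An empty file with a
#' valid header yields an empty table.
#'
#' @param path CSV file path.
#' @return data.frame with typed columns, row order preserved.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("trace_id", "cohort", "t_s", "value"), path)
  if (nrow(df) == 0L) return(df)
  df <- check_numeric_col(df, "t_s", path)
  df <- check_numeric_col(df, "value", path)
  for (id in unique(df$trace_id)) {
    tt <- sort(df$t_s[df$trace_id == id])
    dt <- diff(tt)
    if (length(dt) > 1L && max(abs(dt - dt[1L])) > 1e-6)
      stopf("%s: trace `%s` is not uniformly sampled", path, id)
  }
  df
}

#' Read a stimulus-aligned spike CSV
#'
#' Schema: `neuron_id, stimulus_index, latency_ms`.
#'
#' @param path CSV file path.
#' @return Typed data.frame.
#' @export
read_spike_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("neuron_id", "stimulus_index", "latency_ms"), path)
  if (nrow(df) == 0L) return(df)
  df <- check_numeric_col(df, "stimulus_index", path)
  check_numeric_col(df, "latency_ms", path)
}

#' Read a psychophysics ratings CSV
#'
#' Schema: `participant_id, repeat_index, kind, rating` with `kind` in
#' single/train (a column named `repeat` is accepted and renamed).
#'
#' @param path CSV file path.
#' @return Typed data.frame.
#' @export
read_ratings_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("repeat." %in% names(df))
    names(df)[names(df) == "repeat."] <- "repeat_index"
  if ("repeat" %in% names(df))
    names(df)[names(df) == "repeat"] <- "repeat_index"
  check_columns(df, c("participant_id", "repeat_index", "kind", "rating"), path)
  if (nrow(df) == 0L) return(df)
  if (!all(df$kind %in% c("single", "train")))
    stopf("%s: column `kind` must be 'single' or 'train'", path)
  check_numeric_col(df, "rating", path)
}

#' Write a data.frame as CSV (stable formatting)
#'
#' Thin wrapper over [utils::write.csv()] without row names, so that
#' identical inputs always produce byte-identical files.
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
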