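#' Segment a trace into aligned repeat epochs
#'
#' Cuts one uniformly sampled ratio trace into the per-pulse epochs
#' defined by the schedule, each starting at a pulse onset and lasting
#' `epoch_length` seconds. The epochs are aligned sample-by-sample
#' relative to onset, which is what makes the repeat-reliability
#' variance decomposition of [reliability_snr()] meaningful.
#'
#' @param trace Numeric vector of ratio values sampled on the
#'   schedule's time base, or a data.frame with columns `t_s`, `value`.
#' @param schedule A [pulse_schedule()].
#' @return A numeric matrix with one column per pulse epoch and
#'   `epoch_length / sample_interval` rows.
#' @examples
#' sch <- pulse_schedule()
#' ep <- segment_epochs(rep(1, 340), sch)
#' dim(ep)  # 90 x 3
#' @export
segment_epochs <- function(trace, schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  v <- as_trace_values(trace, schedule)
  dt <- schedule$sample_interval
  len <- as.integer(round(schedule$epoch_length / dt))
  need <- max(schedule$pulse_onsets) / dt + len
  if (length(v) < need)
    stopf("trace too short: %d samples, schedule needs %d", length(v),
          as.integer(need))
  sapply(schedule$pulse_onsets, function(on) {
    i0 <- as.integer(round(on / dt)) + 1L
    v[i0:(i0 + len - 1L)]
  })
}

#' Repeat-reliability signal-to-noise ratio
#'
#' Scores how consistently a cell responded across repeated identical
#' stimulations. The across-repeat mean trace is taken as the signal a
#' repeat-consistent response explains; its variance over time is the
#' *explainable variance*. The *total variance* pools every sample of
#' every repeat about the grand mean. The score is
#' \deqn{SNR = \frac{signal\ power}{noise\ power}
#'          = \frac{explainable\ variance}
#'                 {total\ variance - explainable\ variance}}
#' so a threshold of 1 marks the point where signal power equals noise
#' power. Population variances (divide by N) are used throughout.
#'
#' Edge conventions: a perfectly repeatable non-constant response has
#' zero noise power and scores `Inf`; a constant trace (total variance
#' zero) scores 0.
#'
#' @param epochs Numeric matrix of aligned repeats, one column per
#'   epoch (as returned by [segment_epochs()]); at least 2 samples and
#'   2 repeats.
#' @return An object of class `reliability_score`: list with `snr`,
#'   `explainable_variance`, `total_variance`.
#' @examples
#' ep <- segment_epochs(rep(sin(1:340 / 10), 1), pulse_schedule())
#' reliability_snr(ep)
#' @export
reliability_snr <- function(epochs) {
  if (!is.matrix(epochs)) epochs <- as.matrix(epochs)
  if (any(!is.finite(epochs))) stopf("epochs contain non-finite values")
  if (nrow(epochs) < 2L || ncol(epochs) < 2L)
    stopf("need >= 2 samples and >= 2 repeats")
  m <- rowMeans(epochs)
  explainable <- pvar(m)
  total <- pvar(as.vector(epochs))
  snr <- if (total == 0) {
    0
  } else if (total - explainable <= 0) {
    Inf
  } else {
    explainable / (total - explainable)
  }
  structure(list(snr = snr, explainable_variance = explainable,
                 total_variance = total),
            class = "reliability_score")
}

#' @export
print.reliability_score <- function(x, ...) {
  cat(sprintf("reliability SNR = %.4g (explainable %.4g / total %.4g)\n",
              x$snr, x$explainable_variance, x$total_variance))
  invisible(x)
}

#' Filter traces by repeat reliability
#'
#' Applies the reliability criterion to a cohort of traces: each trace
#' is segmented into its repeat epochs, scored with
#' [reliability_snr()], and kept only if its score is strictly greater
#' than `threshold` (default 1, i.e. signal power must exceed noise
#' power). Cells lacking a second or third response - including the
#' "dying" class that stays elevated after the first pulse - score low
#' and are discarded.
#'
#' @param traces Long data.frame with columns `trace_id`, `cohort`,
#'   `t_s`, `value` (one block per trace).
#' @param schedule A [pulse_schedule()].
#' @param threshold Reliability cut-off (default 1); strictly-greater
#'   passes.
#' @return A list with `kept` and `discarded` (subsets of `traces`),
#'   `scores` (data.frame `trace_id`, `cohort`, `snr`, `kept`) and
#'   `summary` (per-cohort `n_in`, `n_kept`).
#' @export
filter_reliable <- function(traces, schedule, threshold = 1) {
  stopifnot(is.data.frame(traces))
  need <- c("trace_id", "cohort", "t_s", "value")
  if (!all(need %in% names(traces)))
    stopf("`traces` must have columns %s", paste(need, collapse = ", "))
  check_pos(threshold, "threshold", strict = FALSE)
  ids <- unique(traces$trace_id)
  scores <- do.call(rbind, lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, , drop = FALSE]
    sc <- reliability_snr(segment_epochs(tr, schedule))
    data.frame(trace_id = id, cohort = tr$cohort[1L], snr = sc$snr,
               stringsAsFactors = FALSE)
  }))
  scores$kept <- scores$snr > threshold
  kept_ids <- scores$trace_id[scores$kept]
  summary <- do.call(rbind, lapply(split(scores, scores$cohort), function(s) {
    data.frame(cohort = s$cohort[1L], n_in = nrow(s), n_kept = sum(s$kept),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(kept = traces[traces$trace_id %in% kept_ids, , drop = FALSE],
       discarded = traces[!traces$trace_id %in% kept_ids, , drop = FALSE],
       scores = scores,
       summary = summary)
}
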