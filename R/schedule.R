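#' Pulse schedule for repeated depolarisation recordings
#'
#' Describes the stimulus timing of a ratiometric calcium recording in
#' which a high-potassium depolarising pulse is delivered repeatedly:
#' 60 s of baseline, then three 30 s pulses separated by 60 s washouts,
#' sampled at 1 Hz for 340 s. Each pulse plus its washout forms one
#' 90 s analysis epoch, so repeat reliability can be scored by aligning
#' the three epochs sample by sample.
#'
#' @param pulse_onsets Numeric vector of pulse onset times in seconds,
#'   strictly increasing. Default `c(60, 150, 240)`.
#' @param pulse_duration Pulse length in seconds (default 30).
#' @param epoch_length Length of one aligned analysis epoch in seconds,
#'   pulse plus washout (default 90). Epochs must not overlap.
#' @param recording_length Total recording length in seconds (default 340).
#' @param sample_interval Sampling interval in seconds (default 1).
#' @return An object of class `pulse_schedule`.
#' @examples
#' sch <- pulse_schedule()
#' peak_times(sch)  # 90, 180, 270 s
#' @export
pulse_schedule <- function(pulse_onsets = c(60, 150, 240),
                           pulse_duration = 30,
                           epoch_length = 90,
                           recording_length = 340,
                           sample_interval = 1) {
  if (!is.numeric(pulse_onsets) || length(pulse_onsets) < 1L)
    stopf("`pulse_onsets` must be a non-empty numeric vector")
  if (is.unsorted(pulse_onsets, strictly = TRUE))
    stopf("`pulse_onsets` must be strictly increasing")
  check_pos(pulse_duration, "pulse_duration")
  check_pos(epoch_length, "epoch_length")
  check_pos(recording_length, "recording_length")
  check_pos(sample_interval, "sample_interval")
  if (pulse_duration > epoch_length)
    stopf("`pulse_duration` cannot exceed `epoch_length`")
  n <- length(pulse_onsets)
  if (n > 1L && any(pulse_onsets[-n] + epoch_length > pulse_onsets[-1L]))
    stopf("epochs overlap: onset + epoch_length exceeds the next onset")
  if (pulse_onsets[n] + epoch_length > recording_length)
    stopf("last epoch does not fit within `recording_length`")
  structure(
    list(pulse_onsets = as.numeric(pulse_onsets),
         pulse_duration = pulse_duration,
         epoch_length = epoch_length,
         recording_length = recording_length,
         sample_interval = sample_interval),
    class = "pulse_schedule")
}

#' @export
print.pulse_schedule <- function(x, ...) {
  cat("Pulse schedule:", length(x$pulse_onsets), "pulses at",
      paste(x$pulse_onsets, collapse = ", "), "s;",
      x$pulse_duration, "s pulse,", x$epoch_length, "s epoch,",
      x$recording_length, "s recording @", 1 / x$sample_interval, "Hz\n")
  invisible(x)
}

#' Nominal peak times of a pulse schedule
#'
#' The fixed read-out times for peak amplitude: each pulse onset plus the
#' pulse duration (90, 180 and 270 s under the default schedule).
#'
#' @param schedule A [pulse_schedule()].
#' @return Numeric vector of times in seconds, one per pulse.
#' @export
peak_times <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  schedule$pulse_onsets + schedule$pulse_duration
}

#' Time axis implied by a schedule
#'
#' @param schedule A [pulse_schedule()].
#' @return Numeric vector of sample times, `0, dt, ..., < recording_length`.
#' @export
schedule_times <- function(schedule) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  seq(0, schedule$recording_length - schedule$sample_interval,
      by = schedule$sample_interval)
}

# Coerce a trace argument (numeric vector or data.frame with t_s/value)
# to a plain value vector, checking uniform sampling against `schedule`.
as_trace_values <- function(trace, schedule) {
  if (is.data.frame(trace)) {
    if (!all(c("t_s", "value") %in% names(trace)))
      stopf("trace data.frame must have columns `t_s` and `value`")
    o <- order(trace$t_s)
    t_s <- trace$t_s[o]
    dt <- diff(t_s)
    if (length(dt) && max(abs(dt - schedule$sample_interval)) > 1e-8)
      stopf("trace is not uniformly sampled at the schedule's %g s interval",
            schedule$sample_interval)
    return(as.numeric(trace$value[o]))
  }
  if (!is.numeric(trace)) stopf("trace must be numeric or a data.frame")
  as.numeric(trace)
}
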