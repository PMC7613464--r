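#' Extract baselines around each pulse
#'
#' Reads the resting ratio level at the start of the recording, between
#' pulses, and at the end. Each baseline is the mean over the last
#' `window` seconds preceding the corresponding pulse onset (start and
#' inter-pulse baselines) and over the final `window` seconds of the
#' recording (end baseline).
#'
#' @param trace Numeric vector or data.frame (`t_s`, `value`) on the
#'   schedule's time base.
#' @param schedule A [pulse_schedule()].
#' @param window Averaging window in seconds (default 15). Must fit in
#'   the pre-pulse gap.
#' @return Named numeric vector: `start`, `pre_pulse_2`, ...,
#'   `pre_pulse_n`, `end`.
#' @export
extract_baselines <- function(trace, schedule, window = 15) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  check_pos(window, "window")
  v <- as_trace_values(trace, schedule)
  dt <- schedule$sample_interval
  w <- as.integer(round(window / dt))
  gaps <- c(schedule$pulse_onsets[1L],
            diff(schedule$pulse_onsets) - schedule$pulse_duration)
  if (any(window > gaps))
    stopf("`window` (%g s) exceeds an available pre-pulse gap (%g s)",
          window, min(gaps))
  ends <- c(schedule$pulse_onsets / dt, length(v))  # sample index before each onset; end
  out <- vapply(ends, function(e) {
    i1 <- as.integer(round(e))
    mean(v[(i1 - w + 1L):i1])
  }, numeric(1))
  names(out) <- c("start",
                  if (length(schedule$pulse_onsets) > 1L)
                    sprintf("pre_pulse_%d", seq_along(schedule$pulse_onsets)[-1L]),
                  "end")
  out
}

#' Extract per-pulse peak values
#'
#' Reads the response peak of each pulse either at the fixed nominal
#' peak time (pulse onset + duration; 90, 180 and 270 s under the
#' default schedule) or as the maximum within each pulse window.
#'
#' @inheritParams extract_baselines
#' @param mode `"at_fixed_times"` (default; the protocol specifies the
#'   read-out times) or `"window_max"` (maximum over the pulse window,
#'   robust to small timing jitter).
#' @return Named numeric vector, one value per pulse.
#' @export
extract_peaks <- function(trace, schedule,
                          mode = c("at_fixed_times", "window_max")) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  mode <- match.arg(mode)
  v <- as_trace_values(trace, schedule)
  dt <- schedule$sample_interval
  pk <- peak_times(schedule)
  if (max(pk) / dt + 1 > length(v))
    stopf("peak time %g s lies outside the trace", max(pk))
  out <- if (mode == "at_fixed_times") {
    v[as.integer(round(pk / dt)) + 1L]
  } else {
    vapply(seq_along(pk), function(i) {
      i0 <- as.integer(round(schedule$pulse_onsets[i] / dt)) + 1L
      i1 <- as.integer(round(pk[i] / dt)) + 1L
      max(v[i0:i1])
    }, numeric(1))
  }
  names(out) <- sprintf("pulse_%d", seq_along(pk))
  out
}

#' Area under the curve per pulse epoch
#'
#' Trapezoidal integral of `value - reference` over each pulse epoch
#' (`[onset, onset + epoch_length)`), with negative contributions
#' retained. Integrating about a caller-supplied reference - by
#' convention the cohort mean of start baselines - makes AUC
#' comparisons independent of between-cohort baseline offsets.
#'
#' @inheritParams extract_baselines
#' @param reference Scalar reference level in ratio units.
#' @return Named numeric vector of AUCs (ratio x s), one per pulse.
#' @export
compute_auc <- function(trace, schedule, reference) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (!is.numeric(reference) || length(reference) != 1L || is.na(reference))
    stopf("`reference` must be a single number")
  ep <- segment_epochs(trace, schedule)
  dt <- schedule$sample_interval
  tt <- (seq_len(nrow(ep)) - 1L) * dt
  out <- apply(ep, 2L, function(col) pracma::trapz(tt, col - reference))
  names(out) <- sprintf("pulse_%d", seq_len(ncol(ep)))
  out
}

#' Fit the exponential decay constant after one pulse
#'
#' Fits \eqn{f(t) = A e^{-t/\tau}} to the decay phase following a
#' pulse, where `A` is the ratio at the peak (t = 0 is the peak
#' sample) and after one time constant the response has fallen to
#' \eqn{e^{-1} \approx 37\%} of `A`. The decay segment runs from the
#' nominal peak time to the next pulse onset (or the end of the
#' recording) and is first normalised by subtracting its final value,
#' so the fitted decay ends at 0.
#'
#' Starting values: `A0` = first (normalised) segment value; `tau0` =
#' linearly interpolated time at which the segment first falls to 37%
#' of `A0`. Fitting uses Levenberg-Marquardt nonlinear least squares
#' with a free residual offset (initialised at 0 after the shift):
#' subtracting the final *sample* only approximates the true
#' asymptote, and absorbing the remainder in an offset term removes
#' that bias, so noiseless exponentials are recovered exactly.
#' Degenerate segments (non-positive initial amplitude, e.g. a
#' monotonically increasing segment) or non-convergence yield a
#' fit-failure result with `tau = NA`, not an error.
#'
#' @inheritParams extract_baselines
#' @param pulse_index Which pulse's decay to fit (1-based).
#' @return List with `tau` (s, `NA` on failure), `amplitude`,
#'   `converged`, `residual_rms`, and `n` (segment length).
#' @export
fit_tau <- function(trace, schedule, pulse_index = 1L) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  np <- length(schedule$pulse_onsets)
  check_count(pulse_index, "pulse_index")
  if (pulse_index > np) stopf("pulse_index %d > number of pulses %d",
                              pulse_index, np)
  v <- as_trace_values(trace, schedule)
  dt <- schedule$sample_interval
  t_start <- peak_times(schedule)[pulse_index]
  t_end <- if (pulse_index < np) schedule$pulse_onsets[pulse_index + 1L] else
    (length(v) - 1L) * dt
  i0 <- as.integer(round(t_start / dt)) + 1L
  i1 <- as.integer(round(t_end / dt)) + 1L
  i1 <- min(i1, length(v))
  if (i1 - i0 + 1L < 5L)
    stopf("decay segment for pulse %d has fewer than 5 samples", pulse_index)
  seg <- v[i0:i1]
  tt <- (seq_along(seg) - 1L) * dt

  y <- seg - seg[length(seg)]      # normalise: final decay value = 0
  a0 <- y[1L]
  fail <- list(tau = NA_real_, amplitude = NA_real_, converged = FALSE,
               residual_rms = NA_real_, n = length(y))
  if (!is.finite(a0) || a0 <= 0) return(fail)

  # initial tau: time to fall to 37% of A0, linearly interpolated
  target <- exp(-1) * a0
  below <- which(y <= target)
  tau0 <- if (length(below) == 0L) {
    max(tt)
  } else {
    k <- below[1L]
    if (k == 1L) dt else {
      frac <- (y[k - 1L] - target) / (y[k - 1L] - y[k])
      tt[k - 1L] + frac * dt
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + C,
                      start = list(A = a0, tau = max(tau0, dt / 2), C = 0),
                      lower = c(A = 0, tau = 1e-6, C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- coef(fit)
  if (cf[["tau"]] <= 1e-5 || cf[["A"]] <= 0) return(fail)
  list(tau = unname(cf[["tau"]]), amplitude = unname(cf[["A"]]),
       converged = TRUE,
       residual_rms = sqrt(mean(residuals(fit)^2)), n = length(y))
}

#' Remove implausible decay constants by cohort rule
#'
#' Dorsal horn (DH) cultures lose tau values above 200 s; dorsal root
#' ganglion (DRG) cultures above 100 s. Values above the cohort's
#' threshold reflect failed or degenerate fits rather than physiology
#' and are excluded.
#'
#' @param taus Numeric vector of fitted decay constants (s).
#' @param cohort `"DH"` or `"DRG"`.
#' @param thresholds Named numeric vector of cut-offs by cohort;
#'   default `c(DH = 200, DRG = 100)`.
#' @return List with `kept` and `removed` numeric vectors.
#' @examples
#' remove_tau_outliers(c(10, 150, 250), "DH")
#' @export
remove_tau_outliers <- function(taus, cohort,
                                thresholds = c(DH = 200, DRG = 100)) {
  if (!is.character(cohort) || length(cohort) != 1L ||
      !cohort %in% names(thresholds))
    stopf("unknown cohort %s; expected one of %s",
          paste(format(cohort), collapse = ","),
          paste(names(thresholds), collapse = ", "))
  taus <- as.numeric(taus)
  cut <- thresholds[[cohort]]
  list(kept = taus[!is.na(taus) & taus <= cut],
       removed = taus[!is.na(taus) & taus > cut])
}

#' Per-cell calcium response metrics for a trace cohort
#'
#' Convenience wrapper running [extract_baselines()],
#' [extract_peaks()], [compute_auc()] and [fit_tau()] over every trace
#' in a long-format table (typically the `kept` output of
#' [filter_reliable()]). The AUC reference defaults to the cohort mean
#' of start baselines, computed per cohort label.
#'
#' @param traces Long data.frame (`trace_id`, `cohort`, `t_s`, `value`).
#' @param schedule A [pulse_schedule()].
#' @param baseline_window Baseline averaging window in seconds.
#' @param peak_mode Passed to [extract_peaks()].
#' @param auc_reference Optional scalar override of the per-cohort AUC
#'   reference.
#' @return data.frame with one row per trace x pulse: baseline columns,
#'   `peak`, `auc`, `tau`, `tau_converged`.
#' @export
calcium_metrics <- function(traces, schedule, baseline_window = 15,
                            peak_mode = "at_fixed_times",
                            auc_reference = NULL) {
  stopifnot(is.data.frame(traces))
  ids <- unique(traces$trace_id)
  base <- lapply(ids, function(id) {
    extract_baselines(traces[traces$trace_id == id, ], schedule,
                      window = baseline_window)
  })
  names(base) <- ids
  cohort_of <- vapply(ids, function(id)
    as.character(traces$cohort[traces$trace_id == id][1L]), character(1))
  start_base <- vapply(base, `[[`, numeric(1), "start")
  ref_by_cohort <- tapply(start_base, cohort_of, mean)

  rows <- lapply(ids, function(id) {
    tr <- traces[traces$trace_id == id, ]
    ref <- if (is.null(auc_reference)) ref_by_cohort[[cohort_of[[id]]]] else
      auc_reference
    pk <- extract_peaks(tr, schedule, mode = peak_mode)
    auc <- compute_auc(tr, schedule, reference = ref)
    np <- length(schedule$pulse_onsets)
    taus <- lapply(seq_len(np), function(p) fit_tau(tr, schedule, p))
    data.frame(trace_id = id, cohort = cohort_of[[id]],
               pulse = seq_len(np),
               baseline_start = base[[id]][["start"]],
               baseline_end = base[[id]][["end"]],
               peak = unname(pk), auc = unname(auc),
               auc_reference = ref,
               tau = vapply(taus, `[[`, numeric(1), "tau"),
               tau_converged = vapply(taus, `[[`, logical(1), "converged"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
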