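#' Post-stimulus latency bands for fibre-type attribution
#'
#' Spikes evoked by a transcutaneous electrical stimulus are attributed
#' to fibre populations by their latency: A-fibre 0-50 ms, C-fibre
#' 50-250 ms, and post-discharge (PD) from 250 ms up to `pd_end`.
#' Intervals are half-open, lower-inclusive, so a spike at exactly
#' 50 ms is counted as C-fibre.
#'
#' @param pd_end Upper bound of the post-discharge band in ms; by
#'   convention the inter-stimulus interval (2000 ms at 0.5 Hz).
#' @param a_end,c_end Band boundaries in ms (defaults 50 and 250).
#' @return An object of class `latency_bands`: list of length-2
#'   interval vectors `A`, `C`, `PD`.
#' @export
latency_bands <- function(pd_end = 2000, a_end = 50, c_end = 250) {
  check_pos(a_end, "a_end"); check_pos(c_end, "c_end")
  check_pos(pd_end, "pd_end")
  if (!(a_end < c_end && c_end < pd_end))
    stopf("bands must satisfy 0 < a_end < c_end < pd_end")
  structure(list(A = c(0, a_end), C = c(a_end, c_end), PD = c(c_end, pd_end)),
            class = "latency_bands")
}

#' Count spikes per latency band
#'
#' Assigns every spike of a stimulus-aligned spike table to its latency
#' band ([latency_bands()]; half-open, lower-inclusive intervals) and
#' tabulates counts per band and per stimulus. Latencies at or beyond
#' the post-discharge upper bound are not silently dropped: they are
#' excluded from the bands but reported as `overflow`, so band totals
#' plus overflow always conserve the spike count.
#'
#' @param spikes data.frame with columns `stimulus_index`, `latency_ms`
#'   (negative latencies are invalid).
#' @param bands A [latency_bands()] object.
#' @param n_stimuli Number of stimuli in the train (default 16).
#' @return List with `band_totals` (named A/C/PD), `per_stimulus`
#'   (matrix stimuli x bands), `overflow` (count), `total` (all spikes).
#' @examples
#' sp <- data.frame(stimulus_index = 1, latency_ms = c(10, 49.9, 50, 250))
#' band_counts(sp, latency_bands())$band_totals  # A 2, C 1, PD 1
#' @export
band_counts <- function(spikes, bands = latency_bands(), n_stimuli = 16) {
  stopifnot(inherits(bands, "latency_bands"), is.data.frame(spikes))
  if (nrow(spikes) && any(spikes$latency_ms < 0))
    stopf("negative spike latencies are invalid")
  if (nrow(spikes) && any(spikes$stimulus_index < 1 |
                          spikes$stimulus_index > n_stimuli))
    stopf("stimulus_index outside 1..%d", n_stimuli)
  lat <- spikes$latency_ms
  band <- rep(NA_character_, length(lat))
  for (b in c("A", "C", "PD"))
    band[lat >= bands[[b]][1L] & lat < bands[[b]][2L]] <- b
  per <- matrix(0L, nrow = n_stimuli, ncol = 3L,
                dimnames = list(NULL, c("A", "C", "PD")))
  inb <- !is.na(band)
  if (any(inb)) {
    tab <- table(factor(spikes$stimulus_index[inb], levels = seq_len(n_stimuli)),
                 factor(band[inb], levels = c("A", "C", "PD")))
    per[] <- as.integer(tab)
  }
  list(band_totals = colSums(per), per_stimulus = per,
       overflow = sum(!inb), total = length(lat))
}

#' Input and wind-up from per-stimulus spike counts
#'
#' The *input* (non-potentiated response) is the response expected if
#' no potentiation occurred: the first-pulse spike count multiplied by
#' the number of pulses. *Wind-up* is the excess over that baseline:
#' total spikes across the train minus the input. Wind-up may be
#' negative when the response habituates.
#'
#' @param per_stimulus_counts Numeric vector of spike counts, one per
#'   stimulus in train order (length >= 1).
#' @return List with `input`, `windup`, `total`.
#' @examples
#' input_windup(c(10, rep(20, 15)))  # input 160, windup 150
#' @export
input_windup <- function(per_stimulus_counts) {
  x <- as.numeric(per_stimulus_counts)
  if (length(x) < 1L || any(!is.finite(x)))
    stopf("`per_stimulus_counts` must be a non-empty finite numeric vector")
  n <- length(x)
  input <- x[1L] * n
  total <- sum(x)
  list(input = input, windup = total - input, total = total)
}

#' Fit the one-phase association rate constant of wind-up
#'
#' Nonlinear least-squares fit of the saturating growth law
#' \deqn{y(i) = y_0 + (P - y_0)(1 - e^{-k(i-1)})}
#' to per-stimulus spike counts over stimulus index `i = 1..n`, with
#' the index shifted so `y(1) = y0` exactly. Starting values: `y0` at
#' the first count, plateau at the mean of the last three counts, `k`
#' at 0.3. A flat response leaves `k` unidentifiable; it is reported
#' as `k = 0` with `identifiable = FALSE` rather than an error.
#'
#' @param per_stimulus_counts Numeric vector of counts (length >= 4).
#' @return List with `k`, `plateau`, `y0`, `converged`,
#'   `identifiable`, `residual_rms`.
#' @export
fit_rate_constant <- function(per_stimulus_counts) {
  y <- as.numeric(per_stimulus_counts)
  n <- length(y)
  if (n < 4L) stopf("need at least 4 stimuli to fit a rate constant")
  if (any(!is.finite(y))) stopf("counts must be finite")
  i <- seq_len(n)
  if (max(y) - min(y) == 0)
    return(list(k = 0, plateau = y[1L], y0 = y[1L], converged = TRUE,
                identifiable = FALSE, residual_rms = 0))
  y0_0 <- y[1L]
  p0 <- mean(y[(n - 2L):n])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ y0 + (plateau - y0) * (1 - exp(-k * (i - 1))),
                      start = list(y0 = y0_0, plateau = p0, k = 0.3),
                      lower = c(y0 = -Inf, plateau = -Inf, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k = NA_real_, plateau = NA_real_, y0 = NA_real_,
                converged = FALSE, identifiable = NA, residual_rms = NA_real_))
  cf <- coef(fit)
  list(k = unname(cf[["k"]]), plateau = unname(cf[["plateau"]]),
       y0 = unname(cf[["y0"]]), converged = TRUE, identifiable = TRUE,
       residual_rms = sqrt(mean(residuals(fit)^2)))
}

#' Full wind-up quantification for one spike table
#'
#' Combines [band_counts()], [input_windup()] and
#' [fit_rate_constant()] for a single neuron's stimulus-aligned spike
#' table.
#'
#' @param spikes data.frame (`neuron_id`, `stimulus_index`, `latency_ms`).
#' @param bands A [latency_bands()]; default PD upper bound from `isi`.
#' @param n_stimuli Stimuli per train (default 16).
#' @param isi Inter-stimulus interval in seconds (default 2).
#' @param fit_k Whether to fit the rate constant (default TRUE).
#' @return List: `per_stimulus_counts`, `band_totals`, `overflow`,
#'   `input`, `windup`, `total`, and (if fitted) `rate_constant`,
#'   `plateau`, `y0`, `fit`.
#' @export
windup_result <- function(spikes, bands = NULL, n_stimuli = 16, isi = 2,
                          fit_k = TRUE) {
  if (is.null(bands)) bands <- latency_bands(pd_end = isi * 1000)
  bc <- band_counts(spikes, bands, n_stimuli)
  counts <- rowSums(bc$per_stimulus)
  iw <- input_windup(counts)
  out <- list(per_stimulus_counts = counts, band_totals = bc$band_totals,
              overflow = bc$overflow, input = iw$input, windup = iw$windup,
              total = iw$total)
  if (fit_k) {
    f <- fit_rate_constant(counts)
    out$rate_constant <- f$k
    out$plateau <- f$plateau
    out$y0 <- f$y0
    out$fit <- f
  }
  out
}

#' Receptive-field positivity criterion
#'
#' A skin area belongs to a neuron's receptive field if probing it
#' evokes more than 30 action potentials over 5 s. For other window
#' lengths the criterion scales proportionally (6 spikes/s).
#'
#' @param spike_count Observed spike count (>= 0).
#' @param window Observation window in seconds (default 5).
#' @return Logical flag.
#' @examples
#' receptive_field_positive(31)         # TRUE
#' receptive_field_positive(30)         # FALSE (strict)
#' receptive_field_positive(15, 2.5)    # threshold 15 -> FALSE
#' @export
receptive_field_positive <- function(spike_count, window = 5) {
  if (!is.numeric(spike_count) || length(spike_count) != 1L ||
      is.na(spike_count) || spike_count < 0)
    stopf("`spike_count` must be a single non-negative number")
  check_pos(window, "window")
  spike_count > 30 * window / 5
}

#' Classify an afferent fibre by conduction velocity
#'
#' Computes velocity = distance / latency and assigns the fibre class
#' by half-open velocity bands: A-beta 20-100 m/s, A-delta 2-20 m/s,
#' C 0.05-2 m/s; anything outside is `"unclassified"`.
#'
#' @param distance Conduction distance in metres (> 0).
#' @param latency Response latency in seconds (> 0).
#' @return Character scalar: `"Abeta"`, `"Adelta"`, `"C"` or
#'   `"unclassified"`.
#' @examples
#' classify_fiber_velocity(0.05, 0.0025)  # 20 m/s -> Abeta
#' classify_fiber_velocity(0.05, 0.1)     # 0.5 m/s -> C
#' @export
classify_fiber_velocity <- function(distance, latency) {
  check_pos(distance, "distance")
  check_pos(latency, "latency")
  v <- distance / latency
  if (v >= 20 && v < 100) "Abeta"
  else if (v >= 2 && v < 20) "Adelta"
  else if (v >= 0.05 && v < 2) "C"
  else "unclassified"
}
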