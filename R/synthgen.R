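#' Simulate ratiometric calcium traces with known ground truth
#'
#' Generates a cohort of Fura-2-style 340/380 ratio traces under the
#' three-pulse depolarisation protocol described by a [pulse_schedule()]:
#' baseline, then repeated 30 s high-K+ pulses each followed by a
#' washout. Three trace classes are produced:
#'
#' * **responder** - rises linearly to its peak amplitude during every
#'   pulse window, then decays exponentially with the cell's own time
#'   constant tau;
#' * **non-responder** - noise around baseline (e.g. a glial cell);
#' * **dying** - responds to the first pulse only, then remains at the
#'   elevated level for the rest of the recording (calcium overload
#'   without recovery), with no later peaks.
#'
#' Class probabilities are `responder_fraction`, `dying_fraction`, and
#' the remainder non-responders. Noise is additive Gaussian per sample.
#'
#' @param n_cells Number of cells to simulate.
#' @param responder_fraction Probability that a cell is a reliable
#'   responder. The default 0.73 mirrors the retention rate seen when
#'   reliability-filtering dorsal horn cultures.
#' @param baseline_level Baseline ratio (dimensionless, default 0.8).
#' @param baseline_drift Linear drift in ratio units per second (default 0).
#' @param peak_amplitude_mean,peak_amplitude_sd Peak response amplitude
#'   above baseline, in ratio units (cell-to-cell normal variation,
#'   truncated positive).
#' @param tau_mean,tau_sd Exponential decay constant in seconds
#'   (cell-to-cell variation, truncated at 1 s).
#' @param noise_sd Additive noise SD in ratio units.
#' @param dying_fraction Probability of the dying-cell class.
#' @param cohort Cohort label attached to every trace (e.g. `"WT"`).
#' @param schedule A [pulse_schedule()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with elements `traces` (long data.frame: `trace_id`,
#'   `cohort`, `t_s`, `value`), `truth` (one row per cell: `trace_id`,
#'   `cohort`, `class`, `baseline`, `amplitude`, `tau`) and `schedule`.
#' @examples
#' sim <- sim_ratio_traces(n_cells = 5, seed = 1)
#' table(sim$truth$class)
#' @export
sim_ratio_traces <- function(n_cells = 100,
                             responder_fraction = 0.73,
                             baseline_level = 0.8,
                             baseline_drift = 0,
                             peak_amplitude_mean = 1,
                             peak_amplitude_sd = 0.2,
                             tau_mean = 20,
                             tau_sd = 5,
                             noise_sd = 0.02,
                             dying_fraction = 0.07,
                             cohort = "WT",
                             schedule = pulse_schedule(),
                             seed = 1) {
  check_count(n_cells, "n_cells")
  check_prob(responder_fraction, "responder_fraction")
  check_prob(dying_fraction, "dying_fraction")
  if (responder_fraction + dying_fraction > 1)
    stopf("responder_fraction + dying_fraction must not exceed 1")
  check_pos(tau_mean, "tau_mean")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_pos(peak_amplitude_mean, "peak_amplitude_mean")
  stopifnot(inherits(schedule, "pulse_schedule"))

  t_s <- schedule_times(schedule)
  nt <- length(t_s)
  with_seed(seed, {
    cls <- sample(c("responder", "dying", "non_responder"), n_cells,
                  replace = TRUE,
                  prob = c(responder_fraction, dying_fraction,
                           1 - responder_fraction - dying_fraction))
    amp <- pmax(rnorm(n_cells, peak_amplitude_mean, peak_amplitude_sd), 0.05)
    tau <- pmax(rnorm(n_cells, tau_mean, tau_sd), 1)
    values <- matrix(0, nrow = nt, ncol = n_cells)
    for (j in seq_len(n_cells)) {
      sig <- baseline_level + baseline_drift * t_s
      if (cls[j] == "responder") {
        for (on in schedule$pulse_onsets)
          sig <- sig + pulse_component(t_s, on, schedule$pulse_duration,
                                       amp[j], tau[j])
      } else if (cls[j] == "dying") {
        on <- schedule$pulse_onsets[1L]
        pk <- on + schedule$pulse_duration
        ramp <- pmin(pmax((t_s - on) / schedule$pulse_duration, 0), 1)
        sig <- sig + amp[j] * ramp * (t_s >= on)
        # stays at baseline + amplitude after the first peak: no decay
        sig[t_s >= pk] <- baseline_level + baseline_drift * t_s[t_s >= pk] + amp[j]
      }
      if (noise_sd > 0) sig <- sig + rnorm(nt, 0, noise_sd)
      values[, j] <- sig
    }
    ids <- sprintf("cell_%03d", seq_len(n_cells))
    truth <- data.frame(
      trace_id = ids, cohort = cohort, class = cls,
      baseline = baseline_level,
      amplitude = ifelse(cls == "non_responder", NA_real_, amp),
      tau = ifelse(cls == "responder", tau, NA_real_),
      stringsAsFactors = FALSE)
    traces <- data.frame(
      trace_id = rep(ids, each = nt),
      cohort = cohort,
      t_s = rep(t_s, times = n_cells),
      value = as.vector(values),
      stringsAsFactors = FALSE)
    list(traces = traces, truth = truth, schedule = schedule)
  })
}

# Single-pulse ratio component: linear ramp to `amp` across the pulse
# window, then exponential decay with constant `tau` from the peak time.
pulse_component <- function(t_s, onset, duration, amp, tau) {
  pk <- onset + duration
  comp <- numeric(length(t_s))
  ramp <- t_s >= onset & t_s <= pk
  comp[ramp] <- amp * (t_s[ramp] - onset) / duration
  dec <- t_s > pk
  comp[dec] <- amp * exp(-(t_s[dec] - pk) / tau)
  comp
}

#' Simulate an in vivo stimulus-train fluorescence recording
#'
#' Emulates a single-photon recording of dorsal horn projection neurons
#' expressing a genetically encoded calcium indicator: a 2 min
#' pre-stimulus baseline followed by a train of electrical stimuli
#' (default 16 pulses) at a fixed frequency, imaged at ~4 Hz. Responder
#' ROIs show a stimulus-locked transient at each pulse (instantaneous
#' rise, exponential decay, linear summation across pulses); all ROIs
#' carry additive noise, and a background trace with its own offset is
#' included so that background subtraction can be exercised.
#'
#' @param freq Stimulation frequency in Hz (> 0; the protocol uses 0.2,
#'   0.5 and 1 Hz trains).
#' @param n_rois Number of cellular ROIs.
#' @param responder_fraction Probability an ROI responds to the train.
#' @param n_stimuli Number of pulses in the train (default 16).
#' @param amplitude,amplitude_sd Fractional transient amplitude per pulse
#'   (peak dF/F of a single isolated transient = 100 * amplitude %).
#' @param decay_s Transient decay constant in seconds. At 1 Hz a decay
#'   slower than the inter-stimulus interval makes transients summate.
#' @param baseline_s Pre-stimulus baseline length in seconds (default 120).
#' @param sample_rate Imaging rate in Hz (default 4).
#' @param f0_level Baseline cellular fluorescence in arbitrary units.
#' @param background_level Background ROI fluorescence (additive offset).
#' @param noise_sd Additive noise SD in the same arbitrary units.
#' @param animal_id,cohort Labels carried through aggregation.
#' @param seed Integer seed.
#' @return An object of class `dff_recording`: a list with `time`,
#'   `traces` (matrix, samples x ROIs), `background`, `stim_times`,
#'   `freq`, `animal_id`, `cohort`, plus a `truth` data.frame
#'   (`roi_id`, `is_responder`, `amplitude`).
#' @export
sim_dff_recording <- function(freq = 0.5,
                              n_rois = 20,
                              responder_fraction = 0.8,
                              n_stimuli = 16,
                              amplitude = 0.4,
                              amplitude_sd = 0.08,
                              decay_s = 2,
                              baseline_s = 120,
                              sample_rate = 4,
                              f0_level = 100,
                              background_level = 20,
                              noise_sd = 1,
                              animal_id = "animal_1",
                              cohort = "WT",
                              seed = 1) {
  check_pos(freq, "freq")
  check_count(n_rois, "n_rois")
  check_prob(responder_fraction, "responder_fraction")
  check_count(n_stimuli, "n_stimuli", min = 1L)
  check_pos(sample_rate, "sample_rate")
  check_pos(f0_level, "f0_level")
  check_pos(noise_sd, "noise_sd", strict = FALSE)

  dt <- 1 / sample_rate
  train_len <- (n_stimuli - 1) / freq
  total_s <- baseline_s + train_len + max(20, 5 * decay_s)
  time <- seq(0, total_s, by = dt)
  stim_times <- baseline_s + (seq_len(n_stimuli) - 1) / freq

  with_seed(seed, {
    resp <- runif(n_rois) < responder_fraction
    amps <- pmax(rnorm(n_rois, amplitude, amplitude_sd), 0)
    amps[!resp] <- 0
    traces <- matrix(0, nrow = length(time), ncol = n_rois)
    for (j in seq_len(n_rois)) {
      frac <- numeric(length(time))
      if (amps[j] > 0) {
        for (s in stim_times) {
          post <- time >= s
          frac[post] <- frac[post] + amps[j] * exp(-(time[post] - s) / decay_s)
        }
      }
      traces[, j] <- background_level + f0_level * (1 + frac) +
        rnorm(length(time), 0, noise_sd)
    }
    colnames(traces) <- sprintf("roi_%02d", seq_len(n_rois))
    background <- background_level + rnorm(length(time), 0, noise_sd)
    truth <- data.frame(roi_id = colnames(traces), is_responder = resp,
                        amplitude = amps, stringsAsFactors = FALSE)
    structure(list(time = time, traces = traces, background = background,
                   stim_times = stim_times, freq = freq,
                   animal_id = animal_id, cohort = cohort,
                   background_subtracted = FALSE, truth = truth),
              class = "dff_recording")
  })
}

#' @export
print.dff_recording <- function(x, ...) {
  cat("dff_recording:", ncol(x$traces), "ROIs,",
      length(x$time), "samples,", length(x$stim_times),
      "stimuli at", x$freq, "Hz",
      if (isTRUE(x$background_subtracted)) "(background subtracted)" else "",
      "\n")
  invisible(x)
}

#' Simulate a stimulus-aligned spike table under a wind-up growth law
#'
#' Draws per-stimulus spike counts for one dorsal horn neuron receiving
#' a train of electrical stimuli, with the expected count following the
#' one-phase association (saturating-growth) law
#' \deqn{y(i) = y_0 + (P - y_0)(1 - e^{-k(i-1)})}
#' where \eqn{y_0} is the first-pulse count, \eqn{P} the plateau and
#' \eqn{k} the per-stimulus rate constant. Each spike is assigned a
#' post-stimulus latency band (A-fibre, C-fibre or post-discharge) by a
#' multinomial draw and given a uniform latency within its band.
#'
#' @param first_pulse_count Expected spike count at the first stimulus.
#' @param plateau Asymptotic per-stimulus count (>= 0).
#' @param rate_constant Per-stimulus rate constant k (>= 0).
#' @param band_fractions Length-3 proportions over the A
#'   (0-50 ms), C (50-250 ms) and post-discharge (250 ms-ISI) latency
#'   bands; must sum to 1.
#' @param count_noise Count noise model: 0 = deterministic (counts are
#'   the rounded means), 1 = Poisson, > 1 = negative binomial with
#'   variance `count_noise` times the mean.
#' @param n_stimuli Number of stimuli in the train (default 16).
#' @param isi Inter-stimulus interval in seconds (default 2 s = 0.5 Hz).
#' @param neuron_id Identifier attached to the spikes.
#' @param seed Integer seed.
#' @return A list with `spikes` (data.frame: `neuron_id`,
#'   `stimulus_index`, `latency_ms`), `counts` (integer per-stimulus
#'   counts), `expected` (the noiseless growth-law means), `isi` and
#'   `truth` (the generating parameters).
#' @export
sim_spike_table <- function(first_pulse_count = 27,
                            plateau = 70,
                            rate_constant = 0.177,
                            band_fractions = c(A = 0.25, C = 0.55, PD = 0.20),
                            count_noise = 1,
                            n_stimuli = 16,
                            isi = 2,
                            neuron_id = "neuron_1",
                            seed = 1) {
  check_pos(first_pulse_count, "first_pulse_count", strict = FALSE)
  if (!is.numeric(plateau) || plateau < 0) stopf("`plateau` must be >= 0")
  check_pos(rate_constant, "rate_constant", strict = FALSE)
  check_count(n_stimuli, "n_stimuli", min = 2L)
  check_pos(isi, "isi")
  if (length(band_fractions) != 3L || any(band_fractions < 0) ||
      abs(sum(band_fractions) - 1) > 1e-8)
    stopf("`band_fractions` must be 3 non-negative proportions summing to 1")
  check_pos(count_noise, "count_noise", strict = FALSE)

  i <- seq_len(n_stimuli)
  mu <- first_pulse_count +
    (plateau - first_pulse_count) * (1 - exp(-rate_constant * (i - 1)))
  bands <- latency_bands(pd_end = isi * 1000)
  with_seed(seed, {
    counts <- if (count_noise == 0) {
      as.integer(round(mu))
    } else if (count_noise <= 1) {
      rpois(n_stimuli, mu)
    } else {
      # variance = count_noise * mean  =>  size = mean / (count_noise - 1)
      rnbinom(n_stimuli, size = pmax(mu, 1e-9) / (count_noise - 1), mu = mu)
    }
    total <- sum(counts)
    band_of <- sample(c("A", "C", "PD"), total, replace = TRUE,
                      prob = band_fractions)
    lims <- rbind(A = bands$A, C = bands$C, PD = bands$PD)
    latency <- runif(total, lims[band_of, 1L], lims[band_of, 2L])
    spikes <- data.frame(
      neuron_id = neuron_id,
      stimulus_index = rep(i, times = counts),
      latency_ms = latency,
      stringsAsFactors = FALSE)
    list(spikes = spikes, counts = as.integer(counts), expected = mu,
         isi = isi,
         truth = list(y0 = first_pulse_count, plateau = plateau,
                      rate_constant = rate_constant,
                      band_fractions = band_fractions))
  })
}

#' Simulate a wind-up-ratio psychophysics cohort
#'
#' Generates per-participant pain ratings for the temporal-summation
#' protocol: five repeats of a single punctate stimulus rating plus
#' five repeats of the mean rating over a 10-stimulus 1 Hz train, on a
#' 0-100 numerical scale. The true wind-up ratio (WUR) of each
#' participant is log-normal, giving the long right tail seen in
#' population data. A fraction of participants are "outliers" whose
#' single-stimulus ratings are near zero (e.g. 0.001), producing the
#' implausibly large WUR values (> 6) that the quality-control step
#' removes.
#'
#' Defaults reflect a cohort of ~1000 healthy volunteers with median
#' WUR 1.27 and median single-stimulus rating 2.85.
#'
#' @param n_participants Cohort size (default 1061).
#' @param log_wur_mean,log_wur_sd Parameters of the log-normal true WUR
#'   (defaults log(1.27) and 0.27).
#' @param single_rating_scale Median single-stimulus rating (default 2.85).
#' @param single_log_sd Log-scale SD of the per-participant single-rating
#'   level (default 0.9; ratings are highly skewed).
#' @param repeat_log_sd Log-scale SD of repeat-to-repeat rating noise.
#' @param n_repeats Repeats per stimulus kind (default 5).
#' @param outlier_fraction Probability of a near-zero-single outlier.
#' @param seed Integer seed.
#' @return A list with `ratings` (long data.frame: `participant_id`,
#'   `repeat`, `kind` in single/train, `rating`) and `truth`
#'   (`participant_id`, `true_wur`, `single_level`, `is_outlier`).
#' @export
sim_wur_cohort <- function(n_participants = 1061,
                           log_wur_mean = log(1.27),
                           log_wur_sd = 0.27,
                           single_rating_scale = 2.85,
                           single_log_sd = 0.9,
                           repeat_log_sd = 0.1,
                           n_repeats = 5,
                           outlier_fraction = 0.02,
                           seed = 1) {
  check_count(n_participants, "n_participants")
  check_count(n_repeats, "n_repeats")
  check_pos(single_rating_scale, "single_rating_scale")
  check_pos(log_wur_sd, "log_wur_sd", strict = FALSE)
  check_prob(outlier_fraction, "outlier_fraction")

  with_seed(seed, {
    ids <- sprintf("p%04d", seq_len(n_participants))
    true_wur <- exp(rnorm(n_participants, log_wur_mean, log_wur_sd))
    level <- single_rating_scale * exp(rnorm(n_participants, 0, single_log_sd))
    outlier <- runif(n_participants) < outlier_fraction
    rows <- vector("list", n_participants)
    for (j in seq_len(n_participants)) {
      noise_s <- exp(rnorm(n_repeats, 0, repeat_log_sd))
      noise_t <- exp(rnorm(n_repeats, 0, repeat_log_sd))
      single <- pmin(level[j] * noise_s, 100)
      train <- pmin(true_wur[j] * level[j] * noise_t, 100)
      if (outlier[j]) single <- rep(0.001, n_repeats)
      rows[[j]] <- data.frame(
        participant_id = ids[j],
        repeat_index = rep(seq_len(n_repeats), 2L),
        kind = rep(c("single", "train"), each = n_repeats),
        rating = c(single, train),
        stringsAsFactors = FALSE)
    }
    ratings <- do.call(rbind, rows)
    rownames(ratings) <- NULL
    truth <- data.frame(participant_id = ids, true_wur = true_wur,
                        single_level = level, is_outlier = outlier,
                        stringsAsFactors = FALSE)
    list(ratings = ratings, truth = truth)
  })
}
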