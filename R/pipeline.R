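#' Pipeline configuration
#'
#' Collects every threshold, convention and seed the full pipeline
#' uses, validating each. Unknown arguments are rejected so a typo in
#' a config cannot silently fall back to a default.
#'
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param snr_threshold Repeat-reliability cut-off (default 1).
#' @param tau_thresholds Named cut-offs (s) for decay-constant outlier
#'   removal (default `c(DH = 200, DRG = 100)`).
#' @param wur_max Wind-up-ratio exclusion cut-off (default 6).
#' @param a_end,c_end Latency band boundaries in ms (50, 250).
#' @param pd_end Post-discharge upper bound in ms; `NULL` means the
#'   inter-stimulus interval of each spike train.
#' @param n_cells,n_neurons,n_participants Synthetic cohort sizes for
#'   the simulate stage.
#' @param power_n,power_r2,power_alpha Parameters reported by the
#'   power stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            snr_threshold = 1,
                            tau_thresholds = c(DH = 200, DRG = 100),
                            wur_max = 6,
                            a_end = 50, c_end = 250, pd_end = NULL,
                            n_cells = 60, n_neurons = 8,
                            n_participants = 400,
                            power_n = 1000, power_r2 = c(0.03, 0.05),
                            power_alpha = 5.3e-8) {
  check_count(seed, "seed", min = 0L)
  check_pos(snr_threshold, "snr_threshold", strict = FALSE)
  if (any(tau_thresholds <= 0)) stopf("tau thresholds must be positive")
  check_pos(wur_max, "wur_max")
  check_pos(a_end, "a_end"); check_pos(c_end, "c_end")
  if (!is.null(pd_end)) check_pos(pd_end, "pd_end")
  structure(list(seed = as.integer(seed), snr_threshold = snr_threshold,
                 tau_thresholds = tau_thresholds, wur_max = wur_max,
                 a_end = a_end, c_end = c_end, pd_end = pd_end,
                 n_cells = check_count(n_cells, "n_cells"),
                 n_neurons = check_count(n_neurons, "n_neurons"),
                 n_participants = check_count(n_participants, "n_participants"),
                 power_n = check_count(power_n, "power_n"),
                 power_r2 = power_r2, power_alpha = power_alpha),
            class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a seeded synthetic bundle (in vitro traces, in vivo
#' recording, spike trains, ratings cohort), then runs every analysis
#' stage: reliability QC, calcium metrics, dF/F response calling and
#' animal-level summary, wind-up quantification, the WUR pipeline, and
#' the analytic power report. All outputs are plain CSV/JSON under
#' `out_dir`, together with a manifest recording every threshold and
#' convention used, so a run is fully reproducible from the manifest
#' alone. Identical configs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- config$seed

  ## --- simulate -----------------------------------------------------
  sim_tr <- sim_ratio_traces(n_cells = config$n_cells, seed = s + 1L)
  rec <- sim_dff_recording(seed = s + 2L)
  spk <- lapply(seq_len(config$n_neurons), function(j)
    sim_spike_table(neuron_id = sprintf("neuron_%02d", j), seed = s + 10L + j))
  wur_sim <- sim_wur_cohort(n_participants = config$n_participants,
                            seed = s + 3L)
  write_table_csv(sim_tr$traces, file.path(out_dir, "traces.csv"))
  write_table_csv(do.call(rbind, lapply(spk, `[[`, "spikes")),
                  file.path(out_dir, "spikes.csv"))
  write_table_csv(wur_sim$ratings, file.path(out_dir, "ratings.csv"))

  ## --- in vitro: QC then metrics ------------------------------------
  qc <- filter_reliable(sim_tr$traces, sim_tr$schedule,
                        threshold = config$snr_threshold)
  write_table_csv(qc$scores, file.path(out_dir, "qc_scores.csv"))
  metrics <- calcium_metrics(qc$kept, sim_tr$schedule)
  tau1 <- metrics$tau[metrics$pulse == 1 & !is.na(metrics$tau)]
  taus <- remove_tau_outliers(tau1, "DH", config$tau_thresholds)
  write_table_csv(metrics, file.path(out_dir, "calcium_metrics.csv"))

  ## --- in vivo: dF/F and response calls -----------------------------
  rec_bs <- background_subtract(rec)
  dff <- recording_dff(rec_bs)
  calls <- call_responses(dff, per_stimulus = FALSE)
  write_table_csv(calls, file.path(out_dir, "response_calls.csv"))
  animal_summary <- summarize_animals(calls)
  write_table_csv(animal_summary$animals, file.path(out_dir, "animal_means.csv"))

  ## --- wind-up ------------------------------------------------------
  isi <- spk[[1L]]$isi
  pd_end <- if (is.null(config$pd_end)) isi * 1000 else config$pd_end
  bands <- latency_bands(pd_end = pd_end, a_end = config$a_end,
                         c_end = config$c_end)
  wu <- do.call(rbind, lapply(spk, function(x) {
    r <- windup_result(x$spikes, bands = bands, isi = x$isi)
    data.frame(neuron_id = x$spikes$neuron_id[1L], input = r$input,
               windup = r$windup, total = r$total,
               a_spikes = r$band_totals[["A"]], c_spikes = r$band_totals[["C"]],
               pd_spikes = r$band_totals[["PD"]],
               rate_constant = r$rate_constant, plateau = r$plateau,
               stringsAsFactors = FALSE)
  }))
  write_table_csv(wu, file.path(out_dir, "windup.csv"))

  ## --- psychophysics ------------------------------------------------
  wt <- wur_table(wur_sim$ratings)
  wq <- qc_exclude(wt, wur_max = config$wur_max)
  wsum <- summarize_wur(wq$kept)
  write_table_csv(wt, file.path(out_dir, "wur.csv"))

  ## --- power --------------------------------------------------------
  power <- data.frame(n = config$power_n, r2 = config$power_r2,
                      alpha = config$power_alpha,
                      power = vapply(config$power_r2, function(r2)
                        analytic_power(config$power_n, r2,
                                       config$power_alpha), numeric(1)))
  write_table_csv(power, file.path(out_dir, "power.csv"))

  ## --- manifest -----------------------------------------------------
  manifest <- list(
    package = "windupr",
    version = as.character(utils::packageVersion("windupr")),
    seed = config$seed,
    conventions = list(
      snr_threshold = config$snr_threshold,
      snr_pass_rule = "strictly greater than threshold",
      variance_estimator = "population (divide by N), pooled total variance",
      tau_thresholds_s = as.list(config$tau_thresholds),
      baseline_window_s = 15,
      peak_mode = "at_fixed_times",
      auc_reference = "cohort mean of start baselines",
      dff_f0_window = "full pre-stimulus baseline",
      response_threshold = "1.2*mean(B_E) + 2*sd(B_E), strict crossing",
      latency_bands_ms = list(A = c(0, config$a_end),
                              C = c(config$a_end, config$c_end),
                              PD = c(config$c_end, pd_end)),
      band_interval_rule = "half-open, lower-inclusive",
      pd_end_ms = pd_end,
      wur_method = "ratio_of_means",
      wur_max = config$wur_max,
      iqr_quantile_type = 7),
    cohort_sizes = list(n_cells = config$n_cells,
                        n_neurons = config$n_neurons,
                        n_participants = config$n_participants),
    qc_summary = qc$summary,
    tau_removed = length(taus$removed),
    wur_summary = wsum,
    n_wur_excluded = nrow(wq$excluded))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(list(qc = qc, metrics = metrics, calls = calls,
                 animal_summary = animal_summary, windup = wu,
                 wur = wq, wur_summary = wsum, power = power,
                 manifest = manifest))
}
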