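test_that("ratio-trace generator matches its noiseless closed form", {
  sim <- sim_ratio_traces(n_cells = 3, responder_fraction = 1, noise_sd = 0,
                          peak_amplitude_mean = 1, peak_amplitude_sd = 0,
                          tau_mean = 20, tau_sd = 0, baseline_level = 0.8,
                          dying_fraction = 0, seed = 7)
  tr <- sim$traces[sim$traces$trace_id == "cell_001", ]
  # 30 s after the first peak (t = 90): baseline + A * exp(-30/20),
  # plus the negligible tail checked exactly via the model
  v120 <- tr$value[tr$t_s == 120]
  expect_equal(v120, 0.8 + 1 * exp(-30 / 20), tolerance = 1e-12)
  # peak samples sit at baseline + amplitude (earlier pulses decayed < 5%)
  expect_equal(tr$value[tr$t_s == 90], 0.8 + 1, tolerance = 1e-12)
  expect_lt(abs(tr$value[tr$t_s == 180] - 1.8), 0.06)
})

test_that("trace classes follow the requested fractions and shapes", {
  none <- sim_ratio_traces(n_cells = 10, responder_fraction = 0,
                           dying_fraction = 0, seed = 1)
  expect_true(all(none$truth$class == "non_responder"))

  dying <- sim_ratio_traces(n_cells = 2, responder_fraction = 0,
                            dying_fraction = 1, noise_sd = 0,
                            peak_amplitude_sd = 0, seed = 2)
  tr <- dying$traces[dying$traces$trace_id == "cell_001", ]
  # elevated and flat after the first peak: no later peaks
  late <- tr$value[tr$t_s >= 90]
  expect_true(all(abs(late - late[1]) < 1e-12))
  expect_gt(late[1], 0.8)
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- sim_ratio_traces(n_cells = 5, seed = 11)
  b <- sim_ratio_traces(n_cells = 5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$traces$value,
                         sim_ratio_traces(n_cells = 5, seed = 12)$traces$value))

  expect_identical(sim_dff_recording(seed = 4), sim_dff_recording(seed = 4))
  expect_identical(sim_spike_table(seed = 5), sim_spike_table(seed = 5))
  expect_identical(sim_wur_cohort(n_participants = 20, seed = 6),
                   sim_wur_cohort(n_participants = 20, seed = 6))
})

test_that("dff transients summate at 1 Hz when decay outlasts the interval", {
  rec <- sim_dff_recording(freq = 1, n_rois = 1, responder_fraction = 1,
                           amplitude = 0.3, amplitude_sd = 0, decay_s = 2,
                           noise_sd = 0, seed = 1)
  tr <- rec$traces[, 1]
  t16 <- rec$stim_times[16]; t1 <- rec$stim_times[1]
  max_after_16 <- max(tr[rec$time >= t16 & rec$time < t16 + 1])
  max_after_1 <- max(tr[rec$time >= t1 & rec$time < t1 + 1])
  expect_gt(max_after_16, max_after_1)
})

test_that("spike generator follows the saturating growth law", {
  flat <- sim_spike_table(first_pulse_count = 12, plateau = 50,
                          rate_constant = 0, count_noise = 0, seed = 1)
  expect_true(all(flat$counts == 12L))

  st <- sim_spike_table(first_pulse_count = 10, plateau = 50,
                        rate_constant = 0.5, count_noise = 0, seed = 1)
  expect_equal(st$expected[3], 10 + 40 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(st$counts[3], as.integer(round(10 + 40 * (1 - exp(-1)))))

  a_only <- sim_spike_table(band_fractions = c(1, 0, 0), seed = 2)
  expect_true(all(a_only$spikes$latency_ms < 50))

  expect_error(sim_spike_table(plateau = -1), "plateau")
  expect_error(sim_ratio_traces(responder_fraction = 1.4), "probability")
  expect_error(sim_dff_recording(freq = 0), "freq")
})

test_that("wur cohort reproduces its outlier fraction and degenerate case", {
  unit <- sim_wur_cohort(n_participants = 10, log_wur_mean = 0,
                         log_wur_sd = 0, outlier_fraction = 0, seed = 3)
  expect_true(all(abs(unit$truth$true_wur - 1) < 1e-12))

  big <- sim_wur_cohort(n_participants = 1000, outlier_fraction = 0.1,
                        seed = 9)
  wt <- wur_table(big$ratings)
  frac <- mean(wt$wur > 6, na.rm = TRUE)
  # binomial error around 0.1 at n = 1000: 3 SE ~ 0.028
  expect_lt(abs(frac - 0.1), 0.03)
})
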