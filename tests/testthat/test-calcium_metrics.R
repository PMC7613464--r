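sch <- pulse_schedule()

test_that("baselines are pre-pulse window means", {
  expect_equal(unname(extract_baselines(rep(0.8, 340), sch)), rep(0.8, 4))
  expect_error(extract_baselines(rep(0.8, 340), sch, window = 200),
               "window")

  # noiseless fast-decaying responder: inter-pulse baselines near truth
  sim <- sim_ratio_traces(n_cells = 1, responder_fraction = 1, noise_sd = 0,
                          tau_mean = 10, tau_sd = 0, dying_fraction = 0,
                          baseline_level = 0.8, seed = 1)
  b <- extract_baselines(sim$traces, sch)
  expect_true(all(abs(b - 0.8) / 0.8 < 0.01))
})

test_that("peak extraction reads fixed times and window maxima", {
  expect_equal(peak_times(sch), c(90, 180, 270))
  v <- rep(0.5, 340)
  v[91] <- 2; v[181] <- 3; v[271] <- 4   # samples at t = 90, 180, 270
  expect_equal(unname(extract_peaks(v, sch)), c(2, 3, 4))

  # overshoot at 85 s: window_max dominates the fixed-time read
  v[86] <- 5
  expect_gte(extract_peaks(v, sch, mode = "window_max")[[1]],
             extract_peaks(v, sch)[[1]])

  # noiseless ramp-to-peak responder: both modes agree
  sim <- sim_ratio_traces(n_cells = 1, responder_fraction = 1, noise_sd = 0,
                          dying_fraction = 0, seed = 2)
  expect_equal(extract_peaks(sim$traces, sch),
               extract_peaks(sim$traces, sch, mode = "window_max"))
})

test_that("translation equivariance of peaks and baselines", {
  sim <- sim_ratio_traces(n_cells = 1, seed = 3)
  v <- sim$traces$value
  expect_equal(extract_peaks(v + 2.5, sch), extract_peaks(v, sch) + 2.5)
  expect_equal(extract_baselines(v + 2.5, sch),
               extract_baselines(v, sch) + 2.5)
})

test_that("AUC follows the discrete trapezoid about the reference", {
  # trace identical to the reference integrates to zero
  expect_equal(unname(compute_auc(rep(0.7, 340), sch, reference = 0.7)),
               c(0, 0, 0))

  # rectangular pulse of height 1 for 30 s: hand trapezoid gives 29.5
  # per epoch (half-sample corrections at both edges)
  v <- rep(0, 340)
  for (on in sch$pulse_onsets) v[(on + 1):(on + 30)] <- 1
  hand <- function(col) sum((col[-1] + col[-length(col)]) / 2)
  ep <- segment_epochs(v, sch)
  expect_equal(unname(compute_auc(v, sch, reference = 0)),
               unname(apply(ep, 2, hand)))
  expect_equal(unname(compute_auc(v, sch, reference = 0))[1], 29.5)

  # shifting trace and reference together leaves AUC unchanged
  expect_equal(compute_auc(v + 3, sch, reference = 3),
               compute_auc(v, sch, reference = 0))

  # additivity about a common reference
  sim <- sim_ratio_traces(n_cells = 2, responder_fraction = 1,
                          dying_fraction = 0, seed = 4)
  v1 <- sim$traces$value[sim$traces$trace_id == "cell_001"]
  v2 <- sim$traces$value[sim$traces$trace_id == "cell_002"]
  expect_equal(compute_auc(v1 + v2 - 0.5, sch, reference = 0.5),
               compute_auc(v1, sch, 0.5) + compute_auc(v2, sch, 0.5))
})

test_that("tau fit recovers noiseless exponentials exactly", {
  # build a trace whose first decay segment is exactly 2 e^(-t/12)
  v <- rep(0, 340)
  tt <- 0:60
  v[91:151] <- 2 * exp(-tt / 12)
  ft <- fit_tau(v, sch, pulse_index = 1)
  expect_true(ft$converged)
  expect_equal(ft$tau, 12, tolerance = 1e-6)
  expect_equal(ft$amplitude, 2, tolerance = 1e-6)
  # after one time constant the fitted curve retains e^-1 of A
  expect_equal(ft$amplitude * exp(-12 / ft$tau) / ft$amplitude,
               exp(-1), tolerance = 1e-9)
})

test_that("tau fit fails gracefully on degenerate segments", {
  v <- seq(0, 3.39, by = 0.01)  # monotonically increasing everywhere
  ft <- fit_tau(v, sch, pulse_index = 1)
  expect_false(ft$converged)
  expect_true(is.na(ft$tau))
})

test_that("tau recovery stays accurate under noise across a tau grid", {
  errs <- c()
  for (tau in c(5, 10, 20, 40)) {
    sim <- sim_ratio_traces(n_cells = 6, responder_fraction = 1,
                            noise_sd = 0.05, tau_mean = tau, tau_sd = 0,
                            peak_amplitude_mean = 1, peak_amplitude_sd = 0,
                            dying_fraction = 0, seed = 100 + tau)
    for (id in unique(sim$traces$trace_id)) {
      ft <- fit_tau(sim$traces[sim$traces$trace_id == id, ], sch, 1)
      errs <- c(errs, abs(ft$tau - tau) / tau)
    }
  }
  expect_lt(median(errs), 0.05)
})

test_that("tau outlier rule applies per cohort", {
  out <- remove_tau_outliers(c(10, 150, 250), "DH")
  expect_equal(out$kept, c(10, 150))
  expect_equal(out$removed, 250)
  expect_equal(remove_tau_outliers(c(99, 101), "DRG")$kept, 99)
  expect_equal(remove_tau_outliers(numeric(0), "DH")$kept, numeric(0))
  expect_error(remove_tau_outliers(1, "spleen"), "cohort")
})

test_that("cohort metrics wrapper produces one row per cell and pulse", {
  sim <- sim_ratio_traces(n_cells = 4, responder_fraction = 1,
                          dying_fraction = 0, noise_sd = 0.01, seed = 6)
  m <- calcium_metrics(sim$traces, sch)
  expect_equal(nrow(m), 4L * 3L)
  expect_true(all(m$peak > m$baseline_start))
  expect_true(all(m$tau[m$tau_converged] > 0))
  # AUC reference defaults to the cohort mean of start baselines
  expect_equal(unique(m$auc_reference),
               mean(m$baseline_start[m$pulse == 1]))
})
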