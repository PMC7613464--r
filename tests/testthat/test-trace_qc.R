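test_that("segmentation aligns epochs to pulse onsets", {
  sch <- pulse_schedule()
  v <- seq_len(340) - 1  # value equals time in seconds
  ep <- segment_epochs(v, sch)
  expect_equal(dim(ep), c(90L, 3L))
  expect_equal(ep[1, ], c(60, 150, 240))
  expect_equal(ep[90, ], c(149, 239, 329))

  sch2 <- pulse_schedule(pulse_onsets = c(0, 10, 20), pulse_duration = 5,
                         epoch_length = 10, recording_length = 30)
  ep2 <- segment_epochs(seq_len(30) - 1, sch2)
  expect_equal(ep2[, 1], 0:9)
  expect_equal(ep2[, 3], 20:29)

  expect_error(segment_epochs(numeric(200), sch), "too short")
  expect_error(segment_epochs(data.frame(t_s = c(0, 1, 3), value = 1:3),
                              pulse_schedule(pulse_onsets = 0,
                                             pulse_duration = 1,
                                             epoch_length = 2,
                                             recording_length = 3)),
               "uniformly")
})

test_that("schedule invariants are enforced", {
  expect_error(pulse_schedule(pulse_onsets = c(60, 50)), "increasing")
  expect_error(pulse_schedule(pulse_onsets = c(0, 50)), "overlap")
  expect_error(pulse_schedule(recording_length = 300), "fit")
})

test_that("reliability score matches the brute-force decomposition", {
  set.seed(42)
  for (rep in 1:20) {
    ep <- matrix(rnorm(15), nrow = 5, ncol = 3)
    sc <- reliability_snr(ep)
    expect_equal(sc$snr, brute_snr(ep), tolerance = 1e-12)
    expect_gte(sc$explainable_variance, 0)
    expect_lte(sc$explainable_variance, sc$total_variance + 1e-15)
  }
})

test_that("reliability edge conventions: identical repeats, boundary, constants", {
  sig <- sin(seq_len(90) / 7)
  expect_equal(reliability_snr(cbind(sig, sig, sig))$snr, Inf)
  expect_equal(reliability_snr(matrix(5, 90, 3))$snr, 0)

  # explainable exactly half of total => snr = 1. Repeats m + d and m - d
  # with cov(m, d) = 0 and var(m) = var(d) give that split exactly.
  m <- rep(c(1, -1), 45)          # var 1, mean 0
  d <- rep(c(1, 1, -1, -1), length.out = 90)
  d <- d - mean(d); d <- d / sqrt(mean(d^2))  # var 1
  stopifnot(abs(mean(m * d)) < 1e-12)
  sc <- reliability_snr(cbind(m + d, m - d))
  expect_equal(sc$snr, 1, tolerance = 1e-12)
})

test_that("snr is invariant under affine changes of the trace", {
  set.seed(1)
  ep <- matrix(rnorm(270), 90, 3) + sin(seq_len(90) / 5)
  s0 <- reliability_snr(ep)$snr
  expect_equal(reliability_snr(ep + 3.7)$snr, s0, tolerance = 1e-9)
  expect_equal(reliability_snr(ep * 0.01)$snr, s0, tolerance = 1e-9)
  expect_equal(reliability_snr(ep * 5 - 2)$snr, s0, tolerance = 1e-9)
})

test_that("pure-noise cells score below 1 and are rejected", {
  set.seed(7)
  snrs <- replicate(500, reliability_snr(matrix(rnorm(270), 90, 3))$snr)
  expect_lt(mean(snrs), 1)          # null mean sits near 0.5
  expect_lt(mean(snrs > 1), 0.01)   # essentially all rejected at threshold 1
})

test_that("reliability filter recovers the responder fraction of a cohort", {
  sim <- sim_ratio_traces(n_cells = 300, responder_fraction = 0.73,
                          noise_sd = 0.05, dying_fraction = 0.07, seed = 21)
  qc <- filter_reliable(sim$traces, sim$schedule, threshold = 1)
  kept_frac <- sum(qc$summary$n_kept) / sum(qc$summary$n_in)
  true_frac <- mean(sim$truth$class == "responder")
  expect_lt(abs(kept_frac - true_frac), 0.03)
  # kept cells are (essentially) the true responders
  kept_ids <- qc$scores$trace_id[qc$scores$kept]
  resp_ids <- sim$truth$trace_id[sim$truth$class == "responder"]
  expect_gt(length(intersect(kept_ids, resp_ids)) / length(resp_ids), 0.97)
})

test_that("noiseless responders all pass and summary counts add up", {
  sim <- sim_ratio_traces(n_cells = 12, responder_fraction = 1, noise_sd = 0,
                          dying_fraction = 0, seed = 5)
  qc <- filter_reliable(sim$traces, sim$schedule)
  expect_equal(qc$summary$n_kept, qc$summary$n_in)
  expect_equal(nrow(qc$scores), 12L)
  expect_equal(length(unique(qc$kept$trace_id)) +
                 length(unique(qc$discarded$trace_id)), 12L)
})
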