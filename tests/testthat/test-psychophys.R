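test_that("wind-up ratio arithmetic and exclusion on zero singles", {
  r <- compute_wur(rep(5, 5), rep(5, 5))
  expect_equal(r$wur, 1)

  # plausible cohort magnitudes: mean single 2.85, mean train 4.00
  r2 <- compute_wur(rep(2.85, 5), rep(4, 5))
  expect_equal(r2$wur, 4 / 2.85, tolerance = 1e-12)

  z <- compute_wur(rep(0, 5), rep(4, 5))
  expect_true(z$excluded)
  expect_true(is.na(z$wur))

  # scale invariance
  s <- c(1, 2, 3, 2, 2); tr <- c(3, 4, 2, 5, 4)
  expect_equal(compute_wur(7 * s / 7, 7 * tr / 7)$wur,
               compute_wur(s, tr)$wur)
  expect_error(compute_wur(c(-1, 1, 1, 1, 1), tr), "0, 100")
})

test_that("QC exclusion is strict at the cut-off and partitions records", {
  rec <- data.frame(participant_id = c("a", "b", "c"),
                    mean_single = 1, mean_train = 1,
                    wur = c(6.0, 6.01, 2), excluded = FALSE,
                    reason = NA_character_)
  q <- qc_exclude(rec)
  expect_equal(q$kept$participant_id, c("a", "c"))     # 6.0 kept
  expect_equal(q$excluded$participant_id, "b")
  expect_equal(nrow(q$kept) + nrow(q$excluded), nrow(rec))
})

test_that("cohort summary uses type-7 quantiles", {
  rec <- data.frame(participant_id = letters[1:3], mean_single = c(1, 2, 3),
                    mean_train = c(2, 4, 6), wur = c(1, 2, 3),
                    excluded = FALSE, reason = NA_character_)
  s <- summarize_wur(rec)
  expect_equal(s$wur$median, 2)
  expect_equal(s$wur$iqr, unname(quantile(1:3, .75) - quantile(1:3, .25)))
  const <- rec; const$wur <- 2
  expect_equal(summarize_wur(const)$wur$iqr, 0)
})

test_that("synthetic cohort pipeline recovers median WUR and outlier rate", {
  sim <- sim_wur_cohort(seed = 31)  # defaults: n = 1061, median 1.27, 2% outliers
  wt <- wur_table(sim$ratings)
  q <- qc_exclude(wt)
  s <- summarize_wur(q$kept)
  expect_lt(abs(s$wur$median - 1.27), 0.05)
  excl_frac <- nrow(q$excluded) / nrow(wt)
  expect_lt(abs(excl_frac - 0.02), 0.015)
  # true outliers are exactly the excluded ones at these magnitudes
  expect_true(all(sim$truth$participant_id[sim$truth$is_outlier] %in%
                    q$excluded$participant_id))
})

test_that("Lilliefors statistic matches brute force and reference code", {
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(50) + rexp(50)
    D <- lilliefors_statistic(x)$statistic
    expect_equal(D, brute_lilliefors(x), tolerance = 1e-6)
  }
  skip_if_not_installed("nortest")
  for (rep in 1:5) {
    x <- rexp(80)
    expect_equal(lilliefors_statistic(x)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("Lilliefors edge properties and Monte-Carlo power", {
  n <- 100
  x <- qnorm((seq_len(n) - 0.5) / n)
  expect_lt(lilliefors_statistic(x)$statistic, 2 / n)  # near-perfect grid

  # duplication leaves D unchanged up to the n-1 SD estimator
  y <- rnorm(40)
  expect_equal(lilliefors_statistic(c(y, y))$statistic,
               lilliefors_statistic(y)$statistic, tolerance = 5e-3)

  u <- with(list(), {set.seed(5); runif(200)})
  p <- lilliefors_statistic(u, mc_reps = 400, seed = 2)$p_value
  expect_lt(p, 0.01)
})

test_that("Box-Cox transform family and affine edge case", {
  x <- c(0.5, 1, 2, 4)
  expect_equal(boxcox_transform(x, 0), log(x))
  expect_equal(boxcox_transform(x, 1), x - 1)
  expect_equal(boxcox_transform(x, 2), (x^2 - 1) / 2)
  expect_error(boxcox_transform(c(1, -1), 1), "positive")

  # lambda = 1 is affine: identical Lilliefors statistic to the raw data
  set.seed(3)
  z <- rexp(200)
  expect_equal(lilliefors_statistic(boxcox_transform(z, 1))$statistic,
               lilliefors_statistic(z)$statistic, tolerance = 1e-12)

  skip_if_not_installed("car")
  expect_equal(boxcox_transform(x, -1.1), unname(car::bcPower(x, -1.1)),
               tolerance = 1e-12)
})

test_that("Box-Cox tuning lands on the normalising parameter", {
  ln <- with(list(), {set.seed(41); exp(rnorm(2000))})
  expect_lt(abs(boxcox_tune(ln)$lambda - 0), 0.2)

  # mean 5, sd 1: far enough from zero to stay positive, close enough
  # that the transform family separates and lambda ~ 1 is identified
  nm <- with(list(), {set.seed(42); rnorm(2000, mean = 5, sd = 1)})
  expect_lte(abs(boxcox_tune(nm)$lambda - 1), 0.3)

  # scale equivariance: rescaling the input leaves the optimum unchanged
  expect_equal(boxcox_tune(ln)$lambda, boxcox_tune(100 * ln)$lambda)
})
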