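# Brute-force variance decomposition for the reliability score:
# explicit summation, independent of reliability_snr()'s vectorised path.
brute_snr <- function(epochs) {
  n <- nrow(epochs); r <- ncol(epochs)
  grand <- sum(epochs) / (n * r)
  m <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in seq_len(r)) acc <- acc + epochs[t, j]
    m[t] <- acc / r
  }
  mbar <- sum(m) / n
  expl <- 0
  for (t in seq_len(n)) expl <- expl + (m[t] - mbar)^2
  expl <- expl / n
  tot <- 0
  for (t in seq_len(n)) for (j in seq_len(r))
    tot <- tot + (epochs[t, j] - grand)^2
  tot <- tot / (n * r)
  if (tot == 0) return(0)
  if (tot - expl <= 0) return(Inf)
  expl / (tot - expl)
}

# Brute-force input/wind-up straight from a raw spike table.
brute_input_windup <- function(spikes, n_stimuli = 16) {
  first <- sum(spikes$stimulus_index == 1)
  total <- nrow(spikes)
  list(input = first * n_stimuli, windup = total - first * n_stimuli)
}

# Grid-based sup-distance between the ECDF and the fitted normal CDF.
brute_lilliefors <- function(x, grid_n = 20000) {
  Fe <- ecdf(x)
  g <- seq(min(x) - 1, max(x) + 1, length.out = grid_n)
  # evaluate just before and after each data point as well
  g <- sort(c(g, x, x - 1e-9))
  max(abs(Fe(g) - pnorm((g - mean(x)) / sd(x))))
}

growth_law <- function(i, y0, plateau, k) y0 + (plateau - y0) * (1 - exp(-k * (i - 1)))
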