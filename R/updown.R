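#' Default mouse von Frey filament ladder
#'
#' A commonly used graded set of von Frey filaments for mouse hind-paw
#' testing, in grams. The middle filament (0.6 g) is the conventional
#' starting stimulus.
#'
#' @return Numeric vector of forces (g), increasing.
#' @export
von_frey_ladder <- function() c(0.04, 0.07, 0.16, 0.4, 0.6, 1, 1.4, 2)

#' 50% withdrawal threshold from an up-down testing sequence
#'
#' Implements the Dixon up-down estimator for the 50% withdrawal
#' threshold from a sequence of von Frey presentations: a withdrawal
#' lowers the next filament, no response raises it, and the session
#' ends a fixed number of trials after the first change of response.
#' The estimate follows the Dixon convention
#' \deqn{T_{50} = 10^{X_f + k\,\delta}}
#' where \eqn{X_f} is the log10 force of the final filament,
#' \eqn{\delta} the mean log10 spacing of the ladder, and `k` the
#' pattern constant for the observed response sequence.
#'
#' The pattern constant is obtained from the statistical model that
#' underlies the tabulated constants - a normal psychometric function
#' on the log10-force axis with spread equal to the ladder spacing -
#' by maximising the sequence likelihood over the threshold location;
#' `k` is the resulting offset from the final filament in units of
#' \eqn{\delta}. Sequences that run off the end of the ladder return
#' the ladder extreme: all-negative sequences at the stiffest filament
#' give the ceiling, all-withdrawal sequences at the lightest give the
#' floor.
#'
#' @param forces Numeric vector of presented forces in grams, in trial
#'   order; every force must be a ladder member.
#' @param responses Logical vector, `TRUE` = withdrawal.
#' @param ladder Available filament forces in grams (default
#'   [von_frey_ladder()]).
#' @return List with `threshold` (g), `k`, `x_final` (log10 g),
#'   `delta`, `boundary` (`"none"`, `"ceiling"` or `"floor"`).
#' @examples
#' # no response up to the stiffest filament: ceiling
#' updown_threshold(c(0.6, 1, 1.4, 2), rep(FALSE, 4))$threshold
#' @export
updown_threshold <- function(forces, responses, ladder = von_frey_ladder()) {
  forces <- as.numeric(forces)
  responses <- as.logical(responses)
  if (length(forces) != length(responses) || length(forces) < 1L)
    stopf("`forces` and `responses` must be non-empty and equal length")
  if (any(is.na(responses))) stopf("responses must be TRUE/FALSE")
  ladder <- sort(as.numeric(ladder))
  idx <- vapply(forces, function(f) {
    i <- which(abs(ladder - f) < 1e-9)
    if (length(i) != 1L) stopf("force %g g is not a ladder filament", f)
    i
  }, integer(1))
  # transition validity: withdrawal must not be followed by a stiffer
  # filament, no-response not by a lighter one (repeats allowed at the
  # ladder extremes only)
  n <- length(idx)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- idx[i + 1L] - idx[i]
      if (responses[i] && d > 0)
        stopf("trial %d: force increased after a withdrawal", i + 1L)
      if (!responses[i] && d < 0)
        stopf("trial %d: force decreased after no response", i + 1L)
      if (d == 0 && !(idx[i] %in% c(1L, length(ladder))))
        stopf("trial %d: force repeated away from the ladder boundary", i + 1L)
    }
  }
  lx <- log10(ladder)
  delta <- mean(diff(lx))
  x <- lx[idx]
  x_f <- x[n]
  if (!any(responses) && idx[n] == length(ladder))
    return(list(threshold = max(ladder), k = 0, x_final = x_f,
                delta = delta, boundary = "ceiling"))
  if (all(responses) && idx[n] == 1L)
    return(list(threshold = min(ladder), k = 0, x_final = x_f,
                delta = delta, boundary = "floor"))
  # normal psychometric with spread = ladder spacing; MLE of location
  nll <- function(mu) {
    p <- pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(responses, log(p), log(1 - p)))
  }
  opt <- optimize(nll, interval = c(min(lx) - 2 * delta, max(lx) + 2 * delta))
  mu <- opt$minimum
  list(threshold = 10^mu, k = (mu - x_f) / delta, x_final = x_f,
       delta = delta, boundary = "none")
}

#' Run an up-down testing session against a response rule
#'
#' Drives the up-down procedure: starting from `start`, each
#' withdrawal steps one filament down, each non-response one filament
#' up, and testing stops `n_after_change` trials after the first
#' change of response (or at `max_trials`, or after repeated trials at
#' a ladder extreme). Useful for simulating sessions against a known
#' psychometric rule.
#'
#' @param respond Function of one force (g) returning `TRUE` for
#'   withdrawal.
#' @param ladder Filament forces (g).
#' @param start Starting force (default the ladder's middle filament).
#' @param n_after_change Trials after the first response change
#'   (default 4).
#' @param max_trials Hard cap on trials (default 20).
#' @return List with `forces` and `responses`, suitable for
#'   [updown_threshold()].
#' @export
run_updown <- function(respond, ladder = von_frey_ladder(), start = NULL,
                       n_after_change = 4, max_trials = 20) {
  ladder <- sort(as.numeric(ladder))
  if (is.null(start)) start <- ladder[ceiling(length(ladder) / 2)]
  i <- which(abs(ladder - start) < 1e-9)
  if (length(i) != 1L) stopf("`start` must be a ladder filament")
  forces <- numeric(0); responses <- logical(0)
  changed_at <- NA_integer_
  boundary_run <- 0L
  for (trial in seq_len(max_trials)) {
    f <- ladder[i]
    r <- isTRUE(respond(f))
    forces <- c(forces, f); responses <- c(responses, r)
    if (is.na(changed_at) && trial > 1L &&
        r != responses[trial - 1L]) changed_at <- trial
    if (!is.na(changed_at) && trial - changed_at + 1L >= n_after_change) break
    j <- i + if (r) -1L else 1L
    if (j < 1L || j > length(ladder)) {
      boundary_run <- boundary_run + 1L
      if (boundary_run >= 3L) break   # ran off the ladder
      j <- i
    } else boundary_run <- 0L
    i <- j
  }
  list(forces = forces, responses = responses)
}
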