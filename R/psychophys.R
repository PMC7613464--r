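#' Wind-up ratio of one participant
#'
#' The wind-up ratio (WUR) is the psychophysical measure of temporal
#' summation: the mean pain rating for the trains of stimuli divided by
#' the mean rating for the single stimulus. By default the ratio of the
#' two five-repeat means is taken (`"ratio_of_means"`); the mean of the
#' five per-repeat ratios is available as an alternative.
#'
#' @param single_ratings Numeric ratings (0-100) for the single
#'   stimulus, one per repeat.
#' @param train_ratings Numeric ratings (0-100), each already the mean
#'   over one 10-stimulus train, one per repeat.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return List with `wur` (`NA` when the single-stimulus mean is 0,
#'   in which case `excluded = TRUE` with a reason), `mean_single`,
#'   `mean_train`, `excluded`, `reason`.
#' @examples
#' compute_wur(c(2, 3, 3, 3, 3.25), c(4, 4, 4, 4, 4))
#' @export
compute_wur <- function(single_ratings, train_ratings,
                        method = c("ratio_of_means", "mean_of_ratios")) {
  method <- match.arg(method)
  s <- as.numeric(single_ratings); tr <- as.numeric(train_ratings)
  if (any(!is.finite(s)) || any(!is.finite(tr)))
    stopf("ratings must be finite")
  if (any(s < 0 | s > 100) || any(tr < 0 | tr > 100))
    stopf("ratings must lie in [0, 100]")
  ms <- mean(s); mt <- mean(tr)
  if (ms <= 0)
    return(list(wur = NA_real_, mean_single = ms, mean_train = mt,
                excluded = TRUE, reason = "zero single-stimulus rating"))
  wur <- if (method == "ratio_of_means") mt / ms else {
    if (any(s <= 0)) return(list(wur = NA_real_, mean_single = ms,
                                 mean_train = mt, excluded = TRUE,
                                 reason = "zero single-stimulus rating"))
    mean(tr / s)
  }
  list(wur = wur, mean_single = ms, mean_train = mt,
       excluded = FALSE, reason = NA_character_)
}

#' Per-participant WUR table from long-format ratings
#'
#' @param ratings Long data.frame with columns `participant_id`,
#'   `kind` (`"single"`/`"train"`), `rating` (a repeat index column is
#'   allowed and ignored).
#' @param method Passed to [compute_wur()].
#' @return data.frame: `participant_id`, `mean_single`, `mean_train`,
#'   `wur`, `excluded`, `reason`.
#' @export
wur_table <- function(ratings, method = "ratio_of_means") {
  need <- c("participant_id", "kind", "rating")
  if (!all(need %in% names(ratings)))
    stopf("`ratings` must have columns %s", paste(need, collapse = ", "))
  rows <- lapply(split(ratings, ratings$participant_id), function(s) {
    r <- compute_wur(s$rating[s$kind == "single"],
                     s$rating[s$kind == "train"], method = method)
    data.frame(participant_id = s$participant_id[1L],
               mean_single = r$mean_single, mean_train = r$mean_train,
               wur = r$wur, excluded = r$excluded, reason = r$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclude phenotypic WUR outliers
#'
#' Removes records whose WUR exceeds `wur_max` (default 6; strictly
#' greater than). Such values arise primarily from very small single
#' stimulus ratings (e.g. 0.001) and are treated as phenotypic
#' outliers. Records already flagged (undefined WUR) are also
#' excluded. Kept and excluded partition the input.
#'
#' @param records data.frame as from [wur_table()].
#' @param wur_max Exclusion cut-off (default 6).
#' @return List with `kept` and `excluded` data.frames; `excluded`
#'   carries a `reason`.
#' @export
qc_exclude <- function(records, wur_max = 6) {
  check_pos(wur_max, "wur_max")
  stopifnot(is.data.frame(records), "wur" %in% names(records))
  out <- is.na(records$wur) | records$wur > wur_max
  excluded <- records[out, , drop = FALSE]
  excluded$reason <- ifelse(is.na(excluded$wur), excluded$reason,
                            sprintf("WUR > %g", wur_max))
  list(kept = records[!out, , drop = FALSE], excluded = excluded)
}

#' Cohort summary of wind-up ratios
#'
#' Median and interquartile range (Q3 - Q1, linear-interpolation
#' type-7 quantiles) of the WUR and of the per-kind rating means.
#'
#' @param records data.frame of kept records (from [qc_exclude()]).
#' @return List with `n`, `wur` (median, iqr), `single` and `train`
#'   (median, iqr of the per-participant means).
#' @export
summarize_wur <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  mi <- function(x) list(median = median(x), iqr = unname(
    quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)))
  list(n = nrow(records),
       wur = mi(records$wur),
       single = mi(records$mean_single),
       train = mi(records$mean_train))
}

#' Box-Cox power transform
#'
#' The unscaled Box-Cox family \eqn{(x^\lambda - 1)/\lambda} for
#' \eqn{\lambda \neq 0} and \eqn{\ln x} at \eqn{\lambda = 0}. Values
#' must be strictly positive.
#'
#' @param x Strictly positive numeric vector.
#' @param lambda Transform parameter.
#' @return Transformed numeric vector.
#' @export
boxcox_transform <- function(x, lambda) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("Box-Cox requires strictly positive finite values")
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Lilliefors statistic for composite normality
#'
#' The Kolmogorov-Smirnov distance between the empirical CDF of the
#' data and the normal distribution with mean and SD estimated from the
#' same data (sample SD),
#' \deqn{D = \sup_x |F_n(x) - \Phi((x - \bar x)/s)|.}
#' Because the null parameters are estimated, the usual KS null
#' distribution does not apply; an optional Monte-Carlo p-value is
#' computed by simulating standard-normal samples of the same size and
#' repeating the estimation step on each.
#'
#' @param x Numeric vector, length >= 5.
#' @param mc_reps Number of Monte-Carlo null replicates (0 = no p-value).
#' @param seed Seed for the Monte-Carlo draw.
#' @return List with `statistic` (D) and, when `mc_reps > 0`,
#'   `p_value` and `mc_reps`.
#' @export
lilliefors_statistic <- function(x, mc_reps = 0, seed = 1) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 5L) stopf("need at least 5 observations")
  if (any(!is.finite(x))) stopf("values must be finite")
  D <- lillie_D(x)
  out <- list(statistic = D)
  if (mc_reps > 0) {
    check_count(mc_reps, "mc_reps")
    null_D <- with_seed(seed, vapply(seq_len(mc_reps), function(r)
      lillie_D(sort(rnorm(n))), numeric(1)))
    out$p_value <- (1 + sum(null_D >= D)) / (mc_reps + 1)
    out$mc_reps <- mc_reps
  }
  out
}

# sup-distance of the step ECDF from the fitted normal CDF,
# evaluated just below and at each order statistic
lillie_D <- function(x_sorted) {
  n <- length(x_sorted)
  p <- pnorm((x_sorted - mean(x_sorted)) / sd(x_sorted))
  max(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n)
}

#' Tune the Box-Cox parameter by the Lilliefors statistic
#'
#' Scans a grid of Box-Cox parameters, transforms the data at each,
#' and scores each transform by its Lilliefors distance from
#' normality. The parameter minimising the distance is returned;
#' exact ties are broken toward the value nearest 1 (no
#' transformation). Because the statistic is computed against a
#' normal with estimated mean and SD, the procedure is invariant to
#' rescaling the input.
#'
#' @param x Strictly positive numeric vector.
#' @param grid Candidate parameter values (default -3 to 3 by 0.1).
#' @return List with `lambda`, `statistic` (at the optimum),
#'   `grid`, `statistics` (per grid point), `transformed` (data at
#'   the optimum).
#' @examples
#' \donttest{
#' x <- exp(rnorm(500))
#' boxcox_tune(x)$lambda  # close to 0: log-normal data
#' }
#' @export
boxcox_tune <- function(x, grid = seq(-3, 3, by = 0.1)) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("Box-Cox tuning requires strictly positive values")
  if (length(grid) < 1L) stopf("empty search grid")
  stats_ <- vapply(grid, function(l)
    lilliefors_statistic(boxcox_transform(x, l))$statistic, numeric(1))
  best <- which(stats_ <= min(stats_) + 1e-15)
  pick <- best[which.min(abs(grid[best] - 1))]
  list(lambda = grid[pick], statistic = stats_[pick], grid = grid,
       statistics = stats_, transformed = boxcox_transform(x, grid[pick]))
}
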