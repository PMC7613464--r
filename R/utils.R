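##' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois rnbinom sd var median quantile
#'   qchisq pchisq pnorm qnorm qt ecdf optimize coef predict residuals
#' @importFrom utils read.csv write.csv
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a probability in [0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stopf("`%s` must be %s, got %s", name,
                 if (strict) "> 0" else ">= 0", paste(format(x), collapse = ", "))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && x == floor(x)
  if (!ok) stopf("`%s` must be an integer >= %d", name, min)
  invisible(as.integer(x))
}

# Population variance (divide by N); used for all reliability and
# threshold statistics so variance identities hold exactly.
pvar <- function(x) mean((x - mean(x))^2)

psd <- function(x) sqrt(pvar(x))

# All generator randomness is scoped: the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), code)
}
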