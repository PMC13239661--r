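# Units and small shared helpers.
#
# Calendar phrases are fixed conventions here: 1 month = 30.4375 days,
# 1 year = 365.25 days.  Everything internal is SI (meters, seconds).

.UNIT_SECONDS <- c(
  second = 1, seconds = 1, sec = 1, s = 1,
  minute = 60, minutes = 60, min = 60,
  hour = 3600, hours = 3600, hr = 3600, h = 3600,
  day = 86400, days = 86400, d = 86400,
  week = 604800, weeks = 604800,
  month = 30.4375 * 86400, months = 30.4375 * 86400,
  year = 365.25 * 86400, years = 365.25 * 86400, yr = 365.25 * 86400
)

#' Convert a duration to seconds
#'
#' Accepts a bare number (already in seconds) or a string of the form
#' `"<number> <unit>"`, e.g. `"10 days"`, `"30 min"`, `"2 months"`.
#' The calendar conventions are fixed: 1 month = 30.4375 days and
#' 1 year = 365.25 days.
#'
#' @param x numeric (seconds) or character like `"2 months"`.
#' @return numeric vector of seconds.
#' @examples
#' asSeconds("1 day")
#' asSeconds(c("30 min", "2 hours"))
#' @export
asSeconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) stop("duration must be numeric seconds or a string")
  vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([-0-9.eE+]+)\\s*([A-Za-z]+)$", s))[[1]]
    if (length(m) != 3L)
      stop("cannot parse duration '", s, "' (expected e.g. '10 days')")
    val <- suppressWarnings(as.numeric(m[2]))
    unit <- tolower(m[3])
    if (is.na(val) || !unit %in% names(.UNIT_SECONDS))
      stop("cannot parse duration '", s, "'")
    val * .UNIT_SECONDS[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic sub-stream seed derivation
#'
#' The i-th sub-seed of `seed`:
#' `(seed + 1000003 * i) mod (2^31 - 1)`.  Population simulations derive
#' one sub-seed per individual from this contract, so they are
#' reproducible individual-by-individual.
#'
#' @param seed integer master seed.
#' @param i sub-stream index.
#' @return integer sub-seed (always below 2^31).
#' @export
subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Chi-square confidence interval for a positive estimate
#'
#' Confidence interval for the true value of a positive estimate whose
#' sampling distribution is `truth * chisq(nu) / nu`, by inverting the
#' chi-square pivot.
#'
#' @param value point estimate.
#' @param nu chi-square degrees of freedom.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(low, high)`.
#' @export
chisqCI <- function(value, nu, level = 0.95) {
  a <- (1 - level) / 2
  c(low = nu * value / qchisq(1 - a, df = nu),
    high = nu * value / qchisq(a, df = nu))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
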