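#' Map calendar dates to day-of-year on the annual circle
#'
#' All seasonal curves in this package live on the day-of-year coordinate
#' `[1, 365]`. Leap-day observations (day 366) are clamped to day 365 so that
#' every year maps onto the same circle.
#'
#' @param dates a `Date` vector (or something coercible via [as.Date()]).
#' @return integer vector of days in `[1, 365]`.
#' @export
#' @examples
#' day_of_year(as.Date(c("2020-01-01", "2020-12-31", "2020-02-29")))
day_of_year <- function(dates) {
  d <- as.POSIXlt(as.Date(dates))$yday + 1L
  pmin(d, 365L)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. With seed = NULL the current stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_days <- function(day, what = "day_of_year") {
  if (any(!is.finite(day)) || any(day < 1 | day > 365))
    stopf("%s must lie in [1, 365]", what)
  invisible(day)
}

## Smooth annual "winterness" weight in [0, 1]: a von Mises shaped bump on the
## 365-day circle centered at the year boundary, scaled so the December/January
## core is ~1 and mid summer ~0.
winterness <- function(day, center = 365, kappa = 2.5) {
  a <- exp(kappa * (cos(2 * pi * (day - center) / 365) - 1))
  (a - exp(-2 * kappa)) / (1 - exp(-2 * kappa))
}

## Smooth plateau over the day window [a, b] with cosine ramps of `ramp` days
## on either side; used to switch group effects on over part of the year.
## Handles windows given in increasing day order; the ramp is clipped at the
## year boundary rather than wrapped (windows are specified within [1, 365]).
window_weight <- function(day, a, b, ramp = 15) {
  w <- numeric(length(day))
  inside <- day >= a & day <= b
  w[inside] <- 1
  if (ramp > 0) {
    lo <- day >= (a - ramp) & day < a
    w[lo] <- 0.5 * (1 + cos(pi * (a - day[lo]) / ramp))
    hi <- day > b & day <= (b + ramp)
    w[hi] <- 0.5 * (1 + cos(pi * (day[hi] - b) / ramp))
  }
  w
}

## days covered by each grid interval [g[i], g[i+1]) ; last interval closed
interval_days <- function(grid, i) {
  from <- ceiling(grid[i])
  to <- if (i + 1 == length(grid)) floor(grid[i + 1]) else ceiling(grid[i + 1]) - 1
  seq.int(from, max(from, to))
}
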