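# Fortnightly (half-month, 24 bins per year) count series ----------------

#' Create a fortnightly series
#'
#' A `fortnight_series` is a regular time series with 24 half-month bins per
#' year (bin 1 of a month covers days 1-15, bin 2 covers day 16 to month end).
#' It is a thin subclass of [stats::ts] with `frequency = 24`, so all the usual
#' windowing and decomposition tools apply.
#'
#' @param values numeric vector of counts or real-valued (e.g. seasonally
#'   adjusted) observations, in time order with no gaps.
#' @param start integer vector `c(year, fortnight)` of the first observation;
#'   fortnight runs 1-24.
#' @return an object of classes `fortnight_series` and `ts`.
#' @export
fortnight_series <- function(values, start = c(1L, 1L)) {
  if (length(start) != 2L || start[2L] < 1L || start[2L] > 24L) {
    stop("`start` must be c(year, fortnight) with fortnight in 1..24")
  }
  x <- ts(as.numeric(values), start = start, frequency = 24)
  class(x) <- c("fortnight_series", "ts")
  x
}

#' @export
print.fortnight_series <- function(x, ...) {
  s <- stats::start(x)
  e <- stats::end(x)
  cat(sprintf("Fortnightly series: %d observations, %d/f%02d to %d/f%02d\n",
              length(x), s[1L], s[2L], e[1L], e[2L]))
  print(unclass(summary(as.numeric(x))))
  invisible(x)
}

#' @export
as.data.frame.fortnight_series <- function(x, ...) {
  tt <- as.numeric(time(x))
  yr <- floor(tt + 1e-8)
  fn <- as.integer(round((tt - yr) * 24)) + 1L
  data.frame(year = as.integer(yr), fortnight = fn, value = as.numeric(x))
}

#' Fortnight index of calendar dates
#'
#' Maps dates to the half-month bin 1-24: two bins per month, split at day
#' 15/16 (days 1-15 fall in the first bin, day 16 onward in the second).
#'
#' @param dates a `Date` vector (or coercible).
#' @return integer vector in 1..24.
#' @export
fortnight_of_date <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  d <- as.integer(format(dates, "%d"))
  2L * (m - 1L) + 1L + as.integer(d >= 16L)
}

# First calendar day of a fortnight bin
fortnight_start_date <- function(year, fortnight) {
  month <- (fortnight + 1L) %/% 2L
  day <- ifelse(fortnight %% 2L == 1L, 1L, 16L)
  as.Date(sprintf("%04d-%02d-%02d", year, month, day))
}

# Number of days in a fortnight bin (second half depends on month length)
fortnight_n_days <- function(year, fortnight) {
  month <- (fortnight + 1L) %/% 2L
  if (fortnight %% 2L == 1L) return(15L)
  first_next <- if (month == 12L) {
    as.Date(sprintf("%04d-01-01", year + 1L))
  } else {
    as.Date(sprintf("%04d-%02d-01", year, month + 1L))
  }
  as.integer(first_next - as.Date(sprintf("%04d-%02d-16", year, month)))
}

# Calendar quarter (1..4) of a fortnight index
quarter_of_fortnight <- function(fortnight) {
  stopifnot(all(fortnight >= 1L & fortnight <= 24L))
  (((fortnight + 1L) %/% 2L) - 1L) %/% 3L + 1L
}

# Run code under a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
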