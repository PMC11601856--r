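#' Simulation calendar
#'
#' The simulation clock uses 365-day years (no leap days) with standard
#' month lengths, so every simulated year has an identical structure.
#' `day_index` is 1-based from the start of the simulation.
#'
#' @param day_index integer vector of 1-based simulation days.
#' @param start_year first calendar year of the simulation.
#' @return `sim_calendar()` returns a data.frame with one row per day and
#'   columns `day_index`, `year`, `doy` (day of year, 1-365), `month`
#'   (1-12) and `month_index` (running month, 1-based from simulation
#'   start).
#' @export
sim_calendar <- function(day_index, start_year = 2002L) {
  stopifnot(all(day_index >= 1))
  doy <- (day_index - 1L) %% 365L + 1L
  yr_off <- (day_index - 1L) %/% 365L
  month <- month_of_doy(doy)
  data.frame(
    day_index = as.integer(day_index),
    year = as.integer(start_year + yr_off),
    doy = as.integer(doy),
    month = month,
    month_index = as.integer(yr_off * 12L + month)
  )
}

# cumulative day at which each month starts in a 365-day year
.month_starts <- cumsum(c(0L, 31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L))

month_of_doy <- function(doy) {
  as.integer(findInterval(doy - 1L, .month_starts))
}

#' @rdname sim_calendar
#' @export
days_per_year <- function() 365L
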