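#' Decompose predictions into background, total and smoke fields
#'
#' Background is the smoke-off model applied everywhere; total equals
#' the smoke-on model on SMOKE_ON cell-days and background elsewhere;
#' smoke = max(0, total - background), so it is exactly zero on
#' SMOKE_OFF cell-days and never negative.
#'
#' @param total_on cell-by-day matrix of smoke-on model predictions.
#' @param background_off cell-by-day matrix of smoke-off model
#'   predictions (full coverage).
#' @param mask `scenario_mask` (TRUE = SMOKE_ON), same shape.
#' @return list of aligned matrices `background`, `total`, `smoke`.
#' @export
decompose_concentrations <- function(total_on, background_off, mask) {
  if (!all(dim(total_on) == dim(background_off)) ||
      !all(dim(total_on) == dim(mask))) {
    stop("misaligned cubes: total, background and mask must share dimensions")
  }
  total <- ifelse(mask, total_on, background_off)
  smoke <- pmax(total - background_off, 0)
  smoke[!mask] <- 0
  list(background = background_off, total = total, smoke = smoke)
}

#' Mean smoke days per year per cell
#'
#' @param mask `scenario_mask` covering the period.
#' @param n_years number of years spanned by the mask.
#' @return numeric vector: per-cell SMOKE_ON day count divided by
#'   `n_years`.
#' @export
count_smoke_days <- function(mask, n_years = ncol(mask) / days_per_year()) {
  rowSums(mask) / n_years
}

#' Heavy-fire-smoke grid-day mask
#'
#' A grid-day is heavy-fire-smoke when the total carbonaceous
#' concentration strictly exceeds `total_threshold` (1 ug/m3) and smoke
#' makes up strictly more than `fraction_threshold` (50%) of the total.
#' Cell-days with zero total are never flagged.
#'
#' @param total_carb,smoke_carb OC+EC total and smoke cell-by-day
#'   matrices (smoke <= total elementwise).
#' @param total_threshold concentration threshold, ug/m3.
#' @param fraction_threshold smoke fraction threshold.
#' @return logical cell-by-day matrix.
#' @export
heavy_smoke_mask <- function(total_carb, smoke_carb,
                             total_threshold = 1, fraction_threshold = 0.5) {
  frac <- ifelse(total_carb > 0, smoke_carb / total_carb, 0)
  (total_carb > total_threshold) & (frac > fraction_threshold)
}

#' Person-days of exposure and within-year cumulative series
#'
#' Daily person-days are the population-weighted count of flagged cells;
#' the cumulative series is the running sum within each calendar year.
#' Period summaries average the within-year cumulative value at each day
#' of year across the period's years.
#'
#' @param mask logical cell-by-day matrix (e.g. [heavy_smoke_mask()]).
#' @param population `population_raster` aligned to the mask's cells.
#' @return object of class `exposure_series`: list with `daily`
#'   (person-days per day), `cumulative` (running within-year sums),
#'   `by_year` (doy-by-year matrix of cumulative values) and
#'   `total_persons`.
#' @export
person_days <- function(mask, population) {
  if (nrow(mask) != nrow(population)) {
    stop("population raster and mask cover different cell sets")
  }
  daily <- as.vector(crossprod(mask, population$persons))
  n_days <- length(daily)
  cal <- sim_calendar(seq_len(n_days))
  cum <- stats::ave(daily, cal$year, FUN = cumsum)
  n_years <- ceiling(n_days / days_per_year())
  by_year <- matrix(NA_real_, days_per_year(), n_years)
  by_year[cbind(cal$doy, cal$year - cal$year[1] + 1L)] <- cum
  structure(list(daily = daily, cumulative = cum, by_year = by_year,
                 total_persons = sum(population$persons)),
            class = "exposure_series")
}

#' Period-average cumulative person-days at a day of year
#'
#' @param series `exposure_series`.
#' @param doy day of year at which to read the cumulative value
#'   (default 365, i.e. year end; July 1st is doy 182).
#' @param years which year indices of the series to average (default all
#'   complete columns).
#' @return mean within-year cumulative person-days at `doy`.
#' @export
cumulative_at <- function(series, doy = days_per_year(),
                          years = seq_len(ncol(series$by_year))) {
  mean(series$by_year[doy, years], na.rm = TRUE)
}

#' Per-capita exposure days per year
#'
#' @param series `exposure_series`.
#' @param population `population_raster` (total persons > 0).
#' @param years year indices to average over.
#' @return annual person-days divided by total persons (days per person
#'   per year).
#' @export
per_capita_days <- function(series, population,
                            years = seq_len(ncol(series$by_year))) {
  tp <- sum(population$persons)
  if (tp <= 0) stop("total population must be > 0")
  cumulative_at(series, days_per_year(), years) / tp
}

#' Percent change between two period values
#'
#' `100 * (later - earlier) / earlier`, rounded to the nearest integer
#' percent for reporting.
#'
#' @param earlier baseline quantity (> 0).
#' @param later comparison quantity.
#' @param digits rounding digits (0 = integer percent).
#' @return percent change.
#' @export
percent_change <- function(earlier, later, digits = 0) {
  if (earlier <= 0) stop("earlier value must be > 0")
  round(100 * (later - earlier) / earlier, digits)
}
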