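#' Read or construct a concentration-bin mortality rate schedule
#'
#' Bins are `[lower, upper)` intervals in ug/m3 that must be
#' non-overlapping and cover `[0, Inf)`; rates are monthly non-accidental
#' deaths per 100,000 per bin.  A synthetic default schedule is shipped
#' at `system.file("extdata", "rate_schedule_synthetic.csv",
#' package = "smokecarbon")` for testing; real applications supply their
#' own CSV with columns `lower`, `upper`, `monthly_rate`.
#'
#' @param path CSV path; `NULL` loads the shipped synthetic schedule.
#' @return data.frame of class `rate_schedule`.
#' @export
read_rate_schedule <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rate_schedule_synthetic.csv",
                        package = "smokecarbon")
  }
  s <- utils::read.csv(path)
  stopifnot(all(c("lower", "upper", "monthly_rate") %in% names(s)))
  s <- s[order(s$lower), , drop = FALSE]
  if (s$lower[1] != 0 || !is.infinite(s$upper[nrow(s)]) ||
      any(s$lower[-1] != s$upper[-nrow(s)]) || any(s$monthly_rate < 0)) {
    stop("rate schedule bins must be non-overlapping, cover [0, Inf), ",
         "and have nonnegative rates")
  }
  class(s) <- c("rate_schedule", "data.frame")
  s
}

#' Annualize a monthly mortality rate schedule
#'
#' Multiplies each bin's monthly rate by 12 to obtain annual deaths per
#' 100,000.
#'
#' @param schedule `rate_schedule` (or numeric monthly rate vector).
#' @return schedule with an `annual_rate` column (or numeric vector).
#' @export
annualize_rate <- function(schedule) {
  if (is.numeric(schedule)) {
    stopifnot(all(schedule >= 0))
    return(12 * schedule)
  }
  schedule$annual_rate <- 12 * schedule$monthly_rate
  schedule
}

#' Attributable deaths by the concentration-bin rate pathway
#'
#' Each cell's annual-mean smoke carbonaceous concentration is looked up
#' in the annualized bin schedule; deaths = population x annual rate /
#' 100,000, booked (by default) to the year after exposure and
#' aggregated to region-year.
#'
#' @param annual_smoke per-cell annual mean smoke OC+EC, ug/m3.
#' @param schedule annualized `rate_schedule` (see [annualize_rate()]).
#' @param population `population_raster`.
#' @param regions per-cell region labels.
#' @param exposure_year calendar year of the exposure.
#' @param lag years between exposure and booked deaths (default 1; 0 for
#'   the no-lag sensitivity variant).
#' @return `burden_table` data.frame: one row per region with `region`,
#'   `year`, `deaths`, `mortality_rate_per_100k`, `pathway`.
#' @export
attributable_deaths_bin <- function(annual_smoke, schedule, population,
                                    regions, exposure_year, lag = 1L) {
  stopifnot(length(annual_smoke) == nrow(population),
            length(regions) == nrow(population))
  if (is.null(schedule$annual_rate)) schedule <- annualize_rate(schedule)
  bin <- findInterval(annual_smoke, schedule$lower)
  rate <- schedule$annual_rate[bin]
  deaths_cell <- population$persons * rate / 1e5
  deaths <- tapply(deaths_cell, regions, sum)
  pop_r <- tapply(population$persons, regions, sum)
  out <- data.frame(region = names(deaths),
                    year = as.integer(exposure_year + lag),
                    deaths = as.numeric(deaths),
                    mortality_rate_per_100k = as.numeric(deaths / pop_r * 1e5),
                    pathway = "BIN_RATE")
  rownames(out) <- NULL
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Regional share of national deaths
#'
#' `100 * region / total`, rounded half-up to one decimal (so 63.0137%
#' prints as 63.0).
#'
#' @param deaths_region,deaths_total death counts (`deaths_total` > 0).
#' @return percent to one decimal.
#' @export
region_share <- function(deaths_region, deaths_total) {
  if (deaths_total <= 0) stop("deaths_total must be > 0")
  floor(1000 * deaths_region / deaths_total + 0.5) / 10
}

#' Adjust a base-year VSL to a target year
#'
#' `VSL_t = base_vsl * (price_t / price_base) * (income_t /
#' income_base)^elasticity`, accounting for inflation and real income
#' growth.
#'
#' @param base_vsl value of a statistical life in base-year currency.
#' @param base_year,target_year calendar years; both must appear in the
#'   index tables.
#' @param price_index,income_index named numeric vectors (names =
#'   years).
#' @param elasticity income elasticity of the VSL (default 1).
#' @return adjusted VSL for `target_year`.
#' @export
adjust_vsl <- function(base_vsl, base_year, target_year,
                       price_index, income_index, elasticity = 1) {
  by <- as.character(base_year); ty <- as.character(target_year)
  if (!(by %in% names(price_index)) || !(ty %in% names(price_index)) ||
      !(by %in% names(income_index)) || !(ty %in% names(income_index))) {
    stop("missing index year: need ", base_year, " and ", target_year,
         " in both indices")
  }
  stopifnot(all(price_index > 0), all(income_index > 0))
  base_vsl * (price_index[[ty]] / price_index[[by]]) *
    (income_index[[ty]] / income_index[[by]])^elasticity
}

#' Build a VSL table for a span of years
#'
#' @inheritParams adjust_vsl
#' @param years integer years to cover.
#' @return data.frame of class `vsl_table` with `year` and `vsl`.
#' @export
vsl_table <- function(base_vsl, base_year, years, price_index, income_index,
                      elasticity = 1) {
  v <- vapply(years, function(y)
    adjust_vsl(base_vsl, base_year, y, price_index, income_index, elasticity),
    numeric(1))
  out <- data.frame(year = as.integer(years), vsl = v)
  class(out) <- c("vsl_table", "data.frame")
  out
}

#' Monetize attributable deaths with year-specific VSLs
#'
#' damage = deaths x VSL of the death year; damages are additive across
#' regions.
#'
#' @param burden `burden_table`.
#' @param vsl `vsl_table` covering every burden year.
#' @return burden table with a `damage` column.
#' @export
monetize <- function(burden, vsl) {
  i <- match(burden$year, vsl$year)
  if (anyNA(i)) {
    stop("missing VSL year(s): ",
         paste(unique(burden$year[is.na(i)]), collapse = ", "))
  }
  burden$damage <- burden$deaths * vsl$vsl[i]
  burden
}

#' Damage-to-budget ratio
#'
#' @param annual_damage monetized damage (currency/yr).
#' @param budget comparison budget (> 0).
#' @return dimensionless ratio.
#' @export
damage_budget_ratio <- function(annual_damage, budget) {
  if (budget <= 0) stop("budget must be > 0")
  annual_damage / budget
}

#' Attributable deaths by a log-linear concentration-response function
#'
#' The chronic-exposure pathway: attributable fraction
#' `AF = 1 - exp(-beta * delta_c)`, deaths = AF x baseline rate x
#' population / 100,000.
#'
#' @param delta_c annual exposure increment, ug/m3 (>= 0).
#' @param baseline_rate baseline non-accidental deaths per 100,000 per
#'   year.
#' @param population persons exposed.
#' @param beta log-linear CRF coefficient per ug/m3 (>= 0).
#' @param region,year labels for the output rows.
#' @return `burden_table` rows with `pathway = "CRF"` and an `af`
#'   column.
#' @export
attributable_deaths_crf <- function(delta_c, baseline_rate, population,
                                    beta, region = "SC", year = NA_integer_) {
  stopifnot(all(beta >= 0), all(delta_c >= 0))
  af <- 1 - exp(-beta * delta_c)
  deaths <- af * baseline_rate * population / 1e5
  out <- data.frame(region = region, year = as.integer(year),
                    deaths = deaths,
                    mortality_rate_per_100k = deaths / population * 1e5,
                    pathway = "CRF", af = af)
  class(out) <- c("burden_table", "data.frame")
  out
}
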