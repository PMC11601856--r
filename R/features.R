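#' Assemble model features for arbitrary cell-days
#'
#' Builds the feature frame used by [predict_daily()] for a set of
#' (cell, day) pairs under one scenario: the matching CTM run mapped to
#' fine cells, the auxiliary layers, and coordinate/time features.  AOD
#' gaps are filled from the same cell's nearest non-missing day within
#' `gap_window` days, then (prediction must be full-coverage) from the
#' cell's median AOD, then the domain median.
#'
#' @param domain grid domain.
#' @param ctm_pair `ctm_pair`.
#' @param aux `aux_cube`.
#' @param cells 1-based cell row indices into `domain`.
#' @param days day indices (same length as `cells`).
#' @param scenario `"on"` or `"off"`: which CTM run feeds the `ctm`
#'   feature.
#' @param start_year calendar year of day 1.
#' @param gap_window AOD nearest-day search half-width.
#' @return data.frame with the model feature columns plus `cell_id` and
#'   `day_index`.
#' @export
assemble_features <- function(domain, ctm_pair, aux, cells, days,
                              scenario = c("off", "on"), start_year = 2002L,
                              gap_window = 3L) {
  scenario <- match.arg(scenario)
  stopifnot(length(cells) == length(days))
  cal <- sim_calendar(days, start_year)
  gap <- fill_aod(aux$aod, cells, days, gap_window)
  aod <- gap$value
  if (anyNA(aod)) {
    cell_med <- apply(aux$aod, 1, stats::median, na.rm = TRUE)
    cell_med[!is.finite(cell_med)] <- stats::median(aux$aod, na.rm = TRUE)
    aod[is.na(aod)] <- cell_med[cells[is.na(aod)]]
  }
  mk <- function(sp) {
    fld <- if (scenario == "on") ctm_pair[[sp]]$ctm_on else ctm_pair[[sp]]$ctm_off
    fld[cbind(ctm_pair$map[cells], days)]
  }
  data.frame(
    cell_id = domain$cell_id[cells], day_index = days,
    ctm_OC = mk("OC"), ctm_EC = mk("EC"),
    aod = aod,
    met_temp = aux$met_temp[cbind(cells, days)],
    met_rh = aux$met_rh[cbind(cells, days)],
    urban = aux$urban[cells], elev = aux$elev[cells],
    x = domain$x[cells], y = domain$y[cells],
    doy = cal$doy, year = cal$year
  )
}

# species view of an assembled frame: renames ctm_<sp> to the ctm feature
species_features <- function(features, species) {
  f <- features
  f$ctm <- f[[paste0("ctm_", species)]]
  f$ctm_OC <- NULL; f$ctm_EC <- NULL
  f
}

#' Monitor-cell monthly means of observations and predictions
#'
#' Aggregates daily observed/predicted pairs at monitor cells to
#' site-months, the input of [fit_residual_smoother()].
#'
#' @param table `training_table` (observed rows are used).
#' @param pred daily predictions aligned to the table rows.
#' @param start_year calendar year of day 1.
#' @return data.frame with `site_id`, `x`, `y`, `month_index`, `obs`,
#'   `pred`, `n_days`.
#' @export
monthly_frame <- function(table, pred, start_year = 2002L) {
  obs <- table$provenance == "OBSERVED"
  d <- table[obs, , drop = FALSE]
  p <- pred[obs]
  cal <- sim_calendar(d$day_index, start_year)
  key <- paste(d$site_id, cal$month_index, sep = "|")
  agg <- function(v) as.vector(tapply(v, key, mean))
  keys <- sort(unique(key))
  o <- tapply(d$label, key, mean)[keys]
  pr <- tapply(p, key, mean)[keys]
  nd <- tapply(p, key, length)[keys]
  xs <- tapply(d$x, key, function(v) v[1])[keys]
  ys <- tapply(d$y, key, function(v) v[1])[keys]
  sid <- sub("\\|.*$", "", keys)
  mi <- as.integer(sub("^.*\\|", "", keys))
  data.frame(site_id = sid, x = as.numeric(xs), y = as.numeric(ys),
             month_index = mi, obs = as.numeric(o), pred = as.numeric(pr),
             n_days = as.integer(nd))
}
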