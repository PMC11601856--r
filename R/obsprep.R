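#' Exclude extreme monitor observations
#'
#' Removes observations strictly above a per-species concentration cap.
#' The default caps are the fixed values used throughout the package
#' (the 99.98th-percentile convention): OC 34.75 ug/m3, EC 7.40 ug/m3.
#' Set `recompute_percentile` to derive caps from the data instead.
#'
#' @param records `monitor_records` data.frame.
#' @param caps named numeric vector of per-species caps (ug/m3, > 0).
#' @param recompute_percentile if non-`NULL`, ignore `caps` and use this
#'   percentile (e.g. `0.9998`) of each species' observed values.
#' @return list with `records` (retained rows, original ordering) and
#'   `n_removed` (named integer per species).
#' @export
filter_outliers <- function(records, caps = c(OC = 34.75, EC = 7.40),
                            recompute_percentile = NULL) {
  stopifnot(all(caps > 0))
  if (!is.null(recompute_percentile)) {
    caps <- vapply(split(records$value, records$species),
                   stats::quantile, numeric(1),
                   probs = recompute_percentile, names = FALSE)
  }
  drop <- records$value > caps[records$species]
  n_removed <- vapply(c(OC = "OC", EC = "EC"),
                      function(sp) sum(drop & records$species == sp, na.rm = TRUE),
                      integer(1))
  list(records = records[!drop, , drop = FALSE], n_removed = n_removed,
       caps = caps)
}

feature_names <- function() {
  c("ctm", "aod", "met_temp", "met_rh", "urban", "elev", "x", "y", "doy", "year")
}

# nearest-day AOD gap fill within +/- window; NA if none found
fill_aod <- function(aod, cells, days, window = 3L) {
  v <- aod[cbind(cells, days)]
  filled <- rep(FALSE, length(v))
  n_days <- ncol(aod)
  for (lag in seq_len(window)) {
    for (s in c(-1L, 1L)) {            # prefer smaller |lag|; tie -> earlier day
      need <- is.na(v)
      if (!any(need)) break
      d2 <- days + s * lag
      ok <- need & d2 >= 1L & d2 <= n_days
      if (!any(ok)) next
      cand <- aod[cbind(cells[ok], d2[ok])]
      got <- !is.na(cand)
      idx <- which(ok)[got]
      v[idx] <- cand[got]
      filled[idx] <- TRUE
    }
  }
  list(value = v, filled = filled)
}

#' Assemble scenario-specific training tables
#'
#' Joins monitor records to their collocated grid cells and builds one
#' feature row per record: the CTM concentration from the run matching
#' the cell-day's scenario, the auxiliary layers, and coordinate/time
#' features.  AOD cloud gaps are filled from the same cell's nearest
#' non-missing day within `gap_window` days (flagged), or the row is
#' dropped when no fill exists (`gap_policy = "fill"`); with
#' `gap_policy = "drop"` any gap row is dropped.
#'
#' @param records filtered `monitor_records`.
#' @param domain grid domain.
#' @param mask `scenario_mask`.
#' @param ctm_pair `ctm_pair`.
#' @param aux `aux_cube`.
#' @param start_year calendar year of simulation day 1.
#' @param gap_policy `"fill"` (default) or `"drop"`.
#' @param gap_window fill search half-width in days.
#' @return named list of `training_table` data.frames, one per
#'   species x scenario (`OC.on`, `OC.off`, `EC.on`, `EC.off`), each
#'   carrying attributes `species`, `scenario`, `standardization`
#'   (feature means/sds over observed rows) and `n_dropped_gap`.
#' @export
collocate <- function(records, domain, mask, ctm_pair, aux,
                      start_year = 2002L, gap_policy = c("fill", "drop"),
                      gap_window = 3L) {
  gap_policy <- match.arg(gap_policy)
  n_days <- ncol(mask)
  if (any(records$day_index < 1 | records$day_index > n_days)) {
    stop("record day_index outside the simulated range 1..", n_days)
  }
  cells <- match(records$cell_id, domain$cell_id)
  if (anyNA(cells)) stop("record cell_id not present in domain")
  days <- records$day_index
  on <- mask[cbind(cells, days)]

  cal <- sim_calendar(days, start_year)
  ctm <- numeric(nrow(records))
  for (sp in c("OC", "EC")) {
    for (sc_on in c(TRUE, FALSE)) {
      sel <- records$species == sp & (on == sc_on)
      if (!any(sel)) next
      fld <- if (sc_on) ctm_pair[[sp]]$ctm_on else ctm_pair[[sp]]$ctm_off
      ctm[sel] <- fld[cbind(ctm_pair$map[cells[sel]], days[sel])]
    }
  }

  gap <- fill_aod(aux$aod, cells, days, gap_window)
  aod <- gap$value
  keep <- !is.na(aod)
  if (gap_policy == "drop") keep <- keep & !gap$filled

  tab <- data.frame(
    site_id = records$site_id, cell_id = records$cell_id,
    day_index = days, species = records$species,
    label = records$value,
    ctm = ctm, aod = aod,
    met_temp = aux$met_temp[cbind(cells, days)],
    met_rh = aux$met_rh[cbind(cells, days)],
    urban = aux$urban[cells], elev = aux$elev[cells],
    x = domain$x[cells], y = domain$y[cells],
    doy = cal$doy, year = cal$year,
    aod_gap_filled = gap$filled,
    provenance = "OBSERVED",
    scenario_on = on
  )
  n_dropped_gap <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]

  out <- list()
  for (sp in c("OC", "EC")) {
    for (sc in c("on", "off")) {
      t1 <- tab[tab$species == sp & (tab$scenario_on == (sc == "on")), , drop = FALSE]
      t1$scenario_on <- NULL
      rownames(t1) <- NULL
      fs <- as.matrix(t1[feature_names()])
      std <- list(mean = colMeans(fs), sd = apply(fs, 2, stats::sd))
      std$sd[std$sd == 0 | !is.finite(std$sd)] <- 1
      attr(t1, "species") <- sp
      attr(t1, "scenario") <- sc
      attr(t1, "standardization") <- std
      attr(t1, "n_dropped_gap") <- n_dropped_gap
      class(t1) <- c("training_table", "data.frame")
      out[[paste(sp, sc, sep = ".")]] <- t1
    }
  }
  out
}

#' SMOTE enrichment of high-concentration rows (regression variant)
#'
#' Oversamples the under-represented high-concentration tail of a
#' training table.  A minority row is any observed row whose label
#' exceeds the `high_cutoff` label quantile.  Each synthetic row is a
#' convex combination (uniform lambda in (0,1), applied jointly to
#' features and label) of a sampled minority row and one of its
#' `k_neighbors` nearest minority neighbours in standardized
#' feature+label space, so every synthetic label lies between its two
#' parents' labels.  Synthetic rows are flagged `SMOTE_SYNTHETIC` and
#' must never enter evaluation.
#'
#' @param table `training_table`.
#' @param high_cutoff label quantile defining the minority (default 0.9).
#' @param k_neighbors neighbours considered per parent (default 5).
#' @param multiplier appends `ceiling(multiplier * n_minority)` synthetic
#'   rows; 0 returns the table unchanged.
#' @param seed integer seed.
#' @return the enriched `training_table`.
#' @export
smote_enrich <- function(table, high_cutoff = 0.9, k_neighbors = 5L,
                         multiplier = 1.0, seed = 6L) {
  if (multiplier == 0) return(table)
  obs <- table$provenance == "OBSERVED"
  cutoff <- stats::quantile(table$label[obs], high_cutoff, names = FALSE)
  minority <- which(obs & table$label > cutoff)
  if (length(minority) < k_neighbors + 1) {
    stop("SMOTE needs at least k_neighbors + 1 = ", k_neighbors + 1,
         " rows above the ", high_cutoff, " label quantile (",
         signif(cutoff, 4), " ug/m3); found ", length(minority))
  }
  set.seed(seed)
  std <- attr(table, "standardization")
  cols <- c(feature_names(), "label")
  M <- as.matrix(table[minority, cols])
  lab_sd <- stats::sd(table$label[obs]); if (!is.finite(lab_sd) || lab_sd == 0) lab_sd <- 1
  Z <- sweep(sweep(M, 2, c(std$mean, mean(table$label[obs]))),
             2, c(std$sd, lab_sd), "/")
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  kk <- min(k_neighbors, nrow(D) - 1L)
  ord <- apply(D, 1, function(r) order(r)[seq_len(kk)])
  nn <- if (kk == 1L) matrix(ord, ncol = 1) else t(ord)

  n_new <- ceiling(multiplier * length(minority))
  pick <- sample.int(length(minority), n_new, replace = TRUE)
  mate <- nn[cbind(pick, sample.int(ncol(nn), n_new, replace = TRUE))]
  lam <- stats::runif(n_new)
  newM <- M[pick, , drop = FALSE] +
    lam * (M[mate, , drop = FALSE] - M[pick, , drop = FALSE])

  new_rows <- table[minority[pick], , drop = FALSE]   # inherit keys from parent
  new_rows[cols] <- newM
  new_rows$provenance <- "SMOTE_SYNTHETIC"
  new_rows$aod_gap_filled <- FALSE
  out <- rbind(table, new_rows)
  rownames(out) <- NULL
  for (a in c("species", "scenario", "standardization", "n_dropped_gap")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- class(table)
  out
}
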