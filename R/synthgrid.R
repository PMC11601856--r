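# ---- internal field helpers -------------------------------------------------

# Spatially smooth unit-variance Gaussian field on the lattice, by separable
# Gaussian-kernel smoothing of white noise.  corr_length = Inf returns an
# exactly constant (zero) field, the degenerate limit of infinite correlation.
smooth_field <- function(n_x, n_y, corr_length) {
  if (!is.finite(corr_length)) return(matrix(0, n_x, n_y))
  z <- matrix(stats::rnorm(n_x * n_y), n_x, n_y)
  if (corr_length <= 0) return(z)
  k1 <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * corr_length^2))
    k / rowSums(k)
  }
  f <- k1(n_x) %*% z %*% t(k1(n_y))
  s <- stats::sd(f)
  if (s > 0) f <- (f - mean(f)) / s
  f
}

# Clustered positive surface in (0, 1]: a few Gaussian "city" bumps on top of
# a low floor.  Used for the urbanization gradient and monitor placement.
urban_surface <- function(domain, n_centers = 5, bump_radius = NULL) {
  n_x <- attr(domain, "n_x"); n_y <- attr(domain, "n_y")
  if (is.null(bump_radius)) bump_radius <- max(2, min(n_x, n_y) / 8)
  cx <- stats::runif(n_centers, 1, n_x)
  cy <- stats::runif(n_centers, 1, n_y)
  amp <- stats::runif(n_centers, 0.5, 1)
  u <- rep(0.02, nrow(domain))
  for (i in seq_len(n_centers)) {
    d2 <- (domain$x - cx[i])^2 + (domain$y - cy[i])^2
    u <- u + amp[i] * exp(-d2 / (2 * bump_radius^2))
  }
  pmin(u, 1)
}

#' Default parameters of the synthetic truth generator
#'
#' Controls the study conditions emulated by [simulate_truth()]: a
#' right-skewed, seasonally varying, spatially autocorrelated background
#' with an urban gradient, plus episodic drifting smoke plumes that peak
#' in the July--November fire season and load organic carbon about three
#' times as heavily as elemental carbon.
#'
#' @return a named list of generator parameters (concentrations in
#'   ug/m3, lengths in cell units, rates in events per day).
#' @export
truth_params <- function() {
  list(
    bg_mean = c(OC = 1.2, EC = 0.30),   # long-term mean background, ug/m3
    bg_corr_length = 8,                 # spatial correlation length, cells
    bg_seasonal_amplitude = 0.35,       # relative winter/summer swing
    bg_peak_doy = 15,                   # background peaks mid-winter
    bg_noise_sd = 0.35,                 # lognormal day-to-day dispersion
    bg_temporal_rho = 0.6,              # AR(1) persistence of daily field
    urban_strength = 1.0,               # background uplift in urban cells
    plume_rate = 0.6,                   # mean ignitions per day, whole domain
    plume_seasonality = 1.2,            # log-scale seasonal modulation
    plume_peak_doy = 258,               # mid-September
    plume_intensity = 4.0,              # median OC peak of a fresh plume, ug/m3
    plume_intensity_sdlog = 0.6,
    plume_radius = 3.0,                 # Gaussian kernel sd, cells
    plume_trunc = 3.0,                  # hard footprint cut at trunc * radius
    plume_drift_sd = 1.2,               # per-day drift velocity sd, cells/day
    plume_mean_duration = 3,            # geometric mean lifetime, days
    plume_decay = 0.6,                  # per-day multiplicative decay
    oc_ec_ratio = 3.0                   # OC:EC plume intensity ratio
  )
}

#' Simulate ground-truth background and smoke concentration fields
#'
#' Background is a clipped smooth random surface modulated by a seasonal
#' cycle and an urban gradient; smoke is a sum of episodic plumes
#' (random ignition cells, Gaussian spatial kernel with a hard footprint
#' truncation, multi-day drift and decay).  OC and EC share plume events
#' with species-specific intensities (`oc_ec_ratio`), so smoke is exactly
#' zero outside plume footprints and scales linearly in
#' `plume_intensity` for a fixed seed.
#'
#' @param domain a [make_domain()] grid.
#' @param n_days number of simulated days (>= 1).
#' @param params list as from [truth_params()]; partial lists are merged
#'   over the defaults.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return an object of class `truth_set`: a list with elements `OC` and
#'   `EC` (each a `truth_field` holding `background` and `smoke`
#'   cell-by-day matrices), `urban` (static urbanization layer),
#'   `events` (plume event table) and `params`.
#' @export
simulate_truth <- function(domain, n_days, params = list(), seed = 1L) {
  stopifnot(n_days >= 1)
  p <- utils::modifyList(truth_params(), params)
  stopifnot(p$plume_rate >= 0, p$plume_intensity >= 0, p$plume_radius > 0)
  n_x <- attr(domain, "n_x"); n_y <- attr(domain, "n_y")
  nc <- nrow(domain)
  set.seed(seed)

  urban <- urban_surface(domain)
  base_surf <- as.vector(smooth_field(n_x, n_y, p$bg_corr_length))
  base <- exp(0.4 * base_surf) * (1 + p$urban_strength * urban)

  cal <- sim_calendar(seq_len(n_days))
  season <- 1 + p$bg_seasonal_amplitude * cos(2 * pi * (cal$doy - p$bg_peak_doy) / 365)

  # AR(1)-in-time, smooth-in-space lognormal daily perturbation
  eps <- matrix(0, nc, n_days)
  prev <- as.vector(smooth_field(n_x, n_y, p$bg_corr_length))
  eps[, 1] <- prev
  if (n_days > 1) {
    for (d in 2:n_days) {
      innov <- as.vector(smooth_field(n_x, n_y, p$bg_corr_length))
      prev <- p$bg_temporal_rho * prev + sqrt(1 - p$bg_temporal_rho^2) * innov
      eps[, d] <- prev
    }
  }

  bg_shape <- base * exp(p$bg_noise_sd * eps)     # nc x n_days via recycling
  bg <- list(
    OC = pmax(p$bg_mean[["OC"]] * bg_shape * rep(season, each = nc), 0),
    EC = pmax(p$bg_mean[["EC"]] * bg_shape * rep(season, each = nc), 0)
  )

  # ---- plumes ----
  seas <- exp(p$plume_seasonality * cos(2 * pi * (cal$doy - p$plume_peak_doy) / 365))
  seas <- seas / mean(seas)
  n_events_day <- stats::rpois(n_days, p$plume_rate * seas)
  smoke_oc <- matrix(0, nc, n_days)
  events <- list()
  xs <- domain$x; ys <- domain$y
  trunc2 <- (p$plume_trunc * p$plume_radius)^2
  for (d in which(n_events_day > 0)) {
    for (e in seq_len(n_events_day[d])) {
      x0 <- stats::runif(1, 0, n_x); y0 <- stats::runif(1, 0, n_y)
      inten <- p$plume_intensity * stats::rlnorm(1, 0, p$plume_intensity_sdlog)
      vx <- stats::rnorm(1, 0, p$plume_drift_sd)
      vy <- stats::rnorm(1, 0, p$plume_drift_sd)
      dur <- 1L + stats::rgeom(1, 1 / p$plume_mean_duration)
      events[[length(events) + 1L]] <-
        data.frame(day0 = d, x0 = x0, y0 = y0, intensity = inten,
                   vx = vx, vy = vy, duration = dur)
      for (a in 0:(dur - 1L)) {
        dd <- d + a
        if (dd > n_days) break
        cx <- x0 + a * vx; cy <- y0 + a * vy
        d2 <- (xs - cx)^2 + (ys - cy)^2
        hit <- d2 < trunc2
        if (!any(hit)) next
        smoke_oc[hit, dd] <- smoke_oc[hit, dd] +
          inten * p$plume_decay^a * exp(-d2[hit] / (2 * p$plume_radius^2))
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(day0 = integer(), x0 = numeric(), y0 = numeric(),
               intensity = numeric(), vx = numeric(), vy = numeric(),
               duration = integer())

  mk <- function(sp, smoke) {
    structure(list(species = sp, background = bg[[sp]], smoke = smoke,
                   n_days = n_days),
              class = "truth_field")
  }
  structure(list(OC = mk("OC", smoke_oc),
                 EC = mk("EC", smoke_oc / p$oc_ec_ratio),
                 urban = urban, events = events, params = p,
                 n_x = n_x, n_y = n_y),
            class = "truth_set")
}

#' Total (background + smoke) truth concentration
#' @param field a `truth_field`.
#' @return cell-by-day matrix of total concentration.
#' @export
truth_total <- function(field) field$background + field$smoke

# ---- coarse CTM pair --------------------------------------------------------

# fine-cell -> coarse-cell index map (1-based), row-major coarse ids
fine_to_coarse <- function(domain, factor) {
  n_x <- attr(domain, "n_x"); n_y <- attr(domain, "n_y")
  if (n_x %% factor != 0 || n_y %% factor != 0) {
    stop("coarsening_factor ", factor, " must divide both grid dimensions (",
         n_x, ", ", n_y, ")")
  }
  cix <- (domain$ix - 1L) %/% factor
  ciy <- (domain$iy - 1L) %/% factor
  as.integer(ciy * (n_x %/% factor) + cix + 1L)
}

block_mean <- function(mat, map, n_coarse) {
  # column-wise mean of mat rows grouped by map (coarse ids 1..n_coarse)
  out <- rowsum(mat, map, reorder = TRUE) / tabulate(map, nbins = n_coarse)
  dimnames(out) <- NULL
  out
}

#' Simulate the paired smoke-on / smoke-off coarse CTM fields
#'
#' Emulates a chemical-transport-model pair run with and without fire
#' emissions: both runs see the same background, only the smoke-on run
#' sees smoke.  Each component is block-averaged to the coarse grid,
#' multiplied by its own bias, and perturbed with additive Gaussian
#' noise, then clipped at zero.
#'
#' @param truth a `truth_set` from [simulate_truth()].
#' @param domain the fine grid the truth lives on.
#' @param bias list with elements `bias_bg`, `bias_smoke`
#'   (multiplicative), `noise_sd` (ug/m3, additive at coarse cell-day
#'   level, shared between the paired runs -- they differ only in fire
#'   emissions, so their errors are common), `smoke_noise_rel`
#'   (multiplicative noise on the smoke component of the smoke-on run),
#'   `pair_noise_sd` (small additive noise independent between the runs)
#'   and `coarsening_factor`.
#' @param seed integer seed.
#' @return object of class `ctm_pair`: per-species `ctm_on` / `ctm_off`
#'   coarse-cell-by-day matrices, the coarsening factor and the
#'   fine-to-coarse index map.
#' @export
simulate_ctm <- function(truth, domain,
                         bias = list(), seed = 2L) {
  b <- utils::modifyList(
    list(bias_bg = 1.2, bias_smoke = 0.6, noise_sd = 0.10,
         smoke_noise_rel = 0.2, pair_noise_sd = 0.02, coarsening_factor = 4),
    bias)
  map <- fine_to_coarse(domain, b$coarsening_factor)
  n_coarse <- length(unique(map))
  set.seed(seed)
  out <- list()
  for (sp in c("OC", "EC")) {
    f <- truth[[sp]]
    bg_c <- block_mean(f$background, map, n_coarse)
    sm_c <- block_mean(f$smoke, map, n_coarse)
    e_shared <- if (b$noise_sd > 0)
      matrix(stats::rnorm(length(bg_c), 0, b$noise_sd), nrow(bg_c)) else 0
    e_off <- if (b$pair_noise_sd > 0)
      matrix(stats::rnorm(length(bg_c), 0, b$pair_noise_sd), nrow(bg_c)) else 0
    e_on <- if (b$pair_noise_sd > 0)
      matrix(stats::rnorm(length(bg_c), 0, b$pair_noise_sd), nrow(bg_c)) else 0
    sm_noise <- if (b$smoke_noise_rel > 0)
      matrix(exp(stats::rnorm(length(bg_c), 0, b$smoke_noise_rel)), nrow(bg_c)) else 1
    out[[sp]] <- list(
      ctm_off = pmax(bg_c * b$bias_bg + e_shared + e_off, 0),
      ctm_on = pmax(bg_c * b$bias_bg + sm_c * b$bias_smoke * sm_noise +
                      e_shared + e_on, 0)
    )
  }
  structure(list(OC = out$OC, EC = out$EC,
                 coarsening_factor = b$coarsening_factor,
                 map = map, n_coarse = n_coarse),
            class = "ctm_pair")
}

# ---- auxiliary predictors ---------------------------------------------------

#' Simulate auxiliary predictor layers
#'
#' Generates the reduced auxiliary set used as model features: an
#' AOD-like daily layer correlated with total carbonaceous concentration
#' with a missing-at-random fraction emulating cloud gaps (flagged as
#' `NA`, never silently imputed here), two meteorology-like daily layers
#' (one seasonal), a static urbanization layer (shared with the truth's
#' urban gradient) and a static elevation-like layer.
#'
#' @param domain grid domain.
#' @param truth `truth_set`.
#' @param missing_frac fraction of AOD cell-days set missing at random.
#' @param seed integer seed.
#' @return object of class `aux_cube`: list of layers; daily layers are
#'   cell-by-day matrices, static layers are vectors.
#' @export
simulate_aux <- function(domain, truth, missing_frac = 0.3, seed = 3L) {
  stopifnot(missing_frac >= 0, missing_frac < 1)
  n_x <- attr(domain, "n_x"); n_y <- attr(domain, "n_y")
  n_days <- truth$OC$n_days
  nc <- nrow(domain)
  set.seed(seed)
  total <- truth_total(truth$OC) + truth_total(truth$EC)
  aod <- 0.1 + 0.12 * total +
    0.05 * matrix(stats::rnorm(nc * n_days), nc)
  aod <- pmax(aod, 0)
  if (missing_frac > 0) {
    aod[stats::runif(nc * n_days) < missing_frac] <- NA_real_
  }
  cal <- sim_calendar(seq_len(n_days))
  tseas <- 15 - 12 * cos(2 * pi * (cal$doy - 15) / 365)
  met_temp <- rep(tseas, each = nc) +
    3 * as.vector(smooth_field(n_x, n_y, 10)) +
    matrix(stats::rnorm(nc * n_days, 0, 1.5), nc)
  met_rh <- 55 + 12 * matrix(stats::rnorm(nc * n_days), nc) * 0.3 +
    8 * as.vector(smooth_field(n_x, n_y, 6))
  elev <- 300 + 200 * as.vector(smooth_field(n_x, n_y, 12))
  structure(list(aod = aod, met_temp = met_temp, met_rh = met_rh,
                 urban = truth$urban, elev = elev,
                 missing_frac = missing_frac, n_days = n_days),
            class = "aux_cube")
}

# ---- monitors ---------------------------------------------------------------

#' Sample synthetic monitor observations
#'
#' Places `n_sites` monitors without replacement, preferentially in
#' high-urbanization cells, and has each site report both species on the
#' same days (co-located, synchronous sampling on a 1-in-`sample_interval`
#' day schedule).  Observed value = truth total + Gaussian noise, clipped
#' at zero.
#'
#' @param domain grid domain.
#' @param truth `truth_set`.
#' @param n_sites number of sites (1..number of cells).
#' @param obs_noise_sd measurement noise sd, ug/m3: either a scalar or a
#'   named per-species vector (default `c(OC = 0.25, EC = 0.08)`;
#'   measurement uncertainty scales with the species' concentration
#'   range).
#' @param urban_oversampling_weight exponent on the urbanization layer in
#'   the site-placement probability; 0 gives uniform placement.
#' @param sample_interval report every `sample_interval`-th day.
#' @param seed integer seed.
#' @return data.frame of class `monitor_records` with columns `site_id`,
#'   `cell_id`, `day_index`, `species`, `value`.
#' @export
sample_monitors <- function(domain, truth, n_sites,
                            obs_noise_sd = c(OC = 0.25, EC = 0.08),
                            urban_oversampling_weight = 2,
                            sample_interval = 3L, seed = 4L) {
  nc <- nrow(domain)
  if (n_sites < 1 || n_sites > nc) {
    stop("n_sites must be between 1 and the number of cells (", nc, ")")
  }
  set.seed(seed)
  if (length(obs_noise_sd) == 1 && is.null(names(obs_noise_sd))) {
    obs_noise_sd <- c(OC = unname(obs_noise_sd), EC = unname(obs_noise_sd))
  }
  w <- truth$urban^urban_oversampling_weight
  cells <- sample.int(nc, n_sites, replace = FALSE, prob = w)
  days <- seq(1L, truth$OC$n_days, by = as.integer(sample_interval))
  site_id <- sprintf("S%04d", seq_len(n_sites))
  recs <- list()
  for (sp in c("OC", "EC")) {
    tot <- truth_total(truth[[sp]])[cells, days, drop = FALSE]
    sd_sp <- obs_noise_sd[[sp]]
    noise <- if (sd_sp > 0)
      matrix(stats::rnorm(length(tot), 0, sd_sp), nrow(tot)) else 0
    val <- pmax(tot + noise, 0)
    recs[[sp]] <- data.frame(
      site_id = rep(site_id, times = length(days)),
      cell_id = rep(domain$cell_id[cells], times = length(days)),
      day_index = rep(days, each = n_sites),
      species = sp,
      value = as.vector(val)
    )
  }
  out <- rbind(recs$OC, recs$EC)
  class(out) <- c("monitor_records", "data.frame")
  out
}

# ---- population -------------------------------------------------------------

#' Simulate a clustered population raster
#'
#' Persons are allocated proportionally to a spatially clustered positive
#' weight raised to `concentration_exponent`, with largest-remainder
#' rounding so the cell counts sum exactly to `total_persons`.
#'
#' @param domain grid domain.
#' @param total_persons total population (> 0).
#' @param concentration_exponent 0 gives near-uniform allocation; larger
#'   values concentrate population in the clustered high-weight cells.
#' @param year label attached to the raster.
#' @param seed integer seed.
#' @return data.frame of class `population_raster` with columns
#'   `cell_id`, `persons`, `year`.
#' @export
simulate_population <- function(domain, total_persons, concentration_exponent = 2,
                                year = 2002L, seed = 5L) {
  if (total_persons <= 0) stop("total_persons must be > 0")
  set.seed(seed)
  w0 <- urban_surface(domain, n_centers = 8) +
    0.1 * exp(as.vector(smooth_field(attr(domain, "n_x"), attr(domain, "n_y"), 6)))
  w <- w0^concentration_exponent
  share <- w / sum(w)
  exact <- share * total_persons
  base <- floor(exact)
  rem <- total_persons - sum(base)
  persons <- base
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    persons[extra] <- persons[extra] + 1
  }
  out <- data.frame(cell_id = domain$cell_id, persons = as.numeric(persons),
                    year = as.integer(year))
  class(out) <- c("population_raster", "data.frame")
  out
}
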