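test_that("make_domain builds complete lattices with exact region tilings", {
  d1 <- make_domain(2, 2, seed = 0)
  expect_equal(nrow(d1), 4)
  expect_equal(unique(d1$region), "all")
  expect_equal(d1$cell_id, 0:3)

  d2 <- make_domain(8, 8, list(a = c(1, 4, 1, 8), b = c(5, 8, 1, 8)), seed = 1)
  expect_equal(as.vector(table(d2$region)), c(32, 32))

  d3 <- make_domain(64, 64, list(q1 = c(1, 32, 1, 32), q2 = c(33, 64, 1, 32),
                                 q3 = c(1, 32, 33, 64), q4 = c(33, 64, 33, 64)),
                    seed = 7)
  expect_equal(nrow(d3), 4096)
  expect_true(all(table(d3$region) == 1024))
})

test_that("make_domain rejects overlapping or non-covering region specs", {
  expect_error(make_domain(4, 4, list(a = c(1, 3, 1, 4), b = c(3, 4, 1, 4))),
               "overlapping")
  expect_error(make_domain(4, 4, list(a = c(1, 2, 1, 4))), "uncovered")
})

test_that("the simulation calendar maps days to months and years", {
  cal <- sim_calendar(c(1L, 182L, 365L, 366L, 730L), start_year = 2002L)
  expect_equal(cal$year, c(2002L, 2002L, 2002L, 2003L, 2003L))
  expect_equal(cal$doy, c(1L, 182L, 365L, 1L, 365L))
  expect_equal(cal$month, c(1L, 7L, 12L, 1L, 12L))  # July 1st is doy 182
  expect_equal(cal$month_index, c(1L, 7L, 12L, 13L, 24L))
})

test_that("zero plume rate gives an identically zero smoke field", {
  dom <- make_domain(8, 8)
  tr <- simulate_truth(dom, 30, params = list(plume_rate = 0), seed = 1)
  expect_true(all(tr$OC$smoke == 0))
  expect_true(all(tr$EC$smoke == 0))
})

test_that("degenerate limits flatten the background spatially", {
  dom <- make_domain(8, 8)
  tr <- simulate_truth(dom, 10,
                       params = list(bg_seasonal_amplitude = 0,
                                     bg_corr_length = Inf,
                                     urban_strength = 0),
                       seed = 2)
  for (d in 1:10) {
    expect_equal(diff(range(tr$OC$background[, d])), 0)
  }
})

test_that("truth invariants hold: nonnegativity, additivity, footprint zeros", {
  w <- small_world()
  for (sp in c("OC", "EC")) {
    f <- w$truth[[sp]]
    expect_true(all(f$background >= 0))
    expect_true(all(f$smoke >= 0))
    expect_equal(truth_total(f), f$background + f$smoke)
  }
  # OC and EC share plume footprints with a fixed intensity ratio
  expect_equal(w$truth$OC$smoke > 0, w$truth$EC$smoke > 0)
  expect_equal(w$truth$OC$smoke,
               w$truth$EC$smoke * w$truth$params$oc_ec_ratio)
})

test_that("plume coverage matches an independent Monte-Carlo footprint oracle", {
  # oracle: simulate only the plume geometry (ignition, drift, duration,
  # truncated footprint) with the same parameter distributions, and record
  # the fraction of cell-days covered, over 50 replicates
  p <- truth_params()
  n_x <- 64L; n_y <- 64L; n_days <- 365L
  dom <- make_domain(n_x, n_y)
  cal <- sim_calendar(seq_len(n_days))
  seas <- exp(p$plume_seasonality * cos(2 * pi * (cal$doy - p$plume_peak_doy) / 365))
  seas <- seas / mean(seas)
  trunc2 <- (p$plume_trunc * p$plume_radius)^2
  oracle_coverage <- function() {
    covered <- matrix(FALSE, n_x * n_y, n_days)
    n_ev <- rpois(n_days, p$plume_rate * seas)
    for (d in which(n_ev > 0)) {
      for (e in seq_len(n_ev[d])) {
        x0 <- runif(1, 0, n_x); y0 <- runif(1, 0, n_y)
        vx <- rnorm(1, 0, p$plume_drift_sd); vy <- rnorm(1, 0, p$plume_drift_sd)
        dur <- 1L + rgeom(1, 1 / p$plume_mean_duration)
        for (a in 0:(dur - 1L)) {
          dd <- d + a
          if (dd > n_days) break
          d2 <- (dom$x - (x0 + a * vx))^2 + (dom$y - (y0 + a * vy))^2
          covered[d2 < trunc2, dd] <- TRUE
        }
      }
    }
    mean(covered)
  }
  set.seed(99)
  reps <- replicate(50, oracle_coverage())
  tr <- simulate_truth(dom, n_days, seed = 11)
  got <- mean(tr$OC$smoke > 0)
  expect_gt(got, mean(reps) - 3 * sd(reps))
  expect_lt(got, mean(reps) + 3 * sd(reps))
})

test_that("same seed reproduces bit-identical truth; different seeds differ", {
  dom <- make_domain(8, 8)
  a <- simulate_truth(dom, 20, seed = 42)
  b <- simulate_truth(dom, 20, seed = 42)
  c <- simulate_truth(dom, 20, seed = 43)
  expect_identical(a$OC$background, b$OC$background)
  expect_identical(a$OC$smoke, b$OC$smoke)
  expect_false(identical(a$OC$background, c$OC$background))
})

test_that("doubling plume intensity doubles the smoke field pointwise", {
  dom <- make_domain(8, 8)
  a <- simulate_truth(dom, 60, seed = 7)
  b <- simulate_truth(dom, 60, params = list(plume_intensity = 8.0), seed = 7)
  expect_equal(b$OC$smoke, 2 * a$OC$smoke, tolerance = 1e-12)
})

test_that("noise-free unit-bias CTM at coarsening 1 reproduces truth smoke exactly", {
  w <- small_world()
  ctm0 <- simulate_ctm(w$truth, w$dom,
                       bias = list(bias_bg = 1, bias_smoke = 1, noise_sd = 0,
                                   smoke_noise_rel = 0, pair_noise_sd = 0,
                                   coarsening_factor = 1),
                       seed = 1)
  for (sp in c("OC", "EC")) {
    expect_equal(ctm0[[sp]]$ctm_on - ctm0[[sp]]$ctm_off,
                 w$truth[[sp]]$smoke, tolerance = 1e-12)
  }
})

test_that("with zero smoke and no noise the paired runs are identical", {
  dom <- make_domain(8, 8)
  tr <- simulate_truth(dom, 20, params = list(plume_rate = 0), seed = 3)
  ctm <- simulate_ctm(tr, dom,
                      bias = list(noise_sd = 0, smoke_noise_rel = 0,
                                  pair_noise_sd = 0, coarsening_factor = 2),
                      seed = 1)
  expect_equal(ctm$OC$ctm_on, ctm$OC$ctm_off)
})

test_that("coarsening produces exact block means", {
  w <- small_world()
  ctm <- simulate_ctm(w$truth, w$dom,
                      bias = list(bias_bg = 1, bias_smoke = 1, noise_sd = 0,
                                  smoke_noise_rel = 0, pair_noise_sd = 0,
                                  coarsening_factor = 4),
                      seed = 1)
  # brute-force block-mean oracle on day 5
  bg <- w$truth$OC$background[, 5]
  oracle <- matrix(NA_real_, 16, 1)
  for (cy in 0:3) for (cx in 0:3) {
    cells <- which((w$dom$ix - 1) %/% 4 == cx & (w$dom$iy - 1) %/% 4 == cy)
    oracle[cy * 4 + cx + 1] <- mean(bg[cells])
  }
  expect_equal(ctm$OC$ctm_off[, 5], as.vector(oracle), tolerance = 1e-12)
  expect_error(simulate_ctm(w$truth, w$dom,
                            bias = list(coarsening_factor = 5), seed = 1),
               "divide")
})

test_that("noiseless monitors report truth totals; full-census placement works", {
  dom <- make_domain(8, 8)
  tr <- simulate_truth(dom, 15, seed = 5)
  mon <- sample_monitors(dom, tr, 10, obs_noise_sd = 0, seed = 1)
  cells <- match(mon$cell_id, dom$cell_id)
  tot <- ifelse(mon$species == "OC",
                truth_total(tr$OC)[cbind(cells, mon$day_index)],
                truth_total(tr$EC)[cbind(cells, mon$day_index)])
  expect_equal(mon$value, tot)

  full <- sample_monitors(dom, tr, 64, urban_oversampling_weight = 0, seed = 2)
  expect_equal(sort(unique(full$cell_id)), dom$cell_id)
  expect_error(sample_monitors(dom, tr, 65, seed = 3), "between 1 and")
})

test_that("monitor records are unique per site-day-species and right-skewed", {
  w <- small_world()
  key <- with(w$mon, paste(site_id, day_index, species))
  expect_equal(anyDuplicated(key), 0L)
  # sample-moment skewness oracle
  v <- w$mon$value[w$mon$species == "OC"]
  skew <- mean((v - mean(v))^3) / (mean((v - mean(v))^2))^1.5
  expect_gt(skew, 0)
})

test_that("population allocation conserves totals and flattens at exponent 0", {
  dom <- make_domain(64, 64)
  pop <- simulate_population(dom, 1e6, concentration_exponent = 2, seed = 5)
  expect_identical(sum(pop$persons), 1e6)
  flat <- simulate_population(dom, 1e5, concentration_exponent = 0, seed = 5)
  expect_lte(diff(range(flat$persons)), 1)
  expect_identical(sum(flat$persons), 1e5)
  expect_error(simulate_population(dom, 0, seed = 1), "> 0")
})

test_that("auxiliary AOD layer has the configured missing fraction, flagged not imputed", {
  w <- small_world()
  frac <- mean(is.na(w$aux$aod))
  expect_gt(frac, 0.27); expect_lt(frac, 0.33)
  expect_true(all(is.finite(w$aux$met_temp)))
  expect_true(all(is.finite(w$aux$elev)))
})
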