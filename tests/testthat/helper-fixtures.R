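# Shared small-scale fixtures, built once per test run and cached.
# All fixtures are generated in code; no files are read.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 16x16 domain, 120 days, 40 sites: fast, exercises every stage
small_world <- function() {
  fixture("small_world", function() {
    dom <- make_domain(16, 16, list(west = c(1, 8, 1, 16),
                                    east = c(9, 16, 1, 16)))
    tr <- simulate_truth(dom, 120, seed = 11)
    ctm <- simulate_ctm(tr, dom, seed = 2)
    aux <- simulate_aux(dom, tr, seed = 3)
    mon <- sample_monitors(dom, tr, 40, seed = 4)
    mask <- classify_scenario(smoke_contribution(ctm), 0.1)
    tabs <- collocate(filter_outliers(mon)$records, dom, mask, ctm, aux)
    pop <- simulate_population(dom, 1e5, seed = 5)
    list(dom = dom, truth = tr, ctm = ctm, aux = aux, mon = mon,
         mask = mask, tabs = tabs, pop = pop)
  })
}

# a fitted RASL stack on the small world's OC smoke-off table
small_fit <- function() {
  fixture("small_fit", function() {
    w <- small_world()
    tab <- smote_enrich(w$tabs$OC.off, seed = 6)
    model <- rasl_fit(tab, k = 3, seed = 10)
    list(tab = tab, model = model)
  })
}

# hand-built training table from a feature data.frame (labels included)
make_table <- function(df, species = "OC", scenario = "off") {
  need <- setdiff(c(feature_names(), "label"), colnames(df))
  if (length(need)) stop("make_table missing: ", paste(need, collapse = ", "))
  if (is.null(df$site_id)) df$site_id <- sprintf("S%03d", seq_len(nrow(df)) %% 23)
  if (is.null(df$day_index)) df$day_index <- seq_len(nrow(df))
  if (is.null(df$cell_id)) df$cell_id <- seq_len(nrow(df)) - 1L
  if (is.null(df$provenance)) df$provenance <- "OBSERVED"
  if (is.null(df$aod_gap_filled)) df$aod_gap_filled <- FALSE
  fs <- as.matrix(df[feature_names()])
  std <- list(mean = colMeans(fs), sd = apply(fs, 2, stats::sd))
  std$sd[std$sd == 0 | !is.finite(std$sd)] <- 1
  attr(df, "species") <- species
  attr(df, "scenario") <- scenario
  attr(df, "standardization") <- std
  class(df) <- c("training_table", "data.frame")
  df
}

# random feature frame with a controllable label rule
random_features <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    ctm = runif(n, 0, 5), aod = runif(n, 0, 2),
    met_temp = rnorm(n, 15, 8), met_rh = runif(n, 30, 90),
    urban = runif(n), elev = rnorm(n, 300, 100),
    x = runif(n, 0, 16), y = runif(n, 0, 16),
    doy = sample(365, n, replace = TRUE),
    year = sample(2002:2003, n, replace = TRUE)
  )
}

# the reference experiment: full default pipeline (64x64, 2 years, 200 sites)
default_run <- function() {
  fixture("default_run", function() run_all(quiet = TRUE))
}

# pooled out-of-fold fused predictions at observed rows for one species
oof_pool <- function(res, species) {
  pool <- NULL
  for (sc in c("on", "off")) {
    tab <- res$tables[[paste(species, sc, sep = ".")]]
    m <- res$models[[paste(species, sc, sep = ".")]]
    obs <- tab$provenance == "OBSERVED"
    fused <- pmax(m$meta$intercept + m$base$oof %*% m$meta$weights, 0)
    pool <- rbind(pool, data.frame(site_id = tab$site_id[obs],
                                   day_index = tab$day_index[obs],
                                   year = tab$year[obs],
                                   obs = tab$label[obs],
                                   pred = fused[obs]))
  }
  pool
}
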