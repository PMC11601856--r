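#' Prediction accuracy metrics
#'
#' R-squared (1 - SSE/SST), root-mean-square error, and the ordinary
#' least squares slope of observed regressed on predicted.
#'
#' @param observed,predicted equal-length numeric vectors (>= 2 values,
#'   nonzero observed variance).
#' @return list with `r2`, `rmse`, `slope`, `n`.
#' @export
eval_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values have zero variance")
  sse <- sum((observed - predicted)^2)
  vp <- stats::var(predicted)
  slope <- if (vp > 0) stats::cov(predicted, observed) / vp else NA_real_
  list(r2 = 1 - sse / sst,
       rmse = sqrt(mean((observed - predicted)^2)),
       slope = slope,
       n = length(observed))
}

# Aggregate pooled daily (obs, pred) pairs to daily/monthly/annual scales
# and compute metrics at each.  Monthly pairs are site-month means with at
# least `min_days_month` daily pairs; annual pairs are site-year means with
# at least `min_days_year`.
cv_report <- function(df, scheme, species, scenario,
                      min_days_month = 4L, min_days_year = 20L) {
  out <- list()
  mk <- function(scale, o, p) {
    m <- eval_metrics(o, p)
    data.frame(scheme = scheme, species = species, scenario = scenario,
               scale = scale, r2 = m$r2, rmse = m$rmse, slope = m$slope,
               n = m$n)
  }
  out$daily <- mk("daily", df$obs, df$pred)
  cal <- sim_calendar(df$day_index, df$year[1] - (df$day_index[1] - 1) %/% 365)
  grp <- paste(df$site_id, cal$month_index)
  agg <- function(v) tapply(v, grp, mean)
  cnt <- tapply(df$obs, grp, length)
  keep <- cnt >= min_days_month
  if (sum(keep) >= 2) out$monthly <- mk("monthly", agg(df$obs)[keep], agg(df$pred)[keep])
  grp_y <- paste(df$site_id, cal$year)
  aggy <- function(v) tapply(v, grp_y, mean)
  cnty <- tapply(df$obs, grp_y, length)
  keepy <- cnty >= min_days_year
  if (sum(keepy) >= 2) out$annual <- mk("annual", aggy(df$obs)[keepy], aggy(df$pred)[keepy])
  do.call(rbind, out)
}

# shared engine: given a fold id per observed row, refit RASL levels 1-2 on
# the complement (plus all synthetic rows) and predict the held-out rows
run_cv <- function(table, fold_id, scheme, k_internal = 5L,
                   learners = default_learners(), seed = 20L,
                   min_days_month = 4L) {
  obs_idx <- which(table$provenance == "OBSERVED")
  syn_idx <- which(table$provenance != "OBSERVED")
  stopifnot(length(fold_id) == length(obs_idx))
  pred <- rep(NA_real_, length(obs_idx))
  for (f in sort(unique(fold_id))) {
    hold <- obs_idx[fold_id == f]
    tr_rows <- c(setdiff(obs_idx, hold), syn_idx)
    tr <- table[tr_rows, , drop = FALSE]
    for (a in c("species", "scenario", "standardization")) {
      attr(tr, a) <- attr(table, a)
    }
    class(tr) <- class(table)
    model <- rasl_fit(tr, k = k_internal, learners = learners, seed = seed + f)
    pred[fold_id == f] <- predict_daily(model, table[hold, , drop = FALSE])
  }
  df <- data.frame(site_id = table$site_id[obs_idx],
                   day_index = table$day_index[obs_idx],
                   year = table$year[obs_idx],
                   obs = table$label[obs_idx], pred = pred,
                   fold = fold_id)
  list(report = cv_report(df, scheme, attr(table, "species"),
                          attr(table, "scenario"),
                          min_days_month = min_days_month),
       predictions = df)
}

#' 10-fold random cross-validation of the RASL levels 1-2
#'
#' Observed rows are partitioned uniformly at random into `k` folds of
#' sizes differing by at most one; the full level-1/level-2 stack is
#' refit per fold and held-out rows predicted.  Synthetic (SMOTE) rows
#' always train, never evaluate.
#'
#' @param table `training_table`.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @param k_internal folds used inside each refit for the out-of-fold
#'   meta-learning.
#' @param learners base-learner families.
#' @return list with `report` (one row per scale) and `predictions`
#'   (pooled held-out daily pairs).
#' @export
random_cv <- function(table, k = 10L, seed = 20L, k_internal = 5L,
                      learners = default_learners()) {
  n_obs <- sum(table$provenance == "OBSERVED")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k), length.out = n_obs))
  run_cv(table, fold_id, "RANDOM_10FOLD", k_internal, learners, seed)
}

#' Clustered spatial cross-validation
#'
#' Sites are grouped into `k` spatial clusters by k-means on their
#' coordinates (20 restarts, fixed seed); all rows of a cluster are held
#' out together, emulating the loss of a whole regional monitoring
#' network.
#'
#' @inheritParams random_cv
#' @return as [random_cv()].
#' @export
spatial_cluster_cv <- function(table, k = 10L, seed = 21L, k_internal = 5L,
                               learners = default_learners()) {
  obs <- table[table$provenance == "OBSERVED", , drop = FALSE]
  sites <- unique(obs[c("site_id", "x", "y")])
  if (k > nrow(sites)) stop("k = ", k, " exceeds the ", nrow(sites), " distinct sites")
  set.seed(seed)
  cluster_of_site <- if (k == nrow(sites)) {
    stats::setNames(seq_len(k), sites$site_id)   # leave-one-site-out
  } else {
    km <- stats::kmeans(as.matrix(sites[c("x", "y")]), centers = k, nstart = 20)
    stats::setNames(km$cluster, sites$site_id)
  }
  fold_id <- as.integer(cluster_of_site[obs$site_id])
  res <- run_cv(table, fold_id, "SPATIAL_CLUSTER_10FOLD", k_internal, learners, seed)
  res$site_cluster <- cluster_of_site
  res
}

#' Leave-one-year-out temporal cross-validation
#'
#' Each simulated year is held out in turn; reports are returned pooled
#' across held-out years and per year.
#'
#' @inheritParams random_cv
#' @return list with `report` (pooled), `per_year` reports and
#'   `predictions`.
#' @export
temporal_loyo_cv <- function(table, seed = 22L, k_internal = 5L,
                             learners = default_learners()) {
  obs_years <- table$year[table$provenance == "OBSERVED"]
  years <- sort(unique(obs_years))
  if (length(years) < 2) stop("temporal CV needs at least 2 distinct years")
  fold_id <- match(obs_years, years)
  res <- run_cv(table, fold_id, "TEMPORAL_LOYO", k_internal, learners, seed)
  res$per_year <- lapply(seq_along(years), function(f) {
    df <- res$predictions[res$predictions$fold == f, , drop = FALSE]
    cv_report(df, "TEMPORAL_LOYO", attr(table, "species"),
              attr(table, "scenario"))
  })
  names(res$per_year) <- years
  res
}

#' Permutation feature importance
#'
#' Mean decrease in in-sample R-squared on observed rows when one
#' feature column is permuted, averaged over `n_repeats` permutations;
#' returned in descending order of importance.
#'
#' @param model fitted `rasl_model`.
#' @param table `training_table`.
#' @param seed integer seed.
#' @param n_repeats permutations per feature.
#' @return data.frame with `feature` and `importance` (mean r2 drop).
#' @export
permutation_importance <- function(model, table, seed = 23L, n_repeats = 5L) {
  obs <- table[table$provenance == "OBSERVED", , drop = FALSE]
  base_r2 <- eval_metrics(obs$label, predict_daily(model, obs))$r2
  set.seed(seed)
  imp <- vapply(model$feature_names, function(fn) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      perm <- obs
      perm[[fn]] <- sample(perm[[fn]])
      base_r2 - eval_metrics(obs$label, predict_daily(model, perm))$r2
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out[order(-out$importance), , drop = FALSE]
}
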