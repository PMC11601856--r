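# ---- fold assignment --------------------------------------------------------

# Deterministic fold assignment keyed by (site_id, day_index): invariant to
# row order.  Multiplicative-congruential hash kept below 2^53 so the double
# arithmetic is exact.
fold_of_key <- function(site_id, day_index, k, seed) {
  sh <- vapply(site_id, function(s) {
    u <- utf8ToInt(s)
    h <- 0
    for (ch in u) h <- (h * 131 + ch) %% 100003
    h
  }, numeric(1))
  key <- (sh * 40000 + (day_index %% 40000)) %% 2147483647
  h <- (69069 * key + seed * 7919 + 12345) %% 2147483647
  h <- (69069 * h + 362437) %% 2147483647
  as.integer(h %% k) + 1L
}

std_matrix <- function(table, std) {
  X <- as.matrix(table[feature_names()])
  sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
}

# ---- level 1 ----------------------------------------------------------------

#' Fit the four base learners with out-of-fold predictions
#'
#' Level 1 of the super learner.  Rows are assigned to `k` folds by a
#' deterministic hash of (site, day), each learner is trained on k-1
#' folds to predict the held-out fold (filling the out-of-fold matrix
#' with predictions from models that never saw the row), and finally
#' refit on all rows.  SMOTE-synthetic rows participate in training and
#' receive out-of-fold predictions for meta-fitting, but are excluded
#' from any reported metric downstream.
#'
#' @param table a `training_table`.
#' @param k number of folds (>= 2).
#' @param learners character vector of learner family names
#'   (see `default_learners`: rf, gbm, enet, knn).
#' @param seed integer seed.
#' @return list with `models` (refit on all rows), `oof` (row-by-learner
#'   matrix of out-of-fold predictions), `folds`, `learners`,
#'   `standardization`.
#' @export
fit_base_learners <- function(table, k = 5L, learners = default_learners(),
                              seed = 10L) {
  stopifnot(k >= 2)
  if (sum(table$provenance == "OBSERVED") < k * 10) {
    stop("need at least k x 10 observed rows (have ",
         sum(table$provenance == "OBSERVED"), ")")
  }
  std <- attr(table, "standardization")
  # train in key-sorted order so results are invariant to input row order
  ord <- order(table$site_id, table$day_index, table$provenance, table$label)
  X <- std_matrix(table, std)[ord, , drop = FALSE]
  y <- table$label[ord]
  folds_s <- fold_of_key(table$site_id, table$day_index, k, seed)[ord]
  for (f in seq_len(k)) {
    if (length(unique(y[folds_s != f])) < 2) {
      stop("degenerate fold ", f, ": training labels have a single unique value")
    }
  }
  oof_s <- matrix(NA_real_, nrow(X), length(learners),
                  dimnames = list(NULL, learners))
  models <- list()
  for (j in seq_along(learners)) {
    nm <- learners[j]
    for (f in seq_len(k)) {
      tr <- folds_s != f
      m <- fit_learner(nm, X[tr, , drop = FALSE], y[tr], seed + 100 * j + f)
      oof_s[!tr, j] <- predict_learner(m, X[!tr, , drop = FALSE])
    }
    models[[nm]] <- fit_learner(nm, X, y, seed + 100 * j)
  }
  oof <- oof_s
  oof[ord, ] <- oof_s
  folds <- folds_s
  folds[ord] <- folds_s
  list(models = models, oof = oof, folds = folds, learners = learners,
       standardization = std)
}

# ---- level 2 ----------------------------------------------------------------

#' Fit the stacking meta-learner
#'
#' Non-negative least squares (Lawson-Hanson) of the labels on the
#' out-of-fold base predictions, with a free-signed intercept obtained
#' by including +1 and -1 intercept columns in the non-negative design.
#' A rank-deficient out-of-fold matrix triggers a ridge-stabilized solve
#' with a warning.
#'
#' @param oof out-of-fold prediction matrix (complete and finite).
#' @param labels training labels.
#' @return list with `intercept` and non-negative `weights` (named by
#'   learner).
#' @export
fit_meta_learner <- function(oof, labels) {
  labels <- as.vector(labels)
  stopifnot(all(is.finite(oof)), all(is.finite(labels)),
            nrow(oof) == length(labels))
  A <- cbind(`+i` = 1, `-i` = -1, oof)
  if (qr(A)$rank < ncol(oof) + 1) {
    warning("rank-deficient out-of-fold matrix; using ridge-stabilized NNLS")
    lam <- sqrt(1e-6 * nrow(A))
    A2 <- rbind(A, cbind(0, 0, diag(lam, ncol(oof))))
    b2 <- c(labels, rep(0, ncol(oof)))
    w <- pracma::lsqnonneg(A2, b2)$x
  } else {
    w <- pracma::lsqnonneg(A, labels)$x
  }
  weights <- w[-(1:2)]
  names(weights) <- colnames(oof)
  list(intercept = w[1] - w[2], weights = weights)
}

meta_combine <- function(meta, base_pred) {
  as.vector(meta$intercept + base_pred %*% meta$weights)
}

#' Fit a full RASL model (levels 1 and 2) for one species x scenario
#'
#' @inheritParams fit_base_learners
#' @return object of class `rasl_model` with the fitted base models,
#'   out-of-fold matrix, meta weights and standardization constants; the
#'   level-3 residual smoother is attached later by
#'   [fit_residual_smoother()].
#' @export
rasl_fit <- function(table, k = 5L, learners = default_learners(), seed = 10L) {
  lv1 <- fit_base_learners(table, k = k, learners = learners, seed = seed)
  meta <- fit_meta_learner(lv1$oof, table$label)
  structure(list(species = attr(table, "species"),
                 scenario = attr(table, "scenario"),
                 base = lv1, meta = meta,
                 feature_names = feature_names(),
                 standardization = lv1$standardization,
                 residual_smoother = NULL),
            class = "rasl_model")
}

#' Predict daily concentrations from a fitted RASL model
#'
#' Standardizes the supplied features with the model's stored constants,
#' obtains each base learner's prediction, combines them with the meta
#' weights and clips at zero.
#'
#' @param model a `rasl_model`.
#' @param features data.frame containing every model feature column.
#' @return numeric vector of fused predictions (>= 0), one per row.
#' @export
predict_daily <- function(model, features) {
  missing_f <- setdiff(model$feature_names, colnames(features))
  if (length(missing_f)) {
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  }
  extra <- setdiff(setdiff(colnames(features), model$feature_names),
                   c("cell_id", "day_index", "site_id", "species", "label",
                     "aod_gap_filled", "provenance", "scenario_on"))
  if (length(extra)) {
    stop("unseen feature column(s): ", paste(extra, collapse = ", "))
  }
  X <- as.matrix(features[model$feature_names])
  X <- sweep(sweep(X, 2, model$standardization$mean), 2,
             model$standardization$sd, "/")
  B <- vapply(model$base$models,
              function(m) predict_learner(m, X), numeric(nrow(X)))
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  pmax(0, meta_combine(model$meta, B))
}

# ---- level 3: monthly residual smoother ------------------------------------

#' Fit the monthly spatiotemporal residual smoother
#'
#' Level 3 of RASL: the monthly residual r = observed - fused prediction
#' at monitor cells is modelled as an additive penalized smooth of space
#' and time, `r ~ te(x, y) + s(month_index)`, with smoothing parameters
#' chosen by GCV.  Monitor-months with fewer than `min_days` daily pairs
#' are dropped as unstable.  The basis is shrunk automatically (with a
#' warning) when there are fewer points than basis functions.
#'
#' @param monthly data.frame with columns `x`, `y`, `month_index`,
#'   `obs`, `pred`, `n_days`.
#' @param k_space per-margin spatial tensor basis dimension (default 5).
#' @param k_time temporal basis dimension (default 6).
#' @param temporal_bs temporal basis: `"cr"` (default, running month
#'   index) or `"cc"` (cyclic over month of year).
#' @param min_days minimum daily pairs per monitor-month.
#' @return object of class `residual_smoother` wrapping the fitted
#'   [mgcv::gam()].
#' @export
fit_residual_smoother <- function(monthly, k_space = 5, k_time = 6,
                                  temporal_bs = c("cr", "cc"), min_days = 4L) {
  temporal_bs <- match.arg(temporal_bs)
  d <- monthly[monthly$n_days >= min_days, , drop = FALSE]
  if (nrow(d) < 20) stop("need at least 20 monitor-months (have ", nrow(d), ")")
  d$r <- d$obs - d$pred
  n_mon <- length(unique(d$month_index))
  kt <- min(k_time, max(3L, n_mon - 1L))   # capped by available months
  ks <- k_space
  while (nrow(d) < ks^2 + kt + 1 && ks > 3) ks <- ks - 1
  if (ks < k_space) {
    warning("shrinking spatial smoother basis to te(", ks, ",", ks,
            ") for ", nrow(d), " monitor-months")
  }
  tvar <- if (temporal_bs == "cc") (d$month_index - 1) %% 12 + 1 else d$month_index
  d$tvar <- tvar
  fit <- if (n_mon >= 3) {
    mgcv::gam(r ~ te(x, y, k = c(ks, ks)) + s(tvar, k = kt, bs = temporal_bs),
              data = d, method = "GCV.Cp")
  } else {
    mgcv::gam(r ~ te(x, y, k = c(ks, ks)), data = d, method = "GCV.Cp")
  }
  structure(list(fit = fit, temporal_bs = temporal_bs, min_days = min_days),
            class = "residual_smoother")
}

#' Evaluate the residual smoother
#' @param smoother a `residual_smoother`.
#' @param x,y cell-center coordinates.
#' @param month_index running month index (1-based).
#' @return predicted residual adjustment (ug/m3).
#' @export
predict_residual <- function(smoother, x, y, month_index) {
  tvar <- if (smoother$temporal_bs == "cc") (month_index - 1) %% 12 + 1 else month_index
  as.vector(mgcv::predict.gam(smoother$fit,
                              newdata = data.frame(x = x, y = y, tvar = tvar)))
}

#' Apply the monthly residual adjustment to a concentration cube
#'
#' `adjusted_month = max(0, predicted_month + r_hat(x, y, month))`; the
#' annual layer is recomputed as the mean of adjusted months.  Daily
#' layers are left untouched: the adjustment is defined at monthly scale
#' only.
#'
#' @param monthly cell-by-month matrix of fused monthly means.
#' @param domain grid domain (supplies cell coordinates).
#' @param smoother a `residual_smoother` fitted for the same
#'   species/scenario.
#' @param months_per_year months per simulated year (12).
#' @return list with `monthly` (adjusted), `annual` (cell-by-year means
#'   of adjusted months) and `adjustment` (the raw smoother surface).
#' @export
apply_adjustment <- function(monthly, domain, smoother, months_per_year = 12L) {
  n_m <- ncol(monthly)
  adj <- matrix(0, nrow(monthly), n_m)
  for (m in seq_len(n_m)) {
    adj[, m] <- predict_residual(smoother, domain$x, domain$y, m)
  }
  adjusted <- pmax(monthly + adj, 0)
  n_y <- n_m %/% months_per_year
  annual <- if (n_y >= 1) {
    vapply(seq_len(n_y), function(yy) {
      rowMeans(adjusted[, ((yy - 1) * months_per_year + 1):(yy * months_per_year),
                        drop = FALSE])
    }, numeric(nrow(monthly)))
  } else {
    matrix(rowMeans(adjusted), ncol = 1)
  }
  list(monthly = adjusted, annual = annual, adjustment = adj)
}

# ---- cubes ------------------------------------------------------------------

#' Aggregate a daily cube to monthly and annual means
#'
#' @param daily cell-by-day matrix.
#' @param start_year calendar year of day 1.
#' @return list with `monthly` (cell-by-month, exact arithmetic mean of
#'   available days), `annual` (cell-by-year), `month_index`, `years`.
#' @export
aggregate_cube <- function(daily, start_year = 2002L) {
  cal <- sim_calendar(seq_len(ncol(daily)), start_year)
  mi <- cal$month_index
  monthly <- t(rowsum(t(daily), mi, reorder = TRUE))
  monthly <- sweep(monthly, 2, as.vector(tabulate(mi)[sort(unique(mi))]), "/")
  yi <- cal$year
  annual <- t(rowsum(t(daily), yi, reorder = TRUE))
  annual <- sweep(annual, 2, as.vector(table(yi)), "/")
  dimnames(monthly) <- NULL
  dimnames(annual) <- NULL
  list(monthly = monthly, annual = annual,
       month_index = sort(unique(mi)), years = sort(unique(yi)))
}
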