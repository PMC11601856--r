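test_that("a realizable linear target is recovered by the penalized linear learner", {
  df <- random_features(300, seed = 2)
  df$label <- 2 * df$ctm + 1          # deterministic linear function
  tab <- make_table(df)
  fit <- fit_base_learners(tab, k = 3, learners = c("enet"), seed = 1)
  o <- eval_metrics(tab$label, fit$oof[, "enet"])
  expect_gte(o$r2, 0.999)
})

test_that("out-of-fold predictions never leak the held-out labels", {
  # true no-leakage audit: perturbing one fold's labels must not change
  # that fold's out-of-fold predictions (the models that produced them
  # never saw those rows)
  df <- random_features(120, seed = 3)
  df$label <- df$ctm + 0.2 * rnorm(120)
  tab <- make_table(df)
  f1 <- fit_base_learners(tab, k = 2, seed = 7)
  hold <- f1$folds == 1
  tab2 <- tab
  tab2$label[hold] <- tab2$label[hold] + 10
  f2 <- fit_base_learners(tab2, k = 2, seed = 7)
  expect_identical(f2$folds, f1$folds)
  expect_equal(f1$oof[hold, ], f2$oof[hold, ], tolerance = 1e-12)
  # and the complement's oof values DO change (labels entered training)
  expect_gt(max(abs(f1$oof[!hold, ] - f2$oof[!hold, ])), 0.1)
})

test_that("out-of-fold values are invariant to row permutation", {
  df <- random_features(150, seed = 4)
  df$label <- df$ctm + df$aod + 0.1 * rnorm(150)
  tab <- make_table(df)
  f1 <- fit_base_learners(tab, k = 3, seed = 5)
  set.seed(99)
  perm <- sample(nrow(tab))
  tabp <- tab[perm, ]
  attr(tabp, "standardization") <- attr(tab, "standardization")
  attr(tabp, "species") <- "OC"; attr(tabp, "scenario") <- "off"
  class(tabp) <- class(tab)
  f2 <- fit_base_learners(tabp, k = 3, seed = 5)
  expect_equal(f2$oof[order(perm), ], f1$oof, tolerance = 1e-9)
})

test_that("degenerate folds are rejected by name", {
  df <- random_features(40, seed = 5)
  df$label <- rep(1, 40)
  tab <- make_table(df)
  expect_error(fit_base_learners(tab, k = 2, seed = 1), "degenerate fold")
})

test_that("a perfect base learner receives weight one and fused R2 of one", {
  set.seed(6)
  y <- runif(200, 0, 5)
  oof <- cbind(perfect = y, junk1 = runif(200), junk2 = runif(200))
  meta <- fit_meta_learner(oof, y)
  expect_equal(unname(meta$weights["perfect"]), 1, tolerance = 1e-6)
  fused <- meta$intercept + oof %*% meta$weights
  expect_gte(eval_metrics(y, as.vector(fused))$r2, 1 - 1e-10)
})

test_that("identical columns leave the fused prediction invariant to weight split", {
  set.seed(7)
  b <- runif(150, 0, 3)
  y <- b + rnorm(150, 0, 0.1)
  oof <- cbind(a = b, b = b, c = runif(150))
  meta <- suppressWarnings(fit_meta_learner(oof, y))
  fused <- meta$intercept + oof %*% meta$weights
  # prediction depends only on the weight sum over the duplicated columns
  combined <- meta$weights["a"] + meta$weights["b"]
  alt <- meta
  alt$weights[c("a", "b")] <- c(combined, 0)
  fused_alt <- alt$intercept + oof %*% alt$weights
  expect_equal(fused, fused_alt, tolerance = 1e-10)
})

test_that("NNLS meta-learner matches a projected-gradient oracle", {
  set.seed(8)
  oof <- matrix(runif(200 * 4, 0, 4), 200)
  colnames(oof) <- paste0("b", 1:4)
  y <- oof %*% c(0.5, 0.3, 0, 0.2) + rnorm(200, 0, 0.2)
  meta <- fit_meta_learner(oof, y)
  A <- cbind(1, -1, oof)
  w_fit <- c(max(meta$intercept, 0), max(-meta$intercept, 0), meta$weights)
  obj_fit <- sum((A %*% w_fit - y)^2)
  # brute-force projected gradient on the same nonnegative design
  w <- rep(0, 6)
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  Aty <- crossprod(A, y)
  AtA <- crossprod(A)
  for (i in 1:200000) {
    w <- pmax(0, w - (AtA %*% w - Aty) / L)
  }
  obj_pg <- sum((A %*% w - y)^2)
  expect_lte(obj_fit, obj_pg + 1e-8)          # the exact solver can't be worse
  expect_lt(abs(obj_fit - obj_pg) / obj_pg, 1e-6)
})

test_that("fused out-of-fold R2 dominates every single base learner", {
  sf <- small_fit()
  obs <- sf$tab$provenance == "OBSERVED"
  y <- sf$tab$label
  fused <- sf$model$meta$intercept +
    sf$model$base$oof %*% sf$model$meta$weights
  r2_fused <- eval_metrics(y[obs], fused[obs])$r2
  r2_each <- apply(sf$model$base$oof[obs, ], 2,
                   function(p) eval_metrics(y[obs], p)$r2)
  expect_gte(r2_fused, max(r2_each) - 0.01)
})

# hand-built rasl_model with stub base learners for prediction contracts
stub_model <- function(weights, intercept = 0) {
  fns <- list(
    function(fit, X) X[, "ctm"],
    function(fit, X) X[, "aod"],
    function(fit, X) rep(0, nrow(X)),
    function(fit, X) rep(1, nrow(X))
  )
  models <- lapply(fns, function(f) list(fit = NULL, predict_fn = f))
  names(models) <- paste0("m", 1:4)
  std <- list(mean = stats::setNames(rep(0, 10), feature_names()),
              sd = stats::setNames(rep(1, 10), feature_names()))
  structure(list(species = "OC", scenario = "off",
                 base = list(models = models),
                 meta = list(intercept = intercept,
                             weights = stats::setNames(weights, names(models))),
                 feature_names = feature_names(),
                 standardization = std, residual_smoother = NULL),
            class = "rasl_model")
}

test_that("prediction is the meta-weighted base combination, clipped at zero", {
  df <- random_features(50, seed = 9)
  # weights (1,0,0,0) reproduce base 1 exactly
  m1 <- stub_model(c(1, 0, 0, 0))
  expect_equal(predict_daily(m1, df), pmax(df$ctm, 0))
  # all-zero bases and zero intercept give zero
  m0 <- stub_model(c(0, 0, 1, 0))
  expect_equal(predict_daily(m0, df), rep(0, 50))
  # negative fused values clip at zero
  mneg <- stub_model(c(0, 0, 0, 1), intercept = -2)
  expect_equal(predict_daily(mneg, df), rep(0, 50))
  expect_error(predict_daily(m1, df[setdiff(names(df), "ctm")]),
               "missing feature")
})

test_that("fused predictions equal an independently recomputed weighted sum", {
  sf <- small_fit()
  sub <- sf$tab[1:200, ]
  got <- predict_daily(sf$model, sub)
  X <- as.matrix(sub[feature_names()])
  std <- sf$model$standardization
  Xs <- sweep(sweep(X, 2, std$mean), 2, std$sd, "/")
  acc <- rep(sf$model$meta$intercept, nrow(sub))
  for (nm in names(sf$model$base$models)) {
    bp <- smokecarbon:::predict_learner(sf$model$base$models[[nm]], Xs)
    acc <- acc + sf$model$meta$weights[[nm]] * bp
  }
  expect_equal(got, unname(pmax(acc, 0)), tolerance = 1e-10)
})

test_that("the residual smoother vanishes on zero residuals and absorbs constants", {
  set.seed(10)
  mf <- data.frame(x = runif(80, 0, 16), y = runif(80, 0, 16),
                   month_index = rep(1:8, 10), n_days = 10L)
  mf$pred <- runif(80, 1, 3)
  mf$obs <- mf$pred                          # zero residual
  sm0 <- suppressWarnings(fit_residual_smoother(mf))
  adj <- predict_residual(sm0, runif(20, 0, 16), runif(20, 0, 16),
                          sample(8, 20, TRUE))
  expect_lte(max(abs(adj)), 1e-6)

  mf$obs <- mf$pred + 0.7                    # constant residual
  smc <- suppressWarnings(fit_residual_smoother(mf))
  adjc <- predict_residual(smc, runif(20, 0, 16), runif(20, 0, 16),
                           sample(8, 20, TRUE))
  expect_equal(adjc, rep(0.7, 20), tolerance = 1e-3)
})

test_that("residual smoothing reduces out-of-sample error on a smooth bias surface", {
  set.seed(11)
  n_site <- 60
  xs <- runif(n_site, 0, 16); ys <- runif(n_site, 0, 16)
  s_true <- function(x, y) 0.5 * sin(x / 3) + 0.4 * cos(y / 4)
  mf <- do.call(rbind, lapply(1:6, function(m) {
    data.frame(x = xs, y = ys, month_index = m, n_days = 10L,
               pred = runif(n_site, 1, 2),
               r = s_true(xs, ys) + rnorm(n_site, 0, 0.15))
  }))
  mf$obs <- mf$pred + mf$r
  train_sites <- seq_len(n_site) <= 42
  tr <- mf[mf$x %in% xs[train_sites], ]
  te <- mf[!(mf$x %in% xs[train_sites]), ]
  sm <- suppressWarnings(fit_residual_smoother(tr))
  adj <- predict_residual(sm, te$x, te$y, te$month_index)
  rmse_adj <- sqrt(mean((te$obs - (te$pred + adj))^2))
  rmse_raw <- sqrt(mean((te$obs - te$pred)^2))
  expect_lt(rmse_adj, rmse_raw)
})

test_that("monthly adjustment clips at zero and leaves a zero smoother inert", {
  w <- small_world()
  set.seed(12)
  mf <- data.frame(x = runif(60, 0, 16), y = runif(60, 0, 16),
                   month_index = rep(1:4, 15), n_days = 8L)
  mf$pred <- runif(60); mf$obs <- mf$pred
  sm0 <- suppressWarnings(fit_residual_smoother(mf))
  monthly <- matrix(runif(nrow(w$dom) * 4, 0, 2), nrow(w$dom))
  out <- apply_adjustment(monthly, w$dom, sm0)
  expect_equal(out$monthly, monthly, tolerance = 1e-5)

  mf$obs <- mf$pred - 0.8                    # constant -0.8 residual
  smn <- suppressWarnings(fit_residual_smoother(mf))
  low <- matrix(0.5, nrow(w$dom), 4)
  outn <- apply_adjustment(low, w$dom, smn)
  expect_equal(outn$monthly, matrix(0, nrow(w$dom), 4), tolerance = 1e-2)
})

test_that("monthly aggregates are exact arithmetic means of available days", {
  set.seed(13)
  daily <- matrix(runif(20 * 400), 20)
  agg <- aggregate_cube(daily, start_year = 2002L)
  cal <- sim_calendar(1:400)
  # brute-force oracle for one cell and every month
  for (m in unique(cal$month_index)) {
    expect_equal(agg$monthly[7, which(unique(cal$month_index) == m)],
                 mean(daily[7, cal$month_index == m]), tolerance = 1e-12)
  }
  expect_equal(agg$annual[3, 1], mean(daily[3, cal$year == 2002]),
               tolerance = 1e-12)
})

test_that("too few monitor-months is an error; sparse data shrinks the basis", {
  mf <- data.frame(x = 1:10, y = 1:10, month_index = 1, n_days = 10L,
                   pred = 1, obs = 2)
  expect_error(fit_residual_smoother(mf), "at least 20")
  mf2 <- do.call(rbind, lapply(1:3, function(m)
    data.frame(x = runif(8), y = runif(8), month_index = m, n_days = 10L,
               pred = 1, obs = rnorm(8, 2))))
  expect_warning(fit_residual_smoother(mf2), "shrinking")
})
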