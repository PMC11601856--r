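# Heterogeneous base-learner registry.  Each entry fits on a standardized
# numeric feature matrix and returns an object with a `predict_fn`.
# Families: random-forest/bagged trees (ranger), gradient-boosted trees
# (xgboost), elastic-net penalized linear regression (glmnet), and
# k-nearest-neighbour regression (caret::knnreg).

default_learners <- function() c("rf", "gbm", "enet", "knn")

# k-NN keeps at most this many reference rows (seeded subsample) so that
# full-cube prediction remains tractable.
KNN_MAX_REF <- 5000L

fit_learner <- function(name, X, y, seed) {
  set.seed(seed)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  nms <- colnames(X)
  obj <- switch(
    name,
    rf = {
      m <- ranger::ranger(x = X, y = y, num.trees = 100,
                          min.node.size = 50, sample.fraction = 0.632,
                          seed = seed, num.threads = 1)
      list(fit = m,
           predict_fn = function(fit, Xn) {
             colnames(Xn) <- nms
             stats::predict(fit, data = Xn, num.threads = 1)$predictions
           })
    },
    gbm = {
      m <- xgboost::xgboost(x = X, y = y, nrounds = 120,
                            max_depth = 6, learning_rate = 0.1,
                            subsample = 0.8, colsample_bytree = 0.8,
                            nthreads = 1, seed = seed,
                            objective = "reg:squarederror", verbosity = 0)
      list(fit = m, predict_fn = function(fit, Xn) stats::predict(fit, Xn))
    },
    enet = {
      m <- glmnet::cv.glmnet(X, y, alpha = 0.5, nfolds = 5)
      list(fit = m,
           predict_fn = function(fit, Xn)
             as.vector(stats::predict(fit, Xn, s = "lambda.min")))
    },
    knn = {
      idx <- if (nrow(X) > KNN_MAX_REF)
        sample.int(nrow(X), KNN_MAX_REF) else seq_len(nrow(X))
      m <- caret::knnreg(X[idx, , drop = FALSE], y[idx],
                         k = min(10L, length(idx) - 1L))
      list(fit = m, predict_fn = function(fit, Xn) stats::predict(fit, Xn))
    },
    stop("unknown learner family: ", name)
  )
  obj$name <- name
  obj
}

predict_learner <- function(obj, Xn) obj$predict_fn(obj$fit, Xn)
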