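#' Random forest configuration
#'
#' Defaults are the tuned reference settings: 500 trees, `mtry = 2000`
#' (capped at the number of available markers, so small panels remain
#' valid) and a minimum terminal-node size of 5.
#'
#' @param ntree number of trees.
#' @param mtry features sampled per split; `NULL` resolves to
#'   `min(2000, m)` at fit time.
#' @param nodesize minimum terminal-node size.
#' @param seed integer RNG seed.
#' @return A validated config list of class `rfConfig`.
#' @export
rfConfig <- function(ntree = 500, mtry = NULL, nodesize = 5, seed = 1) {
  .check(ntree >= 1, "ntree must be >= 1")
  .check(is.null(mtry) || mtry >= 1, "mtry must be >= 1")
  structure(list(ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 nodesize = as.integer(nodesize), seed = as.integer(seed)),
            class = "rfConfig")
}

#' Fit a random forest regressor
#'
#' Ensemble of regression trees on bootstrap samples with `mtry`-feature
#' splits (backed by \pkg{ranger}, single-threaded for determinism).
#' Predictions are the tree mean; the out-of-bag MSE is reported in the
#' `oobMSE` slot.
#'
#' @param y numeric training phenotypes.
#' @param X training genotype-code matrix (samples x markers, complete).
#' @param config an [rfConfig()].
#' @return An [RFModel-class].
#' @export
fitRandomForest <- function(y, X, config = rfConfig()) {
  stopifnot(inherits(config, "rfConfig"))
  X <- as.matrix(X)
  .check(!anyNA(X), "training genotypes must be complete")
  m <- ncol(X)
  mtry <- if (is.null(config$mtry)) min(2000L, m) else config$mtry
  .check(mtry <= m, "mtry (%d) exceeds the number of features (%d)", mtry, m)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(m))
  fit <- ranger::ranger(x = X, y = y,
                        num.trees = config$ntree, mtry = mtry,
                        min.node.size = config$nodesize,
                        num.threads = 1L, seed = config$seed,
                        oob.error = TRUE, verbose = FALSE)
  new("RFModel", method = "rf", nFeatures = m, fit = fit,
      oobMSE = fit$prediction.error,
      config = c(unclass(config), list(mtryUsed = mtry)))
}

#' @describeIn fitRandomForest tree-mean prediction for new individuals.
#' @param object a fitted [RFModel-class].
#' @param newdata genotype-code matrix (samples x markers).
#' @export
setMethod("predict", "RFModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  .check(ncol(newdata) == object@nFeatures,
         "column mismatch: model expects %d markers", object@nFeatures)
  colnames(newdata) <- object@fit$forest$independent.variable.names
  stats::predict(object@fit, data = newdata, num.threads = 1L)$predictions
})

#' Gradient boosting configuration
#'
#' Defaults are the tuned reference settings: learning rate 0.10, tree
#' depth 3, 80% subsampling per boosting iteration, and early stopping
#' when the held-out MSE has not improved for 50 rounds.
#'
#' @param learningRate shrinkage in (0, 1].
#' @param maxDepth tree depth.
#' @param subsample row fraction bagged per iteration.
#' @param earlyStoppingRounds stop after this many rounds without
#'   improvement on the holdout.
#' @param maxTrees upper bound on boosting iterations.
#' @param validationFraction fraction of the training data held out for
#'   early stopping.
#' @param seed integer RNG seed.
#' @return A validated config list of class `gbConfig`.
#' @export
gbConfig <- function(learningRate = 0.10, maxDepth = 3, subsample = 0.80,
                     earlyStoppingRounds = 50, maxTrees = 5000,
                     validationFraction = 0.20, seed = 1) {
  .check(learningRate >= 0 && learningRate <= 1,
         "learningRate must be in [0, 1]")
  .check(maxDepth >= 1, "maxDepth must be >= 1")
  .check(validationFraction > 0 && validationFraction < 1,
         "validationFraction must be in (0, 1)")
  structure(list(learningRate = learningRate, maxDepth = as.integer(maxDepth),
                 subsample = subsample,
                 earlyStoppingRounds = as.integer(earlyStoppingRounds),
                 maxTrees = as.integer(maxTrees),
                 validationFraction = validationFraction,
                 seed = as.integer(seed)),
            class = "gbConfig")
}

#' Fit gradient-boosted regression trees
#'
#' Boosted depth-limited trees with shrinkage (backed by \pkg{xgboost},
#' single-threaded). A fixed random `validationFraction` of the training
#' data is held out; training stops once the holdout MSE has not improved
#' for `earlyStoppingRounds` rounds and the best iteration is retained.
#'
#' @param y numeric training phenotypes.
#' @param X training genotype-code matrix (samples x markers, complete).
#' @param config a [gbConfig()].
#' @return A [GBModel-class].
#' @export
fitGradientBoosting <- function(y, X, config = gbConfig()) {
  stopifnot(inherits(config, "gbConfig"))
  X <- as.matrix(X)
  .check(!anyNA(X), "training genotypes must be complete")
  n <- nrow(X)
  nVal <- max(2L, round(config$validationFraction * n))
  .check(n - nVal >= 2, "too few records to hold out a validation split")
  set.seed(config$seed)
  valIdx <- sample.int(n, nVal)
  dtrain <- xgboost::xgb.DMatrix(X[-valIdx, , drop = FALSE],
                                 label = y[-valIdx], nthread = 1)
  dval <- xgboost::xgb.DMatrix(X[valIdx, , drop = FALSE],
                               label = y[valIdx], nthread = 1)
  params <- list(objective = "reg:squarederror",
                 eta = config$learningRate,
                 max_depth = config$maxDepth,
                 subsample = config$subsample,
                 base_score = mean(y[-valIdx]),
                 nthread = 1, seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$maxTrees,
                                evals = list(val = dval),
                                early_stopping_rounds = config$earlyStoppingRounds,
                                verbose = 0)
  best <- xgboost::xgb.attr(booster, "best_iteration")
  best <- if (is.null(best)) config$maxTrees else as.integer(best) + 1L
  new("GBModel", method = "gb", nFeatures = ncol(X), fit = booster,
      bestIter = best, config = unclass(config))
}

#' @describeIn fitGradientBoosting best-iteration prediction for new
#'   individuals.
#' @param object a fitted [GBModel-class].
#' @param newdata genotype-code matrix (samples x markers).
#' @export
setMethod("predict", "GBModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  .check(ncol(newdata) == object@nFeatures,
         "column mismatch: model expects %d markers", object@nFeatures)
  stats::predict(object@fit,
                 xgboost::xgb.DMatrix(newdata, nthread = 1),
                 iterationrange = c(1, object@bestIter))
})
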