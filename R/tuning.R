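#' Exhaustive hyperparameter grid evaluation
#'
#' Evaluates every row of a configuration grid under the requested scheme
#' and returns the minimum-MSE configuration together with the full score
#' table. Scheme `"oob"` (random forest only) scores each configuration by
#' its out-of-bag MSE; `"cv5"` scores by five-fold cross-validated MSE
#' with folds shared across configurations.
#'
#' @param method one of `"rf"`, `"gb"`, `"mlp"`, `"cnn"`.
#' @param grid data.frame; columns are config-field names, one row per
#'   candidate (fields not in the grid keep their defaults).
#' @param y,X training response and genotype-code matrix.
#' @param scheme `"oob"` or `"cv5"`.
#' @param seed integer RNG seed (fold assignment and per-fit seeds).
#' @return List with `best` (the winning config list) and `table` (the
#'   grid with an `mse` column).
#' @export
tuneHyperparameters <- function(method = c("rf", "gb", "mlp", "cnn"),
                                grid, y, X, scheme = c("oob", "cv5"),
                                seed = 1) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  .check(is.data.frame(grid) && nrow(grid) > 0, "grid must be a non-empty data.frame")
  .check(scheme != "oob" || method == "rf", "OOB scoring is defined for random forests only")
  X <- as.matrix(X)
  n <- nrow(X)
  if (scheme == "cv5") {
    .check(n >= 5, "cv5 infeasible: fewer than 5 records")
    plan <- makeCVFolds(n, k = 5, replicates = 1, seed = seed)
    folds <- foldAssignments(plan)[1, ]
  }
  if (!is.null(grid$mtry)) grid$mtry <- pmin(grid$mtry, ncol(X))
  mseCol <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- .methodConfig(method, c(as.list(grid[i, , drop = FALSE]),
                                   list(seed = seed)))
    if (scheme == "oob") {
      mseCol[i] <- fitRandomForest(y, X, cfg)@oobMSE
    } else {
      sq <- numeric(0)
      for (f in 1:5) {
        te <- which(folds == f); tr <- which(folds != f)
        fit <- .fitMethod(method, y[tr], X[tr, , drop = FALSE], cfg)
        sq <- c(sq, (predict(fit, X[te, , drop = FALSE]) - y[te])^2)
      }
      mseCol[i] <- mean(sq)
    }
  }
  best <- which.min(mseCol)
  table <- cbind(grid, mse = mseCol)
  list(best = .methodConfig(method, c(as.list(grid[best, , drop = FALSE]),
                                      list(seed = seed))),
       table = table)
}

#' @describeIn tuneHyperparameters the shipped random-forest preset grid:
#'   `ntree` in \{200, 500, 1000\} x `mtry` in \{500, 1000, 2000, 5000\}
#'   (12 configurations; `mtry` is capped at the marker count during
#'   evaluation).
#' @export
rfGridPreset <- function() {
  expand.grid(ntree = c(200, 500, 1000), mtry = c(500, 1000, 2000, 5000))
}

#' @describeIn tuneHyperparameters the shipped MLP search-range preset
#'   (returned as a grid frame; exhaustive evaluation at this size is a
#'   full-scale computation).
#' @export
mlpGridPreset <- function() {
  expand.grid(batchSize = c(32, 64, 128, 256),
              epochs = c(50, 100, 200, 500, 1000),
              learningRate = c(0.001, 0.01, 0.1, 0.2, 0.3),
              weightDecay = c(0.00001, 0.0001, 0.001, 0.01))
}
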