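#' Replicated cross-validation fold plan
#'
#' Stratification-free random partitions into `k` folds whose sizes differ
#' by at most one, drawn independently per replicate. The same plan object
#' is reused across all methods of a benchmark run, which guarantees every
#' method sees identical train/test splits.
#'
#' @param n number of individuals.
#' @param k folds (default 5).
#' @param replicates independent replicates (default 5).
#' @param seed integer RNG seed.
#' @return A [CVPlan-class].
#' @export
#' @examples
#' plan <- makeCVFolds(10, k = 5, replicates = 2, seed = 1)
#' table(foldAssignments(plan)[1, ])
makeCVFolds <- function(n, k = 5, replicates = 5, seed = 1) {
  .check(k >= 2 && n >= k, "need n >= k >= 2")
  set.seed(as.integer(seed))
  assignments <- t(vapply(seq_len(replicates),
                          function(r) sample(rep_len(seq_len(k), n)),
                          integer(n)))
  new("CVPlan", n = as.integer(n), k = as.integer(k),
      replicates = as.integer(replicates), assignments = assignments,
      seed = as.integer(seed))
}

#' Pearson correlation between observed and predicted values
#'
#' @param yObs,yHat numeric vectors of equal length (at least 3).
#' @return The correlation.
#' @export
predictiveCorrelation <- function(yObs, yHat) {
  .check(length(yObs) == length(yHat), "length mismatch")
  .check(length(yObs) >= 3, "need at least 3 pairs")
  .check(sd(yObs) > 0 && sd(yHat) > 0, "zero variance in observed or predicted values")
  cor(yObs, yHat)
}

#' Mean squared error of prediction
#'
#' @param yObs,yHat numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
mse <- function(yObs, yHat) {
  .check(length(yObs) == length(yHat), "length mismatch")
  .check(length(yObs) >= 1, "empty input")
  mean((yObs - yHat)^2)
}

# method-name -> config constructor; user fields override defaults
.methodConfig <- function(method, user = list()) {
  ctor <- switch(method, gblup = gblupConfig, bayesb = bayesbConfig,
                 rf = rfConfig, gb = gbConfig, mlp = mlpConfig,
                 cnn = cnnConfig,
                 stop("unknown method: ", method))
  do.call(ctor, user[names(user) %in% names(formals(ctor))])
}

.fitMethod <- function(method, y, X, config) {
  switch(method,
         gblup = fitGBLUP(y, X, config),
         bayesb = fitBayesB(y, X, config),
         rf = fitRandomForest(y, X, config),
         gb = fitGradientBoosting(y, X, config),
         mlp = fitMLP(y, X, config),
         cnn = fitCNN(y, X, config),
         stop("unknown method: ", method))
}

.benchmarkMethods <- c("gblup", "bayesb", "rf", "gb", "mlp", "cnn")

#' Desk-scale per-method benchmark configurations
#'
#' Reduced-cost method settings for desk-scale benchmark runs (a few
#' thousand individuals, causal-size feature sets) on a single CPU:
#' closed-form GBLUP at the scenario heritability, a 3000-iteration
#' Bayes B chain (500 burn-in) with the mixture weight estimated from the
#' data, 200 random-forest trees, default gradient boosting, and 40/24
#' training epochs for the MLP/CNN. Full-scale
#' settings remain available through the individual config constructors.
#'
#' @param h2 heritability passed to GBLUP's variance ratio (use the
#'   scenario's broad-sense value when scoring total genetic values).
#' @return Named list of per-method override lists for [runBenchmark()].
#' @export
deskConfigs <- function(h2 = 0.5) {
  list(gblup = list(mode = "closed_form", h2 = h2),
       bayesb = list(nIter = 3000, burnIn = 500, thin = 5, updatePi = TRUE),
       rf = list(ntree = 200),
       gb = list(),
       mlp = list(epochs = 40),
       cnn = list(epochs = 24))
}

#' Benchmark prediction methods under replicated cross-validation
#'
#' For every replicate and fold of the plan, each method is trained on the
#' training folds (always on the observed phenotype) and its predictions
#' for the held-out fold are scored against `truthTarget`: the total
#' genetic value (simulation-style scoring) or the phenotype itself
#' (real-data-style). All methods see identical folds. Constant prediction
#' vectors yield a flagged `NA` correlation rather than an abort, and any
#' method failure is recorded in the row's `error` field and surfaced as a
#' warning.
#'
#' @param genotypes a [GenotypeData-class] with complete codes, or a
#'   genotype-code matrix.
#' @param trait a [SimulatedTrait-class] (or a numeric phenotype vector,
#'   in which case only phenotype scoring is available).
#' @param methods character vector of method names among `"gblup"`,
#'   `"bayesb"`, `"rf"`, `"gb"`, `"mlp"`, `"cnn"`.
#' @param plan a [CVPlan-class]; per-fold model seeds are derived from its
#'   seed.
#' @param predictorSet `"causal"` (feature columns are exactly the QTN
#'   columns) or `"markers"` (QTN columns excluded entirely, mimicking a
#'   SNP panel that tags, but does not include, the causal loci);
#'   `"all"` uses every column. Requires `qtn` except for `"all"`.
#' @param qtn a [QTNSet-class] or integer vector of QTN column indices.
#' @param truthTarget `"genetic_value"` or `"phenotype"`.
#' @param configs named list of per-method config overrides (lists of
#'   constructor arguments, e.g. `list(gblup = list(h2 = 0.3))`).
#' @param scenario label stamped on every record.
#' @return A long-format `data.frame` (the metric table) with one row per
#'   (method, replicate, fold): `scenario`, `method`, `predictorSet`,
#'   `replicate`, `fold`, `r`, `mse`, `target`, `degenerate`, `error`.
#' @export
runBenchmark <- function(genotypes, trait, methods = .benchmarkMethods,
                         plan, predictorSet = c("all", "causal", "markers"),
                         qtn = NULL,
                         truthTarget = c("genetic_value", "phenotype"),
                         configs = list(), scenario = "scenario") {
  predictorSet <- match.arg(predictorSet)
  truthTarget <- match.arg(truthTarget)
  stopifnot(is(plan, "CVPlan"))
  .check(all(methods %in% .benchmarkMethods), "unknown method name(s): %s",
         paste(setdiff(methods, .benchmarkMethods), collapse = ", "))
  codes <- if (is(genotypes, "GenotypeData")) genoCodes(genotypes) else
    as.matrix(genotypes)
  .check(!anyNA(codes), "benchmark requires complete genotypes (run applyQC)")

  if (predictorSet != "all") {
    .check(!is.null(qtn), "predictorSet '%s' requires qtn", predictorSet)
    qidx <- if (is(qtn, "QTNSet")) qtnIndices(qtn) else as.integer(qtn)
    codes <- if (predictorSet == "causal") codes[, qidx, drop = FALSE]
    else codes[, -qidx, drop = FALSE]
  }

  if (is(trait, "SimulatedTrait")) {
    y <- phenotype(trait)
    truth <- if (truthTarget == "genetic_value") geneticValue(trait) else y
  } else {
    .check(truthTarget == "phenotype",
           "genetic-value scoring needs a SimulatedTrait")
    y <- as.numeric(trait)
    truth <- y
  }
  .check(length(y) == nrow(codes), "phenotype length must match genotype rows")

  rows <- list()
  assign <- foldAssignments(plan)
  for (rep in seq_len(plan@replicates)) {
    for (fold in seq_len(plan@k)) {
      te <- which(assign[rep, ] == fold)
      tr <- which(assign[rep, ] != fold)
      for (method in methods) {
        cfgArgs <- configs[[method]]
        cfgArgs$seed <- deriveSeed(plan@seed, paste(method, rep, fold))
        rec <- list(scenario = scenario, method = method,
                    predictorSet = predictorSet, replicate = rep,
                    fold = fold, r = NA_real_, mse = NA_real_,
                    target = truthTarget, degenerate = FALSE,
                    error = NA_character_)
        res <- tryCatch({
          cfg <- .methodConfig(method, cfgArgs)
          fit <- .fitMethod(method, y[tr], codes[tr, , drop = FALSE], cfg)
          pred <- predict(fit, codes[te, , drop = FALSE])
          rec$mse <- mse(truth[te], pred)
          if (sd(pred) < 1e-12 || sd(truth[te]) < 1e-12) {
            rec$degenerate <- TRUE        # correlation undefined
          } else {
            rec$r <- cor(truth[te], pred)
          }
          rec
        }, error = function(e) { rec$error <- conditionMessage(e); rec })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  failed <- !is.na(out$error)
  if (any(failed))
    warning(sprintf("%d benchmark fit(s) failed; see the 'error' column", sum(failed)))
  out
}

#' Summarize a metric table
#'
#' Per (scenario, method, predictorSet) group: the mean correlation and
#' MSE over replicate means, with 95% t-intervals computed over replicate
#' means (not fold-level records) to respect the dependence between folds
#' of one replicate.
#'
#' @param table a metric table from [runBenchmark()].
#' @return data.frame with one row per group: means, confidence bounds
#'   and the replicate count.
#' @export
summarizeMetrics <- function(table) {
  .check(all(c("scenario", "method", "predictorSet", "replicate", "r", "mse")
             %in% colnames(table)), "not a metric table")
  groups <- unique(table[, c("scenario", "method", "predictorSet")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- table$scenario == g$scenario & table$method == g$method &
      table$predictorSet == g$predictorSet
    sub <- table[sel, ]
    repMeans <- function(col) {
      v <- tapply(sub[[col]], sub$replicate, mean, na.rm = TRUE)
      v[is.finite(v)]
    }
    rM <- repMeans("r"); mM <- repMeans("mse")
    .check(length(rM) >= 2, "need at least 2 replicates per group to summarize")
    ci <- function(v) qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v))
    data.frame(g, nReplicates = length(rM),
               meanR = mean(rM), lowerR = mean(rM) - ci(rM),
               upperR = mean(rM) + ci(rM),
               meanMSE = mean(mM), lowerMSE = mean(mM) - ci(mM),
               upperMSE = mean(mM) + ci(mM),
               row.names = NULL)
  })
  do.call(rbind, out)
}
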