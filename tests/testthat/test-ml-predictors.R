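test_that("random forest fits a deterministic signal and reduces OOB error with more trees", {
  set.seed(61)
  n <- 300
  X <- matrix(sample(0:2, n * 20, TRUE), n, 20)
  y <- as.numeric(X[, 7])      # y equals one feature exactly
  fit <- fitRandomForest(y, X, rfConfig(ntree = 300, nodesize = 1, seed = 1))
  pred <- predict(fit, X)
  expect_gt(1 - mean((pred - y)^2) / var(y), 0.95)   # training R^2

  # ensemble averaging: OOB MSE at 500 trees beats a single tree
  wins <- vapply(1:10, function(s) {
    set.seed(700 + s)
    Xs <- matrix(sample(0:2, 150 * 30, TRUE), 150, 30)
    ys <- 0.5 * Xs[, 1] + rnorm(150)
    oob1 <- fitRandomForest(ys, Xs, rfConfig(ntree = 1, seed = s))@oobMSE
    oob500 <- fitRandomForest(ys, Xs, rfConfig(ntree = 500, seed = s))@oobMSE
    oob500 <= oob1
  }, logical(1))
  expect_gte(sum(wins), 9)
  expect_error(fitRandomForest(y, X, rfConfig(mtry = 50)), "mtry")
})

test_that("gradient boosting stops early on noise and beats a single tree on signal", {
  stopped <- vapply(1:5, function(s) {
    set.seed(800 + s)
    X <- matrix(sample(0:2, 300 * 40, TRUE), 300, 40)
    y <- rnorm(300)
    fit <- fitGradientBoosting(y, X, gbConfig(seed = s))
    fit@bestIter
  }, numeric(1))
  expect_lt(median(stopped), 200)

  fx <- additiveFixture(n = 500, m = 40, h2 = 0.5, seed = 67)
  tr <- 1:400; te <- 401:500
  gb <- fitGradientBoosting(fx$y[tr], fx$X[tr, ], gbConfig(seed = 1))
  rGB <- cor(predict(gb, fx$X[te, ]), fx$y[te])
  oneTree <- fitGradientBoosting(fx$y[tr], fx$X[tr, ],
                                 gbConfig(learningRate = 1, maxTrees = 1,
                                          earlyStoppingRounds = 1, seed = 1))
  rTree <- cor(predict(oneTree, fx$X[te, ]), fx$y[te])
  expect_gt(rGB, rTree)

  # zero learning rate: constant predictions at the initial mean
  fit0 <- fitGradientBoosting(fx$y[tr], fx$X[tr, ],
                              gbConfig(learningRate = 0, maxTrees = 60,
                                       seed = 1))
  pred0 <- predict(fit0, fx$X[te, ])
  expect_lt(diff(range(pred0)), 1e-10)
})

test_that("the MLP learns a linear map and trains deterministically", {
  fx <- additiveFixture(n = 600, m = 50, h2 = 0.98, seed = 71)
  tr <- 1:500; te <- 501:600
  cfg <- mlpConfig(dropout = c(0, 0), epochs = 120, seed = 5)
  fit <- fitMLP(fx$y[tr], fx$X[tr, ], cfg)
  pred <- predict(fit, fx$X[te, ])
  r2 <- 1 - mean((pred - fx$y[te])^2) / var(fx$y[te])
  expect_gt(r2, 0.8)
  expect_equal(nrow(fit@curve), 120L)

  # same seed -> identical training curves; zero epochs -> initialization
  fit2 <- fitMLP(fx$y[tr], fx$X[tr, ], cfg)
  expect_identical(fit@curve, fit2@curve)
  fit0 <- fitMLP(fx$y[tr], fx$X[tr, ], mlpConfig(epochs = 0, seed = 5))
  expect_equal(nrow(fit0@curve), 0L)
  predInit <- predict(fit0, fx$X[te, ])
  expect_lt(abs(mean((predInit - fx$y[te])^2) / var(fx$y[te]) - 1), 0.5)
})

test_that("CNN geometry, degenerate inputs and weak-signal behaviour", {
  geo <- convGeometry(5000)
  expect_equal(geo$convLen, 1666L)
  expect_equal(geo$poolLen, 833L)
  expect_error(convGeometry(4), "too short")

  # constant input rows give constant predictions
  set.seed(73)
  Xconst <- matrix(1L, 40, 60)
  yr <- rnorm(40)
  fitC <- fitCNN(yr, Xconst, cnnConfig(epochs = 3, seed = 1))
  predC <- predict(fitC, Xconst[1:5, ])
  expect_lt(diff(range(predC)), 1e-10)

  # signal in one SNP window beats a shuffled-label control
  wins <- vapply(1:5, function(s) {
    set.seed(900 + s)
    n <- 300; m <- 60
    X <- matrix(sample(0:2, n * m, TRUE), n, m)
    gv <- rowSums(X[, 30:34])
    y <- scale(gv)[, 1] * sqrt(0.7) + rnorm(n, 0, sqrt(0.3))
    tr <- 1:240; te <- 241:300
    cfg <- cnnConfig(epochs = 150, batchSize = 32, seed = s)
    fitS <- fitCNN(y[tr], X[tr, ], cfg)
    rS <- cor(predict(fitS, X[te, ]), y[te])
    fitN <- fitCNN(sample(y[tr]), X[tr, ], cfg)
    rN <- cor(predict(fitN, X[te, ]), y[te])
    rS > max(rN, 0)
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("hyperparameter tuning is exhaustive and picks the dominant config", {
  fx <- additiveFixture(n = 150, m = 30, h2 = 0.5, seed = 79)
  # grid of size 1 returns that config
  res1 <- tuneHyperparameters("rf", data.frame(ntree = 100), fx$y, fx$X,
                              scheme = "oob", seed = 1)
  expect_equal(res1$best$ntree, 100L)
  expect_equal(nrow(res1$table), 1L)

  # a strictly dominant config is selected under cv5
  grid <- data.frame(learningRate = c(0.1, 0), maxTrees = 50,
                     earlyStoppingRounds = 50)
  resGB <- tuneHyperparameters("gb", grid, fx$y, fx$X, scheme = "cv5", seed = 2)
  expect_equal(resGB$best$learningRate, 0.1)
  expect_lt(resGB$table$mse[1], resGB$table$mse[2])
})

test_that("the shipped random-forest preset grid runs to a 12-row table", {
  fx <- additiveFixture(n = 500, m = 200, h2 = 0.5, seed = 83)
  res <- tuneHyperparameters("rf", rfGridPreset(), fx$y, fx$X,
                             scheme = "oob", seed = 3)
  expect_equal(nrow(res$table), 12L)
  expect_true(all(is.finite(res$table$mse)))
})
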