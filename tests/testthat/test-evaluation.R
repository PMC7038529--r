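test_that("CV plans partition individuals into near-equal folds", {
  plan <- makeCVFolds(10, k = 5, replicates = 3, seed = 1)
  a <- foldAssignments(plan)
  for (r in 1:3) {
    expect_equal(sort(unique(a[r, ])), 1:5)
    expect_true(all(tabulate(a[r, ]) == 2))
  }
  # identical seed, identical plan; partition property for uneven n
  plan2 <- makeCVFolds(10, k = 5, replicates = 3, seed = 1)
  expect_identical(foldAssignments(plan2), a)
  plan3 <- makeCVFolds(23, k = 5, replicates = 2, seed = 9)
  sizes <- tabulate(foldAssignments(plan3)[1, ])
  expect_equal(sum(sizes), 23)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(makeCVFolds(3, k = 5), "n >= k")
})

test_that("metrics match hand computations", {
  expect_equal(predictiveCorrelation(1:5, 1:5), 1.0)
  expect_equal(predictiveCorrelation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(predictiveCorrelation(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_error(predictiveCorrelation(1:3, rep(1, 3)), "variance")
  expect_error(predictiveCorrelation(1:4, 1:3), "mismatch")

  expect_equal(mse(1:4, 1:4), 0)
  expect_equal(mse(c(0, 0), c(1, -1)), 1.0)
  # shift identity: MSE(yhat + c) = MSE(yhat) + c^2 + 2 c mean(yhat - y)
  set.seed(5)
  y <- rnorm(50); yhat <- rnorm(50); cshift <- 0.7
  expect_equal(mse(y, yhat + cshift),
               mse(y, yhat) + cshift^2 + 2 * cshift * mean(yhat - y))
})

test_that("benchmark records share folds, score the requested target and flag degenerate fits", {
  g <- simPanel(n = 120, m = 150, seed = 91)
  sim <- simulateTrait(g, architectureConfig("additive", nQTN = 20, seed = 2))
  plan <- makeCVFolds(120, k = 3, replicates = 2, seed = 7)
  tbl <- runBenchmark(g, sim$trait, methods = c("gblup", "gb"), plan = plan,
                      predictorSet = "causal", qtn = sim$qtn,
                      truthTarget = "genetic_value",
                      configs = list(gblup = list(h2 = 0.3),
                                     gb = list(learningRate = 0,
                                               maxTrees = 20)),
                      scenario = "toy")
  expect_equal(nrow(tbl), 2 * 3 * 2)
  expect_true(all(tbl$scenario == "toy"))
  expect_true(all(is.na(tbl$error)))
  # zero-learning-rate boosting predicts a constant: degenerate correlation
  gbRows <- tbl[tbl$method == "gb", ]
  expect_true(all(gbRows$degenerate))
  expect_true(all(is.na(gbRows$r)))
  expect_true(all(is.finite(gbRows$mse)))
  # GBLUP on causal loci carries real signal
  expect_gt(mean(tbl$r[tbl$method == "gblup"]), 0)

  # an oracle that reproduces the truth would score r = 1, MSE = 0
  truth <- geneticValue(sim$trait)
  expect_equal(predictiveCorrelation(truth, truth), 1.0)
  expect_equal(mse(truth, truth), 0)
})

test_that("method failures are recorded per record, not silently dropped", {
  g <- simPanel(n = 30, m = 40, seed = 93)
  sim <- simulateTrait(g, architectureConfig("additive", nQTN = 5, seed = 2))
  plan <- makeCVFolds(30, k = 3, replicates = 1, seed = 1)
  # CNN geometry underflows on 5 causal columns -> per-record error
  expect_warning(
    tbl <- runBenchmark(g, sim$trait, methods = c("cnn"), plan = plan,
                        predictorSet = "causal", qtn = sim$qtn),
    "failed")
  expect_true(all(!is.na(tbl$error)))
  expect_error(runBenchmark(g, sim$trait, methods = "svm", plan = plan),
               "unknown method")
})

test_that("summaries use t-intervals over replicate means", {
  tbl <- data.frame(scenario = "s", method = "m", predictorSet = "all",
                    replicate = rep(1:3, each = 2), fold = rep(1:2, 3),
                    r = rep(c(0.30, 0.32, 0.34), each = 2),
                    mse = rep(c(0.30, 0.32, 0.34), each = 2),
                    target = "phenotype", degenerate = FALSE,
                    error = NA_character_)
  s <- summarizeMetrics(tbl)
  expect_equal(s$meanR, 0.32)
  hw <- qt(0.975, 2) * sd(c(0.30, 0.32, 0.34)) / sqrt(3)
  expect_equal(s$upperR - s$meanR, hw)
  expect_equal(s$meanR - s$lowerR, hw)

  # identical records collapse to a zero-width interval
  tbl0 <- tbl
  tbl0$r <- 0.5; tbl0$mse <- 0.1
  s0 <- summarizeMetrics(tbl0)
  expect_equal(s0$upperR - s0$lowerR, 0)
  expect_error(summarizeMetrics(tbl[tbl$replicate == 1, ]), "2 replicates")
})
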