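test_that("GRM matches hand arithmetic and has unit-scale diagonal", {
  # 2 individuals, 2 SNPs, codes [[0,2],[2,0]], p = 0.5 both:
  # z = (x - 1)/sqrt(0.5), G = ZZ'/2 = [[2,-2],[-2,2]]
  codes <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
  G <- grmMatrix(computeGRM(codes))
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2, 2))

  # identical individuals give identical rows/columns
  codes2 <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L))
  G2 <- grmMatrix(computeGRM(codes2))
  expect_equal(G2[1, ], G2[2, ])
  expect_equal(G2, t(G2))

  # simulated panel: average diagonal within [0.9, 1.1]
  g <- simPanel(n = 500, m = 400, seed = 31)
  expect_lt(abs(mean(diag(grmMatrix(computeGRM(g)))) - 1), 0.1)

  expect_error(computeGRM(matrix(c(0L, 0L, 1L, 2L), 2, 2)), "monomorphic")
})

test_that("closed-form GBLUP equals marker ridge regression to 1e-8", {
  fx <- additiveFixture(n = 70, m = 20, h2 = 0.5, seed = 41)
  tr <- 1:50; te <- 51:70
  h2 <- 0.5
  lambda <- (1 - h2) / h2
  fit <- fitGBLUP(fx$y[tr], fx$X[tr, ], gblupConfig(h2 = h2, jitter = 0))
  predPkg <- predict(fit, fx$X[te, ])
  # oracle: same standardization written independently, marker-space ridge
  # with penalty m * lambda
  p <- colMeans(fx$X[tr, ]) / 2
  ZTr <- standardizeOracle(fx$X[tr, ], p)
  ZTe <- standardizeOracle(fx$X[te, ], p)
  predOracle <- ridgeOracle(fx$y[tr], ZTr, ZTe, penalty = 20 * lambda)
  expect_lt(max(abs(predPkg - predOracle)), 1e-8)
})

test_that("GBLUP limiting behaviour: infinite shrinkage and interpolation", {
  fx <- additiveFixture(n = 40, m = 80, h2 = 0.5, seed = 43)
  # lambda -> infinity: predictions collapse to the training mean
  fitBig <- fitGBLUP(fx$y, fx$X, gblupConfig(h2 = 1e-8))
  expect_lt(max(abs(predict(fitBig, fx$X) - mean(fx$y))), 1e-3)
  # lambda -> 0 with full-rank G: training predictions approach y
  fitSmall <- fitGBLUP(fx$y, fx$X, gblupConfig(h2 = 1 - 1e-9, jitter = 0))
  expect_lt(max(abs(predict(fitSmall, fx$X) - fx$y)), 1e-4)
  # constant phenotype: every prediction equals the constant
  yConst <- rep(2.5, 40)
  fitC <- fitGBLUP(yConst, fx$X, gblupConfig(h2 = 0.5))
  expect_equal(unname(predict(fitC, fx$X)), rep(2.5, 40), tolerance = 1e-8)
})

test_that("Gibbs GBLUP agrees with the closed form and recovers h2", {
  fx <- additiveFixture(n = 200, m = 80, h2 = 0.3, seed = 47)
  tr <- 1:160; te <- 161:200
  cf <- fitGBLUP(fx$y[tr], fx$X[tr, ], gblupConfig(h2 = 0.3))
  gb <- fitGBLUP(fx$y[tr], fx$X[tr, ],
                 gblupConfig(mode = "gibbs", h2 = 0.3, nIter = 6000,
                             burnIn = 1000, thin = 5, seed = 2))
  expect_gt(cor(predict(cf, fx$X[te, ]), predict(gb, fx$X[te, ])), 0.98)
  expect_equal(gb@posterior$retained, 1000L)   # (6000 - 1000)/5

  # identical seed + config reproduce the chain exactly
  gb2 <- fitGBLUP(fx$y[tr], fx$X[tr, ],
                  gblupConfig(mode = "gibbs", h2 = 0.3, nIter = 6000,
                              burnIn = 1000, thin = 5, seed = 2))
  expect_identical(gb@markerWeights, gb2@markerWeights)

  # posterior h2 near the simulated value (averaged over seeds)
  h2Hat <- mean(vapply(1:5, function(s) {
    fxs <- additiveFixture(n = 1000, m = 60, h2 = 0.3, seed = 100 + s)
    fit <- fitGBLUP(fxs$y, fxs$X,
                    gblupConfig(mode = "gibbs", h2 = 0.5, nIter = 3000,
                                burnIn = 500, thin = 5, seed = s))
    fit@posterior$h2
  }, numeric(1)))
  expect_lt(abs(h2Hat - 0.3), 0.1)
})

test_that("Bayes B stays near the prior under pure noise", {
  inclusion <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    X <- matrix(sample(0:2, 200 * 100, TRUE, prob = c(.25, .5, .25)), 200, 100)
    y <- rnorm(200)
    fit <- fitBayesB(y, X, bayesbConfig(nIter = 3000, burnIn = 500, seed = s))
    mean(fit@inclusion)
  }, numeric(1))
  expect_lte(mean(inclusion), 0.10)
})

test_that("Bayes B recovers a single large QTN", {
  hits <- vapply(1:5, function(s) {
    set.seed(2000 + s)
    X <- matrix(sample(0:2, 500 * 100, TRUE, prob = c(.25, .5, .25)), 500, 100)
    b <- 1
    gv <- X[, 37] * b
    gv <- gv - mean(gv)
    y <- gv + rnorm(500, 0, sd(gv))   # QTN explains 50% of variance
    fit <- fitBayesB(y, X, bayesbConfig(nIter = 3000, burnIn = 500, seed = s))
    which.max(fit@inclusion) == 37 && sign(fit@beta[37]) == sign(b)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("Bayes B with pi = 0 approaches ridge regression", {
  fx <- additiveFixture(n = 200, m = 50, h2 = 0.5, seed = 53)
  tr <- 1:160; te <- 161:200
  fit <- fitBayesB(fx$y[tr], fx$X[tr, ],
                   bayesbConfig(pi = 0, nu = 50, nIter = 3000, burnIn = 500,
                                seed = 3))
  predB <- predict(fit, fx$X[te, ])
  # matched-shrinkage ridge oracle on centered codes
  Xc <- scale(fx$X[tr, ], center = TRUE, scale = FALSE)
  ctr <- attr(Xc, "scaled:center")
  s2 <- fit@posterior$s2
  lambdaMatched <- fit@posterior$sigma2e / (s2 * 50 / (50 - 2))
  XcTe <- scale(fx$X[te, ], center = ctr, scale = FALSE)
  predR <- ridgeOracle(fx$y[tr], Xc, XcTe, penalty = lambdaMatched)
  expect_gt(cor(predB, predR), 0.99)
  expect_true(all(fit@inclusion == 1))
})

test_that("Bayes B prediction contract holds", {
  fx <- additiveFixture(n = 120, m = 30, h2 = 0.5, seed = 59)
  fit <- fitBayesB(fx$y, fx$X, bayesbConfig(nIter = 1500, burnIn = 300, seed = 1))
  # all-zero genotypes predict mu + offset of the centering
  pred0 <- predict(fit, matrix(0L, 3, 30))
  expect_equal(pred0, rep(pred0[1], 3))
  # permutation equivariance
  Xte <- fx$X[1:10, ]
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  expect_equal(predict(fit, Xte)[perm], predict(fit, Xte[perm, ]))
  # determinism
  fit2 <- fitBayesB(fx$y, fx$X, bayesbConfig(nIter = 1500, burnIn = 300, seed = 1))
  expect_identical(fit@beta, fit2@beta)
  expect_error(predict(fit, fx$X[, 1:10]), "mismatch")
})
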