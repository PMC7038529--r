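test_that("clustered QTN placement builds contiguous non-overlapping triples", {
  g <- simPanel(n = 20, m = 200, seed = 2)
  q <- placeQTN(g, 9, "clustered", seed = 3)
  idx <- qtnIndices(q)
  expect_length(idx, 9L)
  expect_equal(sum(q@coreFlags), 3L)
  cores <- idx[q@coreFlags]
  for (core in cores)
    expect_true(all(c(core - 1L, core + 1L) %in% idx))
  chrom <- snpMap(g)$chrom
  for (core in cores)
    expect_equal(length(unique(chrom[(core - 1L):(core + 1L)])), 1L)
})

test_that("clustered placement tops up to the exact QTN count", {
  g <- simPanel(n = 20, m = 2000, seed = 2, nChrom = 5)
  q <- placeQTN(g, 100, "clustered", seed = 8)
  expect_length(qtnIndices(q), 100L)
  expect_equal(sum(q@coreFlags), 33L)   # 33 clusters + 1 singleton
})

test_that("random placement is uniform across the genome", {
  g <- simPanel(n = 10, m = 1000, seed = 2)
  pvals <- vapply(1:50, function(s) {
    idx <- qtnIndices(placeQTN(g, 100, "random", seed = s))
    counts <- table(cut(idx, breaks = seq(0, 1000, by = 100)))
    suppressWarnings(chisq.test(as.vector(counts))$p.value)
  }, numeric(1))
  # no more rejections at alpha = 0.01 than chance allows
  expect_lte(sum(pvals < 0.01), 4)
  expect_error(placeQTN(g, 2000, "random"), "nQTN")
})

test_that("epistatic pair list matches the documented combinatorics", {
  expect_equal(nrow(epistaticPairs(100)), 294L)
  expect_equal(nrow(epistaticPairs(1000)), 2994L)
  p4 <- epistaticPairs(4)
  expect_equal(unname(as.matrix(p4)),
               rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)),
               ignore_attr = TRUE)
  expect_error(epistaticPairs(3), "at least 4")
})

test_that("dominance and interaction codings follow the genotype tables", {
  expect_equal(dominanceCode(c(0, 1, 2)), c(0, 1, 0))
  expect_equal(dominanceCode(rep(c(0, 2), 5)), rep(0, 10))
  x <- c(0, 1, 2, 2, 1)
  expect_equal(sum(dominanceCode(x)), sum(x == 1))

  # A x A: 2,2 -> 4; 1,2 -> 2; 1,1 -> 1; 0,* -> 0
  expect_equal(interactionCode(c(2, 1, 1, 0), c(2, 2, 1, 2), "AA"),
               c(4, 2, 1, 0))
  # A x D: additive 2 at locus 1, heterozygote at locus 2 -> 2
  expect_equal(interactionCode(c(2, 2, 1), dominanceCode(c(1, 0, 1)), "AD"),
               c(2, 0, 1))
  # D x D: both heterozygous -> 1, any homozygote -> 0
  expect_equal(interactionCode(dominanceCode(c(1, 1, 0)),
                               dominanceCode(c(1, 0, 1)), "DD"),
               c(1, 0, 0))
  expect_error(interactionCode(c(0, 1), c(0, 1, 2), "AA"), "mismatch")
  expect_error(interactionCode(c(3, 0), c(0, 1), "AA"), "0/1/2")
})

test_that("substitution effects follow alpha = a + d(q - p)", {
  g <- simPanel(n = 50, m = 60, seed = 6)
  q <- placeQTN(g, 10, "random", seed = 1)
  pairs <- epistaticPairs(q)
  arch <- architectureConfig("nonadditive", nQTN = 10, seed = 4)
  freqs <- rep(0.3, 10)
  eff <- sampleEffects(q, pairs, arch, freqs)
  expect_equal(eff@substitution, eff@additive + eff@dominance * (0.7 - 0.3))
  # p = q = 0.5 makes alpha = a regardless of d
  eff5 <- sampleEffects(q, pairs, arch, rep(0.5, 10))
  expect_equal(eff5@substitution, eff5@additive)
  # direct arithmetic: a = 0.5, d = 0.2, p = 0.3 -> 0.58
  expect_equal(0.5 + 0.2 * (0.7 - 0.3), 0.58)

  # additive action zeroes dominance and epistasis, so alpha = a
  archA <- architectureConfig("additive", nQTN = 10, seed = 4)
  effA <- sampleEffects(q, pairs, archA, freqs)
  expect_true(all(effA@dominance == 0))
  expect_true(all(effA@epiAA == 0) && all(effA@epiDD == 0))
  expect_equal(effA@substitution, effA@additive)
})

test_that("effect streams are sub-seeded independently of placement", {
  g <- simPanel(n = 50, m = 200, seed = 6)
  arch <- architectureConfig("nonadditive", nQTN = 12, seed = 9)
  qC <- placeQTN(g, 12, "clustered", seed = 1)
  qR <- placeQTN(g, 12, "random", seed = 1)
  effC <- sampleEffects(qC, epistaticPairs(qC), arch, rep(0.4, 12))
  effR <- sampleEffects(qR, epistaticPairs(qR), arch, rep(0.4, 12))
  expect_identical(effC@additive, effR@additive)
  expect_identical(effC@dominance, effR@dominance)
  expect_identical(effC@epiAA, effR@epiAA)
})

test_that("genetic values match hand arithmetic and a double-loop oracle", {
  # 2 x 2 hand example: X = [[0,2],[2,1]], alpha = (1, -0.5)
  codes <- matrix(c(0L, 2L, 2L, 1L), 2, 2)
  g <- tinyPanel(codes)
  q <- new("QTNSet", indices = 1:2, coreFlags = c(FALSE, FALSE),
           placement = "random")
  eff <- new("EffectSet", additive = c(1, -0.5), dominance = c(0, 0),
             substitution = c(1, -0.5),
             pairs = matrix(integer(0), 0, 2),
             epiAA = numeric(0), epiAD = numeric(0),
             epiDA = numeric(0), epiDD = numeric(0))
  gv <- geneticValues(g, q, eff)
  expect_equal(gv$gAdditive, c(-1.0, 1.5))
  expect_equal(gv$gDominance, c(0, 0))

  # single pair, AA effect only, genotypes (2,2) -> 4 * aa
  eff2 <- new("EffectSet", additive = c(0, 0), dominance = c(0, 0),
              substitution = c(0, 0),
              pairs = matrix(c(1L, 2L), 1, 2),
              epiAA = 0.7, epiAD = 0, epiDA = 0, epiDD = 0)
  gv2 <- geneticValues(tinyPanel(matrix(c(2L, 0L, 2L, 1L), 2, 2)), q, eff2)
  expect_equal(gv2$gEpistatic[1], 4 * 0.7)

  # double-loop oracle on a 20 x 20 panel
  set.seed(11)
  X <- matrix(sample(0:2, 400, TRUE), 20, 20)
  qAll <- new("QTNSet", indices = 1:20, coreFlags = rep(FALSE, 20),
              placement = "random")
  pairs <- epistaticPairs(20)
  effR <- sampleEffects(qAll, pairs,
                        architectureConfig("nonadditive", nQTN = 20, seed = 2),
                        freqs = rep(0.4, 20))
  gv3 <- geneticValues(tinyPanel(X), qAll, effR)
  # naive per-individual loops
  D <- ifelse(X == 1, 1, 0)
  for (i in c(1, 7, 20)) {
    gA <- 0; gD <- 0; gI <- 0
    for (k in 1:20) {
      gA <- gA + X[i, k] * effR@substitution[k]
      gD <- gD + D[i, k] * effR@dominance[k]
    }
    for (pr in seq_len(nrow(pairs))) {
      k <- pairs[pr, 1]; kp <- pairs[pr, 2]
      gI <- gI + X[i, k] * X[i, kp] * effR@epiAA[pr] +
        X[i, k] * D[i, kp] * effR@epiAD[pr] +
        D[i, k] * X[i, kp] * effR@epiDA[pr] +
        D[i, k] * D[i, kp] * effR@epiDD[pr]
    }
    expect_equal(gv3$gAdditive[i], gA)
    expect_equal(gv3$gDominance[i], gD)
    expect_equal(gv3$gEpistatic[i], gI)
  }
  # all effects zero -> all components zero
  eff0 <- new("EffectSet", additive = rep(0, 20), dominance = rep(0, 20),
              substitution = rep(0, 20), pairs = pairs,
              epiAA = numeric(nrow(pairs)), epiAD = numeric(nrow(pairs)),
              epiDA = numeric(nrow(pairs)), epiDD = numeric(nrow(pairs)))
  gv0 <- geneticValues(tinyPanel(X), qAll, eff0)
  expect_true(all(unlist(gv0) == 0))
})

test_that("phenotype assembly calibrates the variance partition", {
  g <- simPanel(n = 1000, m = 400, seed = 13)
  simA <- simulateTrait(g, architectureConfig("additive", nQTN = 50, seed = 1))
  p <- realizedPartition(simA$trait)
  expect_lt(abs(p["h2_a"] - 0.30), 0.05)
  expect_equal(unname(p["h2_d"]), 0)
  tr <- simA$trait
  expect_equal(phenotype(tr),
               tr@gAdditive + tr@gDominance + tr@gEpistatic + tr@residual)

  # all targets zero: pure noise, no genetic signal
  arch0 <- architectureConfig("additive", nQTN = 50, h2A = 0, seed = 1)
  sim0 <- simulateTrait(g, arch0)
  expect_true(all(geneticValue(sim0$trait) == 0))
  expect_lt(abs(var(phenotype(sim0$trait)) - 1), 0.2)

  # positive target with a zero-variance component is an error
  comps <- list(gAdditive = rep(0, 100), gDominance = rep(0, 100),
                gEpistatic = rep(0, 100))
  expect_error(assemblePhenotype(comps,
                                 architectureConfig("additive", seed = 1)),
               "zero variance")
})

test_that("architecture defaults follow the simulated-trait table", {
  a <- architectureConfig("additive", nQTN = 100)
  expect_equal(c(a$h2A, a$h2D, a$h2I), c(0.30, 0, 0))
  n100 <- architectureConfig("nonadditive", nQTN = 100)
  expect_equal(c(n100$h2A, n100$h2D, n100$h2I), c(0.10, 0.10, 0.50))
  n1000 <- architectureConfig("nonadditive", nQTN = 1000)
  expect_equal(c(n1000$h2A, n1000$h2D, n1000$h2I), c(0.02, 0.02, 0.68))
  expect_error(architectureConfig("additive", h2D = 0.1), "h2D")
  expect_error(architectureConfig("nonadditive", h2A = 0.5, h2I = 0.6),
               "less than 1")
})
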