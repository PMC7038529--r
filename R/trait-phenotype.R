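#' Per-individual genetic-value components
#'
#' Builds the additive, dominance and epistatic genetic values implied by a
#' QTN set and its effects:
#' `g_A = X alpha`, `g_D = D d`, and the epistatic component sums the four
#' Hadamard-coded interaction matrices (A x A, A x D, D x A, D x D; see
#' [interactionCode()]) weighted by their per-pair effects.
#'
#' @param g a [GenotypeData-class] with complete QTN columns
#'   (post-imputation) or a complete genotype-code matrix.
#' @param q a [QTNSet-class].
#' @param eff an [EffectSet-class] (its `pairs` slot defines the epistatic
#'   pair list).
#' @return List with numeric vectors `gAdditive`, `gDominance`,
#'   `gEpistatic`.
#' @export
geneticValues <- function(g, q, eff) {
  stopifnot(is(q, "QTNSet"), is(eff, "EffectSet"))
  codes <- if (is(g, "GenotypeData")) genoCodes(g) else as.matrix(g)
  X <- codes[, q@indices, drop = FALSE]
  .check(!anyNA(X), "QTN columns must be complete (impute first)")
  .check(ncol(X) == length(eff@additive), "effect/QTN length mismatch")
  storage.mode(X) <- "double"
  D <- (X == 1) * 1

  gA <- unname(drop(X %*% eff@substitution))
  gD <- unname(drop(D %*% eff@dominance))

  pairs <- eff@pairs
  if (nrow(pairs) > 0) {
    Xk <- X[, pairs[, 1], drop = FALSE]; Xp <- X[, pairs[, 2], drop = FALSE]
    Dk <- D[, pairs[, 1], drop = FALSE]; Dp <- D[, pairs[, 2], drop = FALSE]
    gI <- unname(drop((Xk * Xp) %*% eff@epiAA + (Xk * Dp) %*% eff@epiAD +
                        (Dk * Xp) %*% eff@epiDA + (Dk * Dp) %*% eff@epiDD))
  } else {
    gI <- numeric(nrow(X))
  }
  list(gAdditive = gA, gDominance = gD, gEpistatic = gI)
}

#' Assemble a phenotype calibrated to a target variance partition
#'
#' Each genetic component with a positive target is rescaled by a constant
#' so that its empirical variance equals the targeted fraction of a unit
#' total phenotypic variance (components with target 0 are zeroed).
#' Residuals are drawn i.i.d. N(0, sigma2_e) with
#' `sigma2_e = 1 - (h2A + h2D + h2I)`, and the phenotype is the sum of the
#' scaled components and the residual. The realized partition reports raw
#' variance ratios Var(component)/Var(phenotype) — component covariances
#' are not removed — plus broad-sense `H2_B` =
#' Var(total genetic)/Var(phenotype).
#'
#' @param components list with `gAdditive`, `gDominance`, `gEpistatic`
#'   (from [geneticValues()]).
#' @param arch an [architectureConfig()]; supplies the targets and the
#'   residual sub-seed.
#' @return A [SimulatedTrait-class].
#' @export
assemblePhenotype <- function(components, arch) {
  stopifnot(inherits(arch, "architectureConfig"))
  targets <- c(h2_a = arch$h2A, h2_d = arch$h2D, h2_I = arch$h2I)
  comps <- components[c("gAdditive", "gDominance", "gEpistatic")]
  n <- length(comps[[1]])
  scaling <- setNames(numeric(3), names(targets))
  for (i in 1:3) {
    if (targets[i] <= 0) {
      comps[[i]] <- numeric(n)
      scaling[i] <- 0
    } else {
      v <- var(comps[[i]])
      .check(v > 0, "component '%s' has positive target but zero variance",
             names(comps)[i])
      scaling[i] <- sqrt(targets[i] / v)
      comps[[i]] <- comps[[i]] * scaling[i]
    }
  }
  sigma2e <- 1 - sum(targets)
  set.seed(deriveSeed(arch$seed, "residual"))
  e <- rnorm(n, 0, sqrt(sigma2e))
  y <- comps$gAdditive + comps$gDominance + comps$gEpistatic + e
  vy <- var(y)
  gTot <- comps$gAdditive + comps$gDominance + comps$gEpistatic
  partition <- c(h2_a = var(comps$gAdditive) / vy,
                 h2_d = var(comps$gDominance) / vy,
                 h2_I = var(comps$gEpistatic) / vy,
                 H2_B = var(gTot) / vy)
  new("SimulatedTrait", gAdditive = comps$gAdditive,
      gDominance = comps$gDominance, gEpistatic = comps$gEpistatic,
      residual = e, phenotype = y, partition = partition,
      target = c(targets, H2_B = sum(targets)), scaling = scaling)
}

#' Simulate a complex trait on a genotype panel
#'
#' Convenience wrapper running the full trait-simulation chain: QTN
#' placement, epistatic pair construction, effect sampling, genetic-value
#' computation, and phenotype assembly with heritability calibration.
#'
#' @param g a [GenotypeData-class] with complete codes (run [applyQC()]
#'   first if the panel has missing genotypes).
#' @param arch an [architectureConfig()].
#' @return List with elements `trait` ([SimulatedTrait-class]),
#'   `qtn` ([QTNSet-class]) and `effects` ([EffectSet-class]).
#' @export
#' @examples
#' g <- simulateGenotypes(genotypeSimConfig(nIndividuals = 200, nSNPs = 300,
#'                                          missingRate = 0, seed = 3))
#' sim <- simulateTrait(g, architectureConfig("additive", nQTN = 20, seed = 3))
#' realizedPartition(sim$trait)
simulateTrait <- function(g, arch = architectureConfig()) {
  stopifnot(is(g, "GenotypeData"), inherits(arch, "architectureConfig"))
  q <- placeQTN(g, arch$nQTN, arch$placement,
                seed = deriveSeed(arch$seed, "placement"))
  pairs <- if (arch$nQTN >= 4) epistaticPairs(q) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("k", "kp")))
  codes <- genoCodes(g)
  .check(!anyNA(codes[, q@indices]), "QTN columns contain missing genotypes")
  p <- colMeans(codes[, q@indices, drop = FALSE]) / 2
  eff <- sampleEffects(q, pairs, arch, freqs = p)
  comps <- geneticValues(codes, q, eff)
  trait <- assemblePhenotype(comps, arch)
  list(trait = trait, qtn = q, effects = eff)
}
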