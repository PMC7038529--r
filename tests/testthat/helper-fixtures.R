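# Small fixtures built in code.

# tiny deterministic panel with hand-set codes
tinyPanel <- function(codes, chrom = NULL, pos = NULL) {
  m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  GenotypeData(codes, chrom = chrom, pos = pos)
}

# complete simulated panel for model tests
simPanel <- function(n = 200, m = 300, seed = 1, nChrom = 3, rho = 0.5) {
  simulateGenotypes(genotypeSimConfig(
    nIndividuals = n, nSNPs = m, nChromosomes = nChrom,
    withinBlockCorr = rho, missingRate = 0, seed = seed))
}

# additive regression fixture: y = X w + noise at a given signal fraction
additiveFixture <- function(n, m, h2 = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.25, .5, .25)), n, m)
  w <- rnorm(m, 0, 1)
  g <- drop(X %*% w)
  g <- (g - mean(g)) / sd(g) * sqrt(h2)
  y <- g + rnorm(n, 0, sqrt(1 - h2))
  list(X = X, y = y, g = g, w = w)
}

# independent ridge-regression oracle: marker-space normal equations with
# a fixed penalty on given (already transformed) design matrices
ridgeOracle <- function(yTr, ZTr, ZTe, penalty) {
  mu <- mean(yTr)
  b <- solve(crossprod(ZTr) + diag(penalty, ncol(ZTr)),
             crossprod(ZTr, yTr - mu))
  drop(mu + ZTe %*% b)
}

# standardization arithmetic written out independently of the package
standardizeOracle <- function(X, p) {
  t((t(X) - 2 * p) / sqrt(2 * p * (1 - p)))
}

# independent enumeration oracle: probability of each heterozygote count
# from the closed-form conditional distribution given allele counts
hweEnumOracle <- function(naa, nAa, nAA) {
  n <- naa + nAa + nAA
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (min(nA, na) == 0) return(1.0)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    homA <- (nA - h) / 2
    homa <- (na - h) / 2
    lfactorial(n) - lfactorial(homA) - lfactorial(h) - lfactorial(homa) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  pObs <- p[match(nAa, hets)]
  min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}

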