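#' Configuration for the synthetic genotype generator
#'
#' Defaults describe the desk-scale stand-in panel used throughout the
#' package: 2,000 individuals, 5,000 SNPs on 10 chromosomes in LD blocks of
#' 50 SNPs with a within-block haplotype correlation of 0.7, allele
#' frequencies drawn uniformly from (0.05, 0.5), and 1% missing genotypes.
#'
#' @param nIndividuals,nSNPs panel dimensions.
#' @param nChromosomes number of chromosomes; SNPs are split into contiguous,
#'   near-equal chromosome chunks and LD blocks never span chromosomes.
#' @param blockLength SNPs per LD block (the last block of a chromosome may
#'   be shorter).
#' @param withinBlockCorr latent haplotype AR(1) correlation in `[0, 1)`
#'   between adjacent SNPs of a block; 0 gives independent SNPs.
#' @param mafRange length-2 numeric in `(0, 0.5]`; each SNP's expected
#'   allele frequency is drawn uniformly from this range (the "A" allele
#'   orientation is then randomized, so codes do not count the minor allele
#'   by construction).
#' @param missingRate fraction of entries set missing uniformly at random.
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @return A validated config list of class `genotypeSimConfig`.
#' @export
genotypeSimConfig <- function(nIndividuals = 2000, nSNPs = 5000,
                              nChromosomes = 10, blockLength = 50,
                              withinBlockCorr = 0.7,
                              mafRange = c(0.05, 0.5),
                              missingRate = 0.01, seed = 1) {
  cfg <- list(nIndividuals = as.integer(nIndividuals),
              nSNPs = as.integer(nSNPs),
              nChromosomes = as.integer(nChromosomes),
              blockLength = as.integer(blockLength),
              withinBlockCorr = withinBlockCorr,
              mafRange = mafRange, missingRate = missingRate,
              seed = as.integer(seed))
  .check(cfg$nIndividuals > 0 && cfg$nSNPs > 0 && cfg$nChromosomes > 0 &&
           cfg$blockLength > 0, "dimensions must be positive")
  .check(cfg$nChromosomes <= cfg$nSNPs, "more chromosomes than SNPs")
  .check(length(mafRange) == 2 && mafRange[1] <= mafRange[2] &&
           mafRange[1] > 0 && mafRange[2] <= 0.5,
         "mafRange must lie within (0, 0.5]")
  .check(withinBlockCorr >= 0 && withinBlockCorr < 1,
         "withinBlockCorr must be in [0, 1)")
  .check(missingRate >= 0 && missingRate < 1, "missingRate must be in [0, 1)")
  class(cfg) <- "genotypeSimConfig"
  cfg
}

#' Simulate a biallelic SNP genotype panel with LD blocks
#'
#' Genotypes are the sum of two independently drawn haplotypes, so each SNP
#' is in Hardy-Weinberg proportions before missingness is injected. Within
#' an LD block, haplotype alleles follow a Gaussian-copula first-order
#' Markov chain: a latent AR(1) series with correlation
#' `withinBlockCorr` is thresholded at each SNP's allele frequency, so
#' adjacent-SNP genotype correlation increases with the block parameter and
#' vanishes when it is 0.
#'
#' @param config a [genotypeSimConfig()] list.
#' @return A [GenotypeData-class] object with a chromosome/position map.
#' @export
#' @examples
#' g <- simulateGenotypes(genotypeSimConfig(nIndividuals = 50, nSNPs = 100,
#'                                          nChromosomes = 2, seed = 7))
#' g
simulateGenotypes <- function(config = genotypeSimConfig()) {
  stopifnot(inherits(config, "genotypeSimConfig"))
  n <- config$nIndividuals; m <- config$nSNPs
  rho <- config$withinBlockCorr
  set.seed(config$seed)

  # chromosome assignment: contiguous near-equal chunks
  chrom <- as.character(sort(rep_len(seq_len(config$nChromosomes), m)))
  # strictly increasing positions within chromosome (1-based bp)
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(1000:10000, length(idx), replace = TRUE))
  }

  # expected "A"-allele frequency per SNP: uniform MAF, random orientation
  p <- runif(m, config$mafRange[1], config$mafRange[2])
  flip <- runif(m) < 0.5
  p[flip] <- 1 - p[flip]

  # block starts: every blockLength SNPs within a chromosome
  withinChromIdx <- unlist(lapply(rle(chrom)$lengths, seq_len), use.names = FALSE)
  newBlock <- (withinChromIdx - 1L) %% config$blockLength == 0L

  # two haplotypes per individual, latent Gaussian AR(1) within blocks
  nh <- 2L * n
  H <- matrix(0L, nh, m)
  z <- numeric(nh)
  sq <- sqrt(1 - rho^2)
  thr <- qnorm(p)
  for (j in seq_len(m)) {
    eps <- rnorm(nh)
    z <- if (newBlock[j]) eps else rho * z + sq * eps
    H[, j] <- as.integer(z < thr[j])
  }
  codes <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]

  if (config$missingRate > 0) {
    miss <- runif(n * m) < config$missingRate
    codes[miss] <- NA_integer_
  }
  GenotypeData(codes, chrom = chrom, pos = pos)
}
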