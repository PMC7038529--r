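#' Marker quality-control configuration
#'
#' Mirrors the standard PLINK-style marker filters: drop SNPs with minor
#' allele frequency below `mafMin`, missing rate above `missingMax`, exact
#' Hardy-Weinberg test p-value below `hweAlpha`, or mapping to an excluded
#' chromosome.
#'
#' @param mafMin minimum minor allele frequency (default 0.05; SNPs with
#'   MAF strictly below are removed).
#' @param missingMax maximum missing-genotype fraction (default 0.05; SNPs
#'   strictly above are removed).
#' @param hweAlpha Hardy-Weinberg exact-test p-value threshold
#'   (default 1e-6; SNPs strictly below are removed).
#' @param dropChroms chromosome labels to exclude (default `"X"`).
#' @return A validated config list of class `qcConfig`.
#' @export
qcConfig <- function(mafMin = 0.05, missingMax = 0.05, hweAlpha = 1e-6,
                     dropChroms = "X") {
  .check(mafMin >= 0 && mafMin <= 0.5, "mafMin must be in [0, 0.5]")
  .check(missingMax >= 0 && missingMax <= 1, "missingMax must be in [0, 1]")
  .check(hweAlpha > 0 && hweAlpha < 1, "hweAlpha must be in (0, 1)")
  structure(list(mafMin = mafMin, missingMax = missingMax,
                 hweAlpha = hweAlpha, dropChroms = as.character(dropChroms)),
            class = "qcConfig")
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test for departure from Hardy-Weinberg genotype
#' proportions (Wigginton-style, as used by PLINK), computed by a numerically
#' stable recurrence over all heterozygote counts compatible with the
#' observed allele counts. The p-value is the summed probability of all
#' tables no more probable than the observed one (plain exact test, no
#' mid-p correction). Monomorphic SNPs return 1 by convention.
#'
#' @param naa,nAa,nAA observed genotype counts (codes 0, 1, 2).
#' @return The exact-test p-value.
#' @export
#' @examples
#' hweExactTest(25, 50, 25)   # modal table: p = 1
#' hweExactTest(50, 0, 50)    # extreme disequilibrium
hweExactTest <- function(naa, nAa, nAA) {
  .check(length(naa) == 1 && length(nAa) == 1 && length(nAA) == 1 &&
           naa >= 0 && nAa >= 0 && nAA >= 0, "counts must be non-negative scalars")
  n <- naa + nAa + nAA
  .check(n > 0, "all genotype counts are zero")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  if (rare == 0) return(1.0)              # monomorphic: nothing to test

  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start from the midpoint and fill by recurrence
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  iMid <- match(mid, hets)
  probs[iMid] <- 1
  # going down: P(h-2) = P(h) * h (h-1) / (4 (homR + 1)(homC + 1))
  if (iMid > 1) for (i in seq(iMid, 2)) {
    h <- hets[i]
    homR <- (rare - h) / 2
    homC <- n - h - homR
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (homR + 1) * (homC + 1))
  }
  # going up: P(h+2) = P(h) * 4 homR homC / ((h+2)(h+1))
  if (iMid < length(hets)) for (i in seq(iMid, length(hets) - 1)) {
    h <- hets[i]
    homR <- (rare - h) / 2
    homC <- n - h - homR
    probs[i + 1] <- probs[i] * 4 * homR * homC / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hets)]
  if (is.na(pObs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

# per-SNP statistics honouring the pre-imputation missingness mask
.snpStats <- function(g) {
  codes <- genoCodes(g)
  mask <- S4Vectors::metadata(g)$missingMask
  if (!is.null(mask) && nrow(mask) > 0) codes[mask] <- NA_integer_
  isNA <- is.na(codes)
  miss <- colMeans(isNA)
  p <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(codes)), function(j) {
    x <- codes[!isNA[, j], j]
    if (length(x) == 0) return(1.0)
    hweExactTest(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
  list(maf = maf, miss = miss, hwe = hwe)
}

#' Apply marker quality control and impute residual missingness
#'
#' Drops every SNP failing any of the four rules (MAF, missingness,
#' Hardy-Weinberg, excluded chromosome); the surviving set does not depend
#' on rule order. Remaining missing genotypes are imputed to the SNP's
#' rounded mean code so downstream fitters see complete matrices; the
#' pre-imputation mask is retained in `metadata(x)$missingMask` and all QC
#' statistics are always computed on originally observed genotypes, which
#' makes the operation idempotent.
#'
#' @param g a [GenotypeData-class] object.
#' @param qc a [qcConfig()] list.
#' @return A list with elements `genotypes` (filtered, imputed
#'   [GenotypeData-class]) and `report` (per-rule character vectors of the
#'   SNP IDs removed, plus counts).
#' @export
applyQC <- function(g, qc = qcConfig()) {
  stopifnot(is(g, "GenotypeData"), inherits(qc, "qcConfig"))
  st <- .snpStats(g)
  map <- snpMap(g)
  failChrom <- map$chrom %in% qc$dropChroms
  failMAF <- st$maf < qc$mafMin
  failMiss <- st$miss > qc$missingMax
  failHWE <- st$hwe < qc$hweAlpha
  drop <- failChrom | failMAF | failMiss | failHWE
  .check(!all(drop), "quality control removed every SNP")

  ids <- snpIDs(g)
  report <- list(chrom = ids[failChrom], maf = ids[failMAF],
                 missing = ids[failMiss], hwe = ids[failHWE])
  report$nRemoved <- sum(drop)
  report$nKept <- sum(!drop)

  keep <- which(!drop)
  codes <- genoCodes(g)
  oldMask <- S4Vectors::metadata(g)$missingMask
  if (!is.null(oldMask) && nrow(oldMask) > 0) codes[oldMask] <- NA_integer_
  codes <- codes[, keep, drop = FALSE]

  # mean-code imputation; keep the mask of originally missing entries
  mask <- which(is.na(codes), arr.ind = TRUE)
  if (nrow(mask) > 0) {
    fill <- as.integer(round(colMeans(codes, na.rm = TRUE)))
    codes[mask] <- fill[mask[, 2]]
  }
  out <- GenotypeData(codes, chrom = map$chrom[keep], pos = map$pos[keep],
                      snpID = ids[keep], sampleID = sampleIDs(g))
  S4Vectors::metadata(out)$missingMask <- mask
  S4Vectors::metadata(out)$qc <- qc
  list(genotypes = out, report = report)
}
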