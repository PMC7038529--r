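test_that("exact HWE test reproduces the reference tables", {
  expect_equal(hweExactTest(25, 50, 25), 1.0)       # modal table
  expect_lt(hweExactTest(50, 0, 50), 1e-6)          # would be filtered
  expect_equal(hweExactTest(0, 0, 60), 1.0)         # monomorphic convention
  expect_error(hweExactTest(0, 0, 0), "zero")
  expect_error(hweExactTest(-1, 2, 3), "non-negative")
})

test_that("exact HWE test agrees with the enumeration oracle up to n = 200", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hweExactTest(naa, nAa, nAA),
                 hweEnumOracle(naa, nAa, nAA), tolerance = 1e-9)
  }
})

test_that("each QC rule removes exactly its offending SNPs", {
  set.seed(2)
  n <- 200
  good <- replicate(4, rbinom(n, 2, 0.4))
  lowMAF <- rbinom(n, 2, 0.04)            # MAF ~ 0.04 < 0.05
  highMiss <- rbinom(n, 2, 0.4)
  highMiss[sample(n, 12)] <- NA           # 6% missing
  hweFail <- rep(c(0L, 2L), each = n / 2) # no heterozygotes at p = 0.5
  onX <- rbinom(n, 2, 0.3)
  codes <- cbind(good, lowMAF, highMiss, hweFail, onX)
  g <- tinyPanel(codes, chrom = c(rep("1", 7), "X"),
                 pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 100L))
  res <- applyQC(g)
  expect_equal(res$report$maf, "snp5")
  expect_equal(res$report$missing, "snp6")
  expect_equal(res$report$hwe, "snp7")
  expect_equal(res$report$chrom, "snp8")
  expect_equal(snpIDs(res$genotypes), paste0("snp", 1:4))
})

test_that("a clean X-chromosome SNP is removed only by the chromosome rule", {
  set.seed(3)
  codes <- cbind(rbinom(300, 2, 0.4), rbinom(300, 2, 0.3))
  g <- tinyPanel(codes, chrom = c("1", "X"), pos = c(100L, 100L))
  res <- applyQC(g)
  expect_equal(res$report$chrom, "snp2")
  expect_length(res$report$maf, 0)
  expect_length(res$report$missing, 0)
  expect_length(res$report$hwe, 0)
})

test_that("QC imputes residual missingness and keeps the mask", {
  set.seed(4)
  codes <- replicate(5, rbinom(400, 2, 0.45))
  miss <- cbind(sample(400, 8), rep(3L, 8))
  codes[miss] <- NA
  g <- tinyPanel(codes)
  res <- applyQC(g)
  out <- genoCodes(res$genotypes)
  expect_false(anyNA(out))
  mask <- S4Vectors::metadata(res$genotypes)$missingMask
  expect_equal(nrow(mask), 8L)
  fill <- as.integer(round(mean(codes[-miss[, 1], 3])))
  expect_true(all(out[mask] == fill))
})

test_that("QC is idempotent on the surviving SNP set", {
  g <- simulateGenotypes(genotypeSimConfig(nIndividuals = 400, nSNPs = 400,
                                           nChromosomes = 2,
                                           mafRange = c(0.03, 0.5),
                                           missingRate = 0.04, seed = 21))
  res1 <- applyQC(g)
  res2 <- applyQC(res1$genotypes)
  expect_identical(snpIDs(res2$genotypes), snpIDs(res1$genotypes))
  expect_identical(genoCodes(res2$genotypes), genoCodes(res1$genotypes))
})

test_that("QC removing every SNP is an error", {
  codes <- cbind(rbinom(100, 2, 0.02), rbinom(100, 2, 0.03))
  g <- tinyPanel(codes)
  expect_error(applyQC(g), "every SNP")
})
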