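#' GenotypeData: SNP genotype matrix with map
#'
#' S4 container for a biallelic SNP panel, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Rows are SNPs (with a
#' `GRanges` of chromosome/position), columns are samples, and the single
#' assay `"geno"` holds allele counts of an arbitrary reference allele "A":
#' 0 = aa, 1 = Aa, 2 = AA, `NA` = missing. `rowData` carries the per-SNP
#' minor-allele frequency and missing rate; after quality control the
#' positions of originally-missing, mean-imputed entries are retained in
#' `metadata(x)$missingMask`.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

.validGenotypeData <- function(object) {
  msg <- character()
  a <- SummarizedExperiment::assay(object, "geno")
  v <- a[!is.na(a)]
  if (!all(v %in% c(0, 1, 2)))
    msg <- c(msg, "assay 'geno' must contain only 0/1/2/NA")
  rr <- SummarizedExperiment::rowRanges(object)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      msg <- c(msg, sprintf("positions on chromosome %s not strictly increasing", ch))
      break
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeData", .validGenotypeData)

#' Construct a GenotypeData object
#'
#' @param codes n x m integer matrix of genotype codes (samples in rows,
#'   SNPs in columns; 0/1/2, `NA` = missing).
#' @param chrom per-SNP chromosome labels (length m).
#' @param pos per-SNP 1-based base-pair positions, strictly increasing
#'   within a chromosome.
#' @param snpID,sampleID optional identifier vectors; defaults are
#'   `snp1..snpm` / `ind1..indn`.
#' @return A [GenotypeData-class] object.
#' @export
#' @examples
#' g <- GenotypeData(matrix(c(0L, 1L, 2L, 1L), 2, 2),
#'                   chrom = c("1", "1"), pos = c(100L, 200L))
#' genoCodes(g)
GenotypeData <- function(codes, chrom, pos,
                         snpID = paste0("snp", seq_len(ncol(codes))),
                         sampleID = paste0("ind", seq_len(nrow(codes)))) {
  codes <- as.matrix(codes)
  .checkCodes(codes)
  .check(length(chrom) == ncol(codes) && length(pos) == ncol(codes),
         "chrom/pos length must equal the number of SNP columns")
  storage.mode(codes) <- "integer"
  dimnames(codes) <- NULL
  rr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start = as.integer(pos), width = 1L))
  names(rr) <- snpID
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = t(codes)),
    rowRanges = rr,
    colData = S4Vectors::DataFrame(row.names = sampleID))
  obj <- new("GenotypeData", se)
  SummarizedExperiment::rowData(obj)$maf <- .mafFromCodes(codes)
  SummarizedExperiment::rowData(obj)$missingRate <- colMeans(is.na(codes))
  obj
}

.mafFromCodes <- function(codes) {
  p <- colMeans(codes, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @rdname gpbench-generics
#' @export
setMethod("genoCodes", "GenotypeData", function(x)
  t(SummarizedExperiment::assay(x, "geno")))

#' @rdname gpbench-generics
#' @export
setMethod("sampleIDs", "GenotypeData", function(x) colnames(x))

#' @rdname gpbench-generics
#' @export
setMethod("snpIDs", "GenotypeData", function(x) rownames(x))

#' @rdname gpbench-generics
#' @export
setMethod("snpMap", "GenotypeData", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(snp = rownames(x),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname gpbench-generics
#' @export
setMethod("snpMAF", "GenotypeData", function(x)
  setNames(SummarizedExperiment::rowData(x)$maf, rownames(x)))

#' @rdname gpbench-generics
#' @export
setMethod("snpMissingRate", "GenotypeData", function(x)
  setNames(SummarizedExperiment::rowData(x)$missingRate, rownames(x)))

#' @rdname gpbench-generics
#' @export
setMethod("nSamples", "GenotypeData", function(x) ncol(x))

#' @rdname gpbench-generics
#' @export
setMethod("nSNPs", "GenotypeData", function(x) nrow(x))

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d samples x %d SNPs on %d chromosome(s)\n",
              ncol(object), nrow(object),
              length(unique(as.character(GenomicRanges::seqnames(
                SummarizedExperiment::rowRanges(object)))))))
  mr <- SummarizedExperiment::rowData(object)$missingRate
  cat(sprintf("  median MAF %.3f | mean missing rate %.4f\n",
              stats::median(SummarizedExperiment::rowData(object)$maf),
              mean(mr)))
  if (!is.null(S4Vectors::metadata(object)$missingMask))
    cat("  residual missingness mean-imputed (mask retained)\n")
})

#' QTNSet: causal-locus indices
#'
#' Ordered SNP-column indices of the simulated causal loci, with a flag
#' marking cluster cores under clustered placement.
#'
#' @slot indices integer SNP column indices, sorted in genome order.
#' @slot coreFlags logical, `TRUE` for cluster cores (all `FALSE` under
#'   random placement).
#' @slot placement `"clustered"` or `"random"`.
#' @aliases QTNSet-class
#' @export
setClass("QTNSet", representation(indices = "integer",
                                  coreFlags = "logical",
                                  placement = "character"))

setValidity("QTNSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@indices)) msg <- c(msg, "QTN indices must be distinct")
  if (is.unsorted(object@indices, strictly = TRUE))
    msg <- c(msg, "QTN indices must be sorted in genome order")
  if (length(object@coreFlags) != length(object@indices))
    msg <- c(msg, "coreFlags length must match indices")
  if (!object@placement %in% c("clustered", "random"))
    msg <- c(msg, "placement must be 'clustered' or 'random'")
  if (length(msg)) msg else TRUE
})

#' @rdname gpbench-generics
#' @export
setMethod("qtnIndices", "QTNSet", function(x) x@indices)

setMethod("show", "QTNSet", function(object) {
  cat(sprintf("QTNSet: %d QTN (%s placement, %d cores)\n",
              length(object@indices), object@placement,
              sum(object@coreFlags)))
})

#' EffectSet: sampled QTN effects
#'
#' Per-QTN additive (`a`), dominance (`d`) and allele-substitution
#' (`alpha = a + d (q - p)`) effects, plus the four per-pair epistatic
#' effect vectors (A x A, A x D, D x A, D x D) indexed by `pairs`.
#'
#' @slot additive,dominance,substitution numeric, one entry per QTN.
#' @slot pairs integer matrix (nPairs x 2) of QTN ranks `k < k'`.
#' @slot epiAA,epiAD,epiDA,epiDD numeric, one entry per pair.
#' @aliases EffectSet-class
#' @export
setClass("EffectSet", representation(additive = "numeric",
                                     dominance = "numeric",
                                     substitution = "numeric",
                                     pairs = "matrix",
                                     epiAA = "numeric", epiAD = "numeric",
                                     epiDA = "numeric", epiDD = "numeric"))

setValidity("EffectSet", function(object) {
  n <- length(object@additive)
  p <- nrow(object@pairs)
  msg <- character()
  if (length(object@dominance) != n || length(object@substitution) != n)
    msg <- c(msg, "additive/dominance/substitution lengths differ")
  for (s in c("epiAA", "epiAD", "epiDA", "epiDD"))
    if (length(slot(object, s)) != p)
      msg <- c(msg, sprintf("%s length must equal the number of pairs", s))
  if (p > 0 && any(object@pairs[, 1] >= object@pairs[, 2]))
    msg <- c(msg, "pairs must satisfy k < k'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EffectSet", function(object) {
  cat(sprintf("EffectSet: %d QTN, %d epistatic pairs\n",
              length(object@additive), nrow(object@pairs)))
})

#' SimulatedTrait: phenotype and its genetic components
#'
#' Per-individual additive, dominance and epistatic genetic values,
#' residuals and the assembled phenotype, together with the realized
#' variance partition and the scaling constants applied during
#' heritability calibration.
#'
#' @slot gAdditive,gDominance,gEpistatic,residual,phenotype numeric vectors
#'   of length n.
#' @slot partition named numeric: realized `h2_a`, `h2_d`, `h2_I` (raw
#'   variance ratios Var(component)/Var(phenotype)) and `H2_B`
#'   (Var(total genetic)/Var(phenotype)).
#' @slot target named numeric of the targeted fractions.
#' @slot scaling named numeric of per-component scale factors.
#' @aliases SimulatedTrait-class
#' @export
setClass("SimulatedTrait", representation(gAdditive = "numeric",
                                          gDominance = "numeric",
                                          gEpistatic = "numeric",
                                          residual = "numeric",
                                          phenotype = "numeric",
                                          partition = "numeric",
                                          target = "numeric",
                                          scaling = "numeric"))

setValidity("SimulatedTrait", function(object) {
  n <- length(object@phenotype)
  msg <- character()
  if (any(vapply(c("gAdditive", "gDominance", "gEpistatic", "residual"),
                 function(s) length(slot(object, s)) != n, logical(1))))
    msg <- c(msg, "component vectors must all have the phenotype's length")
  tot <- object@gAdditive + object@gDominance + object@gEpistatic + object@residual
  if (max(abs(tot - object@phenotype)) > 1e-8)
    msg <- c(msg, "phenotype must equal the sum of components and residual")
  if (length(msg)) msg else TRUE
})

#' @rdname gpbench-generics
#' @export
setMethod("phenotype", "SimulatedTrait", function(x) x@phenotype)

#' @rdname gpbench-generics
#' @export
setMethod("geneticValue", "SimulatedTrait", function(x)
  x@gAdditive + x@gDominance + x@gEpistatic)

#' @rdname gpbench-generics
#' @export
setMethod("realizedPartition", "SimulatedTrait", function(x) x@partition)

setMethod("show", "SimulatedTrait", function(object) {
  p <- object@partition
  cat(sprintf("SimulatedTrait: n = %d\n", length(object@phenotype)))
  cat(sprintf("  realized partition: h2_a = %.3f, h2_d = %.3f, h2_I = %.3f, H2_B = %.3f\n",
              p["h2_a"], p["h2_d"], p["h2_I"], p["H2_B"]))
})

#' GRM: genomic relationship matrix
#'
#' Additive genomic relationship matrix `G = Z Z' / m` built from centered
#' and standardized genotype codes.
#'
#' @slot matrix n x n numeric relationship matrix.
#' @slot nMarkers number of markers used.
#' @slot sampleIDs sample identifiers (row/column names of `matrix`).
#' @aliases GRM-class
#' @export
setClass("GRM", representation(matrix = "matrix", nMarkers = "integer",
                               sampleIDs = "character"))

setValidity("GRM", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "relationship matrix must be square")
  else if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "relationship matrix must be symmetric")
  if (length(object@sampleIDs) != nrow(m))
    msg <- c(msg, "sampleIDs length must match matrix dimension")
  if (length(msg)) msg else TRUE
})

#' @rdname gpbench-generics
#' @export
setMethod("grmMatrix", "GRM", function(x) x@matrix)

setMethod("show", "GRM", function(object) {
  cat(sprintf("GRM: %d x %d from %d markers | mean diagonal %.3f\n",
              nrow(object@matrix), ncol(object@matrix), object@nMarkers,
              mean(diag(object@matrix))))
})

#' CVPlan: replicated cross-validation fold assignments
#'
#' @slot n number of individuals.
#' @slot k number of folds.
#' @slot replicates number of independent replicates.
#' @slot assignments replicates x n integer matrix of fold ids in `1..k`.
#' @slot seed integer seed the plan was drawn from.
#' @aliases CVPlan-class
#' @export
setClass("CVPlan", representation(n = "integer", k = "integer",
                                  replicates = "integer",
                                  assignments = "matrix", seed = "integer"))

setValidity("CVPlan", function(object) {
  a <- object@assignments
  msg <- character()
  if (nrow(a) != object@replicates || ncol(a) != object@n)
    msg <- c(msg, "assignments must be replicates x n")
  for (r in seq_len(nrow(a))) {
    sizes <- tabulate(a[r, ], nbins = object@k)
    if (sum(sizes) != object@n) { msg <- c(msg, "folds must partition individuals"); break }
    if (max(sizes) - min(sizes) > 1L) { msg <- c(msg, "fold sizes may differ by at most 1"); break }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname gpbench-generics
#' @export
setMethod("foldAssignments", "CVPlan", function(x) x@assignments)

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d individuals, %d folds x %d replicates (seed %d)\n",
              object@n, object@k, object@replicates, object@seed))
})

#' GenomicPredictor: virtual parent of fitted prediction machines
#'
#' All fitted models answer `predict(object, newdata)` where `newdata` is a
#' genotype-code matrix in the feature space the model was trained on, and
#' return one value per row. Predictions are deterministic given the fitted
#' state.
#'
#' @slot method method label ("gblup", "bayesb", "rf", "gb", "mlp", "cnn").
#' @slot nFeatures number of marker columns the model was trained on.
#' @aliases GenomicPredictor-class
#' @export
setClass("GenomicPredictor",
         representation("VIRTUAL", method = "character", nFeatures = "integer"))

setMethod("show", "GenomicPredictor", function(object) {
  cat(sprintf("<%s> fitted %s model on %d features\n",
              class(object), object@method, object@nFeatures))
})

#' @aliases GBLUPModel-class
#' @rdname GenomicPredictor-class
#' @export
setClass("GBLUPModel", contains = "GenomicPredictor",
         representation(mu = "numeric", markerWeights = "numeric",
                        freqs = "numeric", lambda = "numeric",
                        mode = "character", posterior = "list",
                        config = "list"))

#' @aliases BayesBModel-class
#' @rdname GenomicPredictor-class
#' @export
setClass("BayesBModel", contains = "GenomicPredictor",
         representation(mu = "numeric", beta = "numeric",
                        centers = "numeric", inclusion = "numeric",
                        posterior = "list", config = "list"))

#' @aliases RFModel-class
#' @rdname GenomicPredictor-class
#' @export
setClass("RFModel", contains = "GenomicPredictor",
         representation(fit = "ANY", oobMSE = "numeric", config = "list"))

#' @aliases GBModel-class
#' @rdname GenomicPredictor-class
#' @export
setClass("GBModel", contains = "GenomicPredictor",
         representation(fit = "ANY", bestIter = "integer", config = "list"))

#' @aliases MLPModel-class
#' @rdname GenomicPredictor-class
#' @export
setClass("MLPModel", contains = "GenomicPredictor",
         representation(params = "list", center = "numeric", scale = "numeric",
                        yCenter = "numeric", yScale = "numeric",
                        curve = "data.frame", config = "list"))

#' @aliases CNNModel-class
#' @rdname GenomicPredictor-class
#' @export
setClass("CNNModel", contains = "GenomicPredictor",
         representation(params = "list", center = "numeric", scale = "numeric",
                        yCenter = "numeric", yScale = "numeric",
                        curve = "data.frame", geometry = "list",
                        config = "list"))
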