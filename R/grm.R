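#' Compute the additive genomic relationship matrix
#'
#' `G = Z Z' / m` with `z_ij = (x_ij - 2 p_j) / sqrt(2 p_j q_j)`, the
#' centered and standardized genotype codes. Under this standardization the
#' average diagonal is close to 1.
#'
#' @param g a [GenotypeData-class] or a complete genotype-code matrix
#'   (samples x SNPs).
#' @param freqs optional per-SNP "A"-allele frequencies to standardize
#'   with; defaults to the frequencies observed in `g`.
#' @return A [GRM-class].
#' @export
#' @examples
#' codes <- matrix(c(0L, 2L, 2L, 0L), 2, 2)
#' grmMatrix(computeGRM(codes))
computeGRM <- function(g, freqs = NULL) {
  codes <- if (is(g, "GenotypeData")) genoCodes(g) else as.matrix(g)
  .check(!anyNA(codes), "GRM requires complete genotypes (impute first)")
  ids <- rownames(codes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(codes)))
  p <- if (is.null(freqs)) colMeans(codes) / 2 else freqs
  .check(all(p > 0 & p < 1), "monomorphic (zero-variance) SNP column")
  Z <- .standardizeCodes(codes, p)
  G <- tcrossprod(Z) / ncol(Z)
  dimnames(G) <- list(ids, ids)
  new("GRM", matrix = G, nMarkers = ncol(Z), sampleIDs = ids)
}

# centered, standardized marker matrix Z
.standardizeCodes <- function(codes, p) {
  storage.mode(codes) <- "double"
  sweep(sweep(codes, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
}
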