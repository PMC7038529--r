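#' Read a genotype matrix from TSV, VCF or PLINK .raw
#'
#' Codes are mapped to 0/1/2 counts of the "A" (for VCF: ALT) allele, with
#' `NA` for missing. All three formats round-trip with [writeGenotypes()].
#'
#' Formats:
#' \describe{
#'   \item{`tsv`}{samples x SNPs table; first column `sample`, remaining
#'     columns one SNP each. Map information is not carried, so chromosome
#'     defaults to `"1"` and positions to the column order.}
#'   \item{`vcf`}{VCF v4.2 with biallelic SNP records and a `GT` field;
#'     the code is the ALT-allele count (`0/1` is 1, `./.` is missing).
#'     Multi-allelic records are rejected with the offending SNP ID.}
#'   \item{`plink_raw`}{PLINK `--recode A` output: six leading columns
#'     (FID IID PAT MAT SEX PHENOTYPE) then one allele-count column per
#'     SNP, `NA` for missing.}
#' }
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"vcf"`, `"plink_raw"`.
#' @return A [GenotypeData-class] object.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf", "plink_raw")) {
  format <- match.arg(format)
  .check(file.exists(path), "file not found: %s", path)
  switch(format,
         tsv = .readTSV(path),
         vcf = .readVCF(path),
         plink_raw = .readRaw(path))
}

.readTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  .check(colnames(dt)[1] == "sample", "malformed header: first column must be 'sample'")
  samples <- as.character(dt[[1]])
  codes <- as.matrix(dt[, -1, drop = FALSE])
  .checkCodes(codes)
  GenotypeData(codes, chrom = rep("1", ncol(codes)),
               pos = seq_len(ncol(codes)),
               snpID = colnames(codes), sampleID = samples)
}

.readVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  .check(!any(multi), "multi-allelic record(s): %s",
         paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  # count ALT alleles; accept / or | separators
  codeOf <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    ifelse(is.na(x) | x == "./.", NA_integer_,
           ifelse(x == "0/0", 0L,
                  ifelse(x %in% c("0/1", "1/0"), 1L,
                         ifelse(x == "1/1", 2L, NA_integer_))))
  }
  codes <- matrix(codeOf(as.vector(gt)), nrow = nrow(gt))  # SNPs x samples
  GenotypeData(t(codes), chrom = fix[, "CHROM"],
               pos = as.integer(fix[, "POS"]),
               snpID = fix[, "ID"], sampleID = colnames(gt))
}

.readRaw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, na.strings = "NA")
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  .check(all(lead %in% colnames(dt)[1:6]), "malformed PLINK .raw header")
  samples <- as.character(dt[["IID"]])
  codes <- as.matrix(dt[, -(1:6), drop = FALSE])
  .checkCodes(codes)
  # strip the trailing _<allele> PLINK appends to SNP names
  snp <- sub("_[ACGT0-9]+$", "", colnames(codes))
  GenotypeData(codes, chrom = rep("1", ncol(codes)),
               pos = seq_len(ncol(codes)), snpID = snp, sampleID = samples)
}

#' Write a genotype matrix to TSV, VCF or PLINK .raw
#'
#' Inverse of [readGenotypes()] with deterministic column order. The VCF
#' writer emits v4.2 with placeholder REF/ALT alleles (`A`/`C`) and a `GT`
#' field only, coding the "A" allele as ALT so that codes round-trip.
#'
#' @param g a [GenotypeData-class] object.
#' @param path output file path.
#' @param format one of `"tsv"`, `"vcf"`, `"plink_raw"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path, format = c("tsv", "vcf", "plink_raw")) {
  stopifnot(is(g, "GenotypeData"))
  format <- match.arg(format)
  codes <- genoCodes(g)
  switch(format,
         tsv = {
           dt <- data.table::data.table(sample = sampleIDs(g))
           dt <- cbind(dt, data.table::as.data.table(codes))
           data.table::setnames(dt, c("sample", snpIDs(g)))
           data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
         },
         vcf = {
           map <- snpMap(g)
           gtStr <- matrix(c("0/0", "0/1", "1/1")[codes + 1L],
                           nrow = nrow(codes))
           gtStr[is.na(gtStr)] <- "./."
           lines <- c("##fileformat=VCFv4.2",
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", sampleIDs(g)),
                            collapse = "\t"))
           body <- vapply(seq_len(nSNPs(g)), function(j) {
             paste(c(map$chrom[j], map$pos[j], map$snp[j], "A", "C", ".",
                     "PASS", ".", "GT", gtStr[, j]), collapse = "\t")
           }, character(1))
           writeLines(c(lines, body), path)
         },
         plink_raw = {
           dt <- data.table::data.table(FID = sampleIDs(g),
                                        IID = sampleIDs(g),
                                        PAT = 0L, MAT = 0L, SEX = 0L,
                                        PHENOTYPE = -9L)
           dt <- cbind(dt, data.table::as.data.table(codes))
           data.table::setnames(dt, c("FID", "IID", "PAT", "MAT", "SEX",
                                      "PHENOTYPE", paste0(snpIDs(g), "_A")))
           data.table::fwrite(dt, path, sep = " ", na = "NA", quote = FALSE)
         })
  invisible(path)
}
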