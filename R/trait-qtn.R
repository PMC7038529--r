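#' Place quantitative trait nucleotides on a genotype panel
#'
#' Two placement modes:
#' \describe{
#'   \item{`random`}{`nQTN` SNP columns sampled uniformly without
#'     replacement.}
#'   \item{`clustered`}{`floor(nQTN / 3)` core SNPs are sampled; each core
#'     together with its two immediate map neighbours (same chromosome)
#'     forms a cluster of three contiguous QTN. Clusters do not overlap;
#'     cores whose neighbours are unavailable are resampled. If
#'     `3 * floor(nQTN / 3) < nQTN`, additional random singleton QTN top up
#'     the set to exactly `nQTN`.}
#' }
#'
#' @param g a [GenotypeData-class] object.
#' @param nQTN number of causal loci.
#' @param mode `"clustered"` or `"random"`.
#' @param seed integer RNG seed.
#' @return A [QTNSet-class] with indices sorted in genome order.
#' @export
placeQTN <- function(g, nQTN, mode = c("clustered", "random"), seed = 1) {
  stopifnot(is(g, "GenotypeData"))
  mode <- match.arg(mode)
  m <- nSNPs(g)
  .check(nQTN >= 1 && nQTN <= m, "nQTN must be in [1, %d]", m)
  set.seed(as.integer(seed))

  if (mode == "random") {
    idx <- sort(sample.int(m, nQTN))
    return(new("QTNSet", indices = idx,
               coreFlags = rep(FALSE, nQTN), placement = "random"))
  }

  chrom <- snpMap(g)$chrom
  # candidate cores: both immediate neighbours exist on the same chromosome
  inner <- 2:(m - 1)
  candidates <- inner[chrom[inner - 1L] == chrom[inner] &
                        chrom[inner + 1L] == chrom[inner]]
  .check(length(candidates) > 0, "no chromosome long enough for a QTN cluster")

  nCores <- nQTN %/% 3L
  used <- logical(m)
  cores <- integer(0)
  pool <- sample(candidates)     # randomized candidate order
  for (core in pool) {
    if (length(cores) == nCores) break
    block <- (core - 1L):(core + 1L)
    if (any(used[block])) next   # overlap: resample (next candidate)
    used[block] <- TRUE
    cores <- c(cores, core)
  }
  .check(length(cores) == nCores,
         "could not place %d non-overlapping clusters", nCores)

  qtn <- which(used)
  topUp <- nQTN - 3L * nCores
  if (topUp > 0) {
    free <- which(!used)
    qtn <- c(qtn, sample(free, topUp))
  }
  idx <- sort(unique(qtn))
  new("QTNSet", indices = as.integer(idx),
      coreFlags = idx %in% cores, placement = "clustered")
}

#' Build the two-locus epistatic pair list
#'
#' Every QTN interacts with the three QTN that follow it in genome order:
#' pairs are `(k, k+1)`, `(k, k+2)`, `(k, k+3)` over QTN ranks wherever the
#' second member exists, giving exactly `3 nQTN - 6` pairs for
#' `nQTN >= 3` (294 pairs for 100 QTN, 2994 for 1000).
#'
#' @param q a [QTNSet-class] (or an integer giving the number of QTN).
#' @return Integer matrix with columns `k`, `kp` of QTN ranks, `k < kp`.
#' @export
#' @examples
#' nrow(epistaticPairs(100))  # 294
epistaticPairs <- function(q) {
  nQTN <- if (is(q, "QTNSet")) length(q@indices) else as.integer(q)
  .check(nQTN >= 4, "epistatic pairs require at least 4 QTN")
  k <- rep(seq_len(nQTN - 1L), each = 3L)
  kp <- k + rep(1:3, times = nQTN - 1L)
  keep <- kp <= nQTN
  cbind(k = k[keep], kp = kp[keep])
}
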