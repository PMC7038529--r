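#' Trait architecture configuration
#'
#' Describes the gene action, number and placement of causal loci, and the
#' targeted variance partition of a simulated trait. When the heritability
#' targets are not given they default to the reference conditions: purely
#' additive traits target `h2_a = 0.30`; non-additive traits target
#' `(0.10, 0.10, 0.50)` at 100 QTN and `(0.02, 0.02, 0.68)` at 1000 QTN
#' (broad-sense 0.70 in both cases).
#'
#' @param geneAction `"additive"` or `"nonadditive"`. Additive action
#'   forces the dominance and epistasis targets to zero.
#' @param nQTN number of causal loci (typically 100 or 1000; any
#'   positive count is accepted).
#' @param placement QTN placement mode, see [placeQTN()].
#' @param h2A,h2D,h2I targeted fractions of phenotypic variance for the
#'   additive, dominance and epistatic components; their sum must be < 1.
#' @param seed integer master seed; placement, each effect class and the
#'   residuals consume independent sub-seeded streams.
#' @return A validated config list of class `architectureConfig`.
#' @export
architectureConfig <- function(geneAction = c("additive", "nonadditive"),
                               nQTN = 100,
                               placement = c("clustered", "random"),
                               h2A = NULL, h2D = NULL, h2I = NULL,
                               seed = 1) {
  geneAction <- match.arg(geneAction)
  placement <- match.arg(placement)
  if (geneAction == "additive") {
    h2A <- if (is.null(h2A)) 0.30 else h2A
    .check(is.null(h2D) || h2D == 0, "additive action forces h2D = 0")
    .check(is.null(h2I) || h2I == 0, "additive action forces h2I = 0")
    h2D <- 0; h2I <- 0
  } else {
    if (is.null(h2A)) h2A <- if (nQTN >= 1000) 0.02 else 0.10
    if (is.null(h2D)) h2D <- if (nQTN >= 1000) 0.02 else 0.10
    if (is.null(h2I)) h2I <- if (nQTN >= 1000) 0.68 else 0.50
  }
  .check(h2A >= 0 && h2D >= 0 && h2I >= 0, "heritability targets must be >= 0")
  .check(h2A + h2D + h2I < 1, "targets must sum to less than 1")
  structure(list(geneAction = geneAction, nQTN = as.integer(nQTN),
                 placement = placement, h2A = h2A, h2D = h2D, h2I = h2I,
                 seed = as.integer(seed)),
            class = "architectureConfig")
}

#' Dominance coding of a genotype column
#'
#' Maps additive codes to the dominance incidence: aa (0) -> 0,
#' Aa (1) -> 1, AA (2) -> 0.
#'
#' @param x genotype codes in \{0, 1, 2\}.
#' @return Numeric vector of 0/1 dominance codes.
#' @export
#' @examples
#' dominanceCode(c(0, 1, 2))  # 0 1 0
dominanceCode <- function(x) {
  .checkCodes(x)
  .check(!anyNA(x), "dominance coding requires complete genotypes")
  as.numeric(x == 1)
}

#' Two-locus interaction coding
#'
#' Hadamard (element-wise) product of the additive (0/1/2) and/or dominance
#' (0/1) codings of two loci. `"AA"` takes both columns additive (values in
#' \{0, 1, 2, 4\}), `"AD"`/`"DA"` mix additive and dominance (\{0, 1, 2\})
#' and `"DD"` takes both dominance (\{0, 1\}).
#'
#' @param col1,col2 coded genotype columns; `col1` is additive for
#'   `"AA"`/`"AD"` and dominance for `"DA"`/`"DD"`, `col2` analogously.
#' @param kind interaction class, one of `"AA"`, `"AD"`, `"DA"`, `"DD"`.
#' @return Numeric vector of interaction codes.
#' @export
#' @examples
#' interactionCode(c(2, 1, 0), c(2, 2, 1), "AA")  # 4 2 0
interactionCode <- function(col1, col2, kind = c("AA", "AD", "DA", "DD")) {
  kind <- match.arg(kind)
  .check(length(col1) == length(col2), "column length mismatch")
  chkA <- function(v) .check(all(v %in% c(0, 1, 2)), "additive codes must be 0/1/2")
  chkD <- function(v) .check(all(v %in% c(0, 1)), "dominance codes must be 0/1")
  switch(kind,
         AA = { chkA(col1); chkA(col2) },
         AD = { chkA(col1); chkD(col2) },
         DA = { chkD(col1); chkA(col2) },
         DD = { chkD(col1); chkD(col2) })
  as.numeric(col1) * as.numeric(col2)
}

#' Sample QTN effects
#'
#' Additive effects are standard-normal draws; dominance effects are
#' N(0, sd = 0.5) (zero under additive action); allele-substitution effects
#' are `alpha_k = a_k + d_k (q_k - p_k)`. Each of the four epistatic effect
#' vectors has magnitudes drawn from a gamma distribution with shape 0.1
#' and scale 10, and an independent sign that is positive or negative with
#' probability 0.5 each (all zero under additive action). Each effect class
#' consumes its own sub-seeded RNG stream, so e.g. changing the placement
#' never perturbs the effect draws.
#'
#' @param q a [QTNSet-class].
#' @param pairs integer pair matrix from [epistaticPairs()] (may have zero
#'   rows under additive action).
#' @param arch an [architectureConfig()].
#' @param freqs per-QTN "A"-allele frequencies `p_k` in (0, 1).
#' @return An [EffectSet-class].
#' @export
sampleEffects <- function(q, pairs, arch, freqs) {
  stopifnot(is(q, "QTNSet"), inherits(arch, "architectureConfig"))
  nQTN <- length(q@indices)
  .check(length(freqs) == nQTN, "freqs must have one entry per QTN")
  .check(all(freqs > 0 & freqs < 1), "freqs must be in (0, 1)")
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2,
                                      dimnames = list(NULL, c("k", "kp")))
  nP <- nrow(pairs)

  set.seed(deriveSeed(arch$seed, "additive"))
  a <- rnorm(nQTN)
  set.seed(deriveSeed(arch$seed, "dominance"))
  d <- if (arch$geneAction == "additive") numeric(nQTN) else rnorm(nQTN, 0, 0.5)
  alpha <- a + d * ((1 - freqs) - freqs)

  if (arch$geneAction == "additive" || nP == 0) {
    epi <- replicate(4, numeric(nP), simplify = FALSE)
  } else {
    set.seed(deriveSeed(arch$seed, "epimagnitude"))
    mags <- replicate(4, rgamma(nP, shape = 0.1, scale = 10), simplify = FALSE)
    set.seed(deriveSeed(arch$seed, "episign"))
    signs <- replicate(4, sample(c(-1, 1), nP, replace = TRUE), simplify = FALSE)
    epi <- Map(`*`, mags, signs)
  }
  new("EffectSet", additive = a, dominance = d, substitution = alpha,
      pairs = pairs, epiAA = epi[[1]], epiAD = epi[[2]],
      epiDA = epi[[3]], epiDD = epi[[4]])
}
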