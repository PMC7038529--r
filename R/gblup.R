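#' GBLUP configuration
#'
#' @param mode `"closed_form"` (mixed-model solve at a fixed variance
#'   ratio) or `"gibbs"` (Bayesian sampling of mean, genetic values and
#'   variance components). The closed form is the desk-scale default.
#' @param h2 assumed heritability; sets the variance ratio
#'   `lambda = (1 - h2) / h2` in closed form and the prior scales under
#'   Gibbs.
#' @param nIter,burnIn,thin Gibbs chain settings. Desk-scale defaults are
#'   (6000, 1000, 5); the full-scale protocol is (100000, 10000, 10).
#' @param df0 prior degrees of freedom of the scaled-inverse-chi-square
#'   variance priors (Gibbs mode).
#' @param jitter ridge added to the diagonal of `G` before inversion.
#' @param seed integer RNG seed (Gibbs mode).
#' @return A validated config list of class `gblupConfig`.
#' @export
gblupConfig <- function(mode = c("closed_form", "gibbs"), h2 = 0.5,
                        nIter = 6000, burnIn = 1000, thin = 5,
                        df0 = 5, jitter = 1e-8, seed = 1) {
  mode <- match.arg(mode)
  .check(h2 > 0 && h2 < 1, "h2 must be in (0, 1)")
  .check(burnIn < nIter, "burnIn must be smaller than nIter")
  .check(jitter >= 0, "jitter must be >= 0")
  structure(list(mode = mode, h2 = h2, nIter = as.integer(nIter),
                 burnIn = as.integer(burnIn), thin = as.integer(thin),
                 df0 = df0, jitter = jitter, seed = as.integer(seed)),
            class = "gblupConfig")
}

#' Fit GBLUP on a training panel
#'
#' Model `y = 1 mu + g_A + e` with `g_A ~ N(0, G sigma2_g)`,
#' `G = Z Z' / m` from centered, standardized genotypes.
#'
#' Closed form: `y` is centered at the training mean and the training-block
#' system `(G + lambda I) u = y - mu` is solved at the fixed ratio
#' `lambda = sigma2_e / sigma2_g = (1 - h2) / h2`. Predictions for new
#' individuals use the conditional expectation
#' `g_new = G_new,train (G + lambda I)^{-1} (y - mu)`, carried in marker
#' space so that any genotype matrix in the training feature space can be
#' scored; this is algebraically identical to ridge regression on markers
#' with penalty `m lambda`.
#'
#' Gibbs: the training GRM is eigendecomposed and the orthogonal
#' regression coefficients, mean and the two variance components are
#' sampled with scaled-inverse-chi-square priors; predictions use the
#' conditional-expectation map at the posterior-mean variance ratio and
#' mean.
#'
#' @param y numeric training phenotypes.
#' @param codes training genotype-code matrix (samples x markers,
#'   complete), or a [GenotypeData-class].
#' @param config a [gblupConfig()].
#' @return A [GBLUPModel-class]; use `predict(model, newCodes)`.
#' @export
fitGBLUP <- function(y, codes, config = gblupConfig()) {
  stopifnot(inherits(config, "gblupConfig"))
  codes <- if (is(codes, "GenotypeData")) genoCodes(codes) else as.matrix(codes)
  .check(length(y) == nrow(codes), "y length must match genotype rows")
  .check(!anyNA(codes), "training genotypes must be complete")
  n <- length(y); m <- ncol(codes)
  p <- colMeans(codes) / 2
  .check(all(p > 0 & p < 1), "monomorphic SNP column in training set")
  Z <- .standardizeCodes(codes, p)
  G <- tcrossprod(Z) / m
  diag(G) <- diag(G) + config$jitter

  if (config$mode == "closed_form") {
    mu <- mean(y)
    lambda <- (1 - config$h2) / config$h2
    u <- solve(G + diag(lambda, n), y - mu)
    w <- drop(crossprod(Z, u)) / m
    posterior <- list()
  } else {
    eg <- eigen(G, symmetric = TRUE)
    keep <- eg$values > 1e-10
    U <- eg$vectors[, keep, drop = FALSE]
    lam <- eg$values[keep]
    r <- sum(keep)
    vy <- var(y)
    S0g <- vy * config$h2
    S0e <- vy * (1 - config$h2)
    df0 <- config$df0
    set.seed(config$seed)
    mu <- mean(y); s2g <- S0g; s2e <- S0e
    dcoef <- numeric(r)
    keepIter <- seq(config$burnIn + config$thin, config$nIter, by = config$thin)
    sums <- list(mu = 0, s2g = 0, s2e = 0, g = numeric(n), h2 = 0)
    nKept <- 0L
    uty <- drop(crossprod(U, y))
    ut1 <- drop(crossprod(U, rep(1, n)))
    for (it in seq_len(config$nIter)) {
      # orthogonal coefficients: independent normal full conditionals
      prec <- 1 / s2e + 1 / (lam * s2g)
      mean_d <- (uty - mu * ut1) / s2e / prec
      dcoef <- rnorm(r, mean_d, sqrt(1 / prec))
      gvec <- drop(U %*% dcoef)
      resid <- y - mu - gvec
      mu <- rnorm(1, mean(resid + mu), sqrt(s2e / n))
      resid <- y - mu - gvec
      s2g <- (sum(dcoef^2 / lam) + df0 * S0g) / rchisq(1, r + df0)
      s2e <- (sum(resid^2) + df0 * S0e) / rchisq(1, n + df0)
      if (it %in% keepIter) {
        nKept <- nKept + 1L
        sums$mu <- sums$mu + mu
        sums$s2g <- sums$s2g + s2g
        sums$s2e <- sums$s2e + s2e
        sums$g <- sums$g + gvec
        sums$h2 <- sums$h2 + s2g / (s2g + s2e)
      }
    }
    mu <- sums$mu / nKept
    s2gHat <- sums$s2g / nKept
    s2eHat <- sums$s2e / nKept
    lambda <- s2eHat / s2gHat
    gHat <- sums$g / nKept
    # marker-space map of the conditional expectation: g_new =
    # G_new,train (G + lambda I)^{-1} (y - mu) at the posterior-mean ratio
    w <- drop(crossprod(Z, solve(G + diag(lambda, n), y - mu))) / m
    posterior <- list(mu = mu, sigma2g = s2gHat, sigma2e = s2eHat,
                      h2 = sums$h2 / nKept, retained = nKept)
  }
  new("GBLUPModel", method = "gblup", nFeatures = m, mu = mu,
      markerWeights = w, freqs = p, lambda = lambda,
      mode = config$mode, posterior = posterior,
      config = unclass(config))
}

#' @describeIn fitGBLUP predict genetic merit for new individuals; `newdata`
#'   is a genotype-code matrix with the training marker columns.
#' @param object a fitted [GBLUPModel-class].
#' @param newdata genotype-code matrix (samples x markers).
#' @export
setMethod("predict", "GBLUPModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  .check(ncol(newdata) == object@nFeatures,
         "column mismatch: model expects %d markers", object@nFeatures)
  Z <- .standardizeCodes(newdata, object@freqs)
  drop(object@mu + Z %*% object@markerWeights)
})
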