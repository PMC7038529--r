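# Feed-forward networks trained by mini-batch SGD with momentum and L2
# weight decay. Both architectures follow the tuned reference settings; the
# implementation is plain R matrix algebra (single-threaded BLAS ops), so
# identical seeds give bit-identical training runs.

.actFun <- function(name) {
  switch(name,
         relu = list(f = function(x) pmax(x, 0),
                     grad = function(x) (x > 0) * 1),
         softplus = list(
           # numerically stable log(1 + exp(x)); gradient is the sigmoid
           f = function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x))),
           grad = function(x) 1 / (1 + exp(-x))),
         linear = list(f = identity, grad = function(x) 1),
         stop("unknown activation: ", name))
}

# column-standardize with a zero-variance guard
.fitScaler <- function(X) {
  ctr <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(center = ctr, scale = sdv)
}
.applyScaler <- function(X, sc) sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")

# inverted dropout mask (training only)
.dropMask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(dim1 * dim2) >= rate) / (1 - rate), dim1, dim2)
}

# momentum + L2 weight-decay update, in place on a parameter list
.sgdStep <- function(params, grads, vel, lr, momentum, decay, decaySet) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (nm %in% decaySet) g <- g + 2 * decay * params[[nm]]
    vel[[nm]] <- momentum * vel[[nm]] - lr * g
    params[[nm]] <- params[[nm]] + vel[[nm]]
  }
  list(params = params, vel = vel)
}

#' Multilayer perceptron configuration
#'
#' Defaults are the tuned reference settings: two hidden layers of 64 and
#' 32 units (ReLU then softReLU/softplus), dropout 0.1 after each hidden
#' layer, SGD with learning rate 0.01, momentum 0.5, weight decay 1e-5,
#' batch size 32 and 200 epochs.
#'
#' @param hiddenUnits integer vector of hidden-layer sizes.
#' @param activations activation per hidden layer (`"relu"`,
#'   `"softplus"`).
#' @param dropout dropout rate per hidden layer.
#' @param learningRate,momentum,weightDecay,batchSize,epochs SGD settings.
#' @param validationFraction fraction held out to track the per-epoch
#'   validation MSE in the training curve.
#' @param seed integer RNG seed.
#' @return A validated config list of class `mlpConfig`.
#' @export
mlpConfig <- function(hiddenUnits = c(64, 32),
                      activations = c("relu", "softplus"),
                      dropout = c(0.1, 0.1),
                      learningRate = 0.01, momentum = 0.5,
                      weightDecay = 1e-5, batchSize = 32, epochs = 200,
                      validationFraction = 0.1, seed = 1) {
  .check(length(hiddenUnits) == length(activations) &&
           length(hiddenUnits) == length(dropout),
         "hiddenUnits/activations/dropout lengths must agree")
  .check(epochs >= 0, "epochs must be >= 0")
  structure(list(hiddenUnits = as.integer(hiddenUnits),
                 activations = activations, dropout = dropout,
                 learningRate = learningRate, momentum = momentum,
                 weightDecay = weightDecay, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 validationFraction = validationFraction,
                 seed = as.integer(seed)),
            class = "mlpConfig")
}

.initW <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)

.mlpForward <- function(X, params, cfg, train = FALSE) {
  a1 <- .actFun(cfg$activations[1]); a2 <- .actFun(cfg$activations[2])
  z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  h1 <- a1$f(z1)
  m1 <- if (train) .dropMask(nrow(h1), ncol(h1), cfg$dropout[1]) else NULL
  h1d <- if (is.null(m1)) h1 else h1 * m1
  z2 <- sweep(h1d %*% params$W2, 2, params$b2, "+")
  h2 <- a2$f(z2)
  m2 <- if (train) .dropMask(nrow(h2), ncol(h2), cfg$dropout[2]) else NULL
  h2d <- if (is.null(m2)) h2 else h2 * m2
  out <- drop(h2d %*% params$W3 + params$b3)
  list(z1 = z1, h1d = h1d, m1 = m1, z2 = z2, h2d = h2d, m2 = m2, out = out)
}

#' Fit a multilayer perceptron regressor
#'
#' Two-hidden-layer feed-forward network trained by mini-batch SGD with
#' momentum, minimizing the penalized loss
#' `(1/2n) sum (y - yhat)^2 + lambda (||W1||^2 + ||W2||^2 + ||W3||^2)`.
#' Inputs are column-standardized internally and the response is
#' standardized for training (predictions are returned on the original
#' scale). The per-epoch train/validation MSE curve (original response
#' units) is retained in the `curve` slot for overfitting inspection.
#'
#' @param y numeric training phenotypes.
#' @param X training genotype-code matrix (samples x markers, complete).
#' @param config an [mlpConfig()].
#' @return An [MLPModel-class].
#' @export
fitMLP <- function(y, X, config = mlpConfig()) {
  stopifnot(inherits(config, "mlpConfig"))
  .check(length(config$hiddenUnits) == 2,
         "this implementation expects exactly two hidden layers")
  X <- as.matrix(X)
  .check(!anyNA(X), "training genotypes must be complete")
  n <- nrow(X); m <- ncol(X)
  set.seed(config$seed)
  sc <- .fitScaler(X)
  Xs <- .applyScaler(X, sc)
  yC <- mean(y); yS <- sd(y); if (yS < 1e-12) yS <- 1
  ys <- (y - yC) / yS

  nVal <- max(2L, round(config$validationFraction * n))
  valIdx <- sample.int(n, nVal)
  Xtr <- Xs[-valIdx, , drop = FALSE]; ytr <- ys[-valIdx]
  Xva <- Xs[valIdx, , drop = FALSE]; yva <- ys[valIdx]
  ntr <- nrow(Xtr)

  h <- config$hiddenUnits
  params <- list(W1 = .initW(m, h[1]), b1 = numeric(h[1]),
                 W2 = .initW(h[1], h[2]), b2 = numeric(h[2]),
                 W3 = matrix(0, h[2], 1), b3 = 0)  # zero output init: first
                 # predictions sit at the response mean
  vel <- lapply(params, function(p) p * 0)
  decaySet <- c("W1", "W2", "W3")
  a1 <- .actFun(config$activations[1]); a2 <- .actFun(config$activations[2])

  curve <- data.frame(epoch = integer(0), trainMSE = numeric(0),
                      valMSE = numeric(0))
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1, ntr, by = config$batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + config$batchSize - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
      B <- length(idx)
      fw <- .mlpForward(Xb, params, config, train = TRUE)
      if (anyNA(fw$out) || any(!is.finite(fw$out)))
        stop(sprintf("MLP: non-finite loss at epoch %d", ep))
      dOut <- matrix((fw$out - yb) / B, ncol = 1)
      gW3 <- crossprod(fw$h2d, dOut); gb3 <- sum(dOut)
      dH2 <- dOut %*% t(params$W3)
      if (!is.null(fw$m2)) dH2 <- dH2 * fw$m2
      dZ2 <- dH2 * a2$grad(fw$z2)
      gW2 <- crossprod(fw$h1d, dZ2); gb2 <- colSums(dZ2)
      dH1 <- dZ2 %*% t(params$W2)
      if (!is.null(fw$m1)) dH1 <- dH1 * fw$m1
      dZ1 <- dH1 * a1$grad(fw$z1)
      gW1 <- crossprod(Xb, dZ1); gb1 <- colSums(dZ1)
      st <- .sgdStep(params,
                     list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                          W3 = gW3, b3 = gb3),
                     vel, config$learningRate, config$momentum,
                     config$weightDecay, decaySet)
      params <- st$params; vel <- st$vel
    }
    predTr <- .mlpForward(Xtr, params, config)$out
    predVa <- .mlpForward(Xva, params, config)$out
    curve <- rbind(curve, data.frame(
      epoch = ep,
      trainMSE = mean((predTr - ytr)^2) * yS^2,
      valMSE = mean((predVa - yva)^2) * yS^2))
  }
  new("MLPModel", method = "mlp", nFeatures = m, params = params,
      center = sc$center, scale = sc$scale, yCenter = yC, yScale = yS,
      curve = curve, config = unclass(config))
}

#' @describeIn fitMLP prediction (dropout disabled) on the original
#'   response scale.
#' @param object a fitted [MLPModel-class].
#' @param newdata genotype-code matrix (samples x markers).
#' @export
setMethod("predict", "MLPModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  .check(ncol(newdata) == object@nFeatures,
         "column mismatch: model expects %d markers", object@nFeatures)
  Xs <- .applyScaler(newdata, list(center = object@center, scale = object@scale))
  cfg <- object@config
  out <- .mlpForward(Xs, object@params, cfg)$out
  out * object@yScale + object@yCenter
})

#' Convolution/pooling output geometry of the 1-D CNN
#'
#' @param m input length (number of markers).
#' @param kernel,stride convolution window and stride.
#' @param pool,poolStride pooling window and stride.
#' @return List with `convLen` and `poolLen`.
#' @export
#' @examples
#' convGeometry(5000)  # convLen 1666, poolLen 833
convGeometry <- function(m, kernel = 5, stride = 3, pool = 2, poolStride = 2) {
  .check(kernel >= 1 && stride >= 1 && pool >= 1 && poolStride >= 1,
         "kernel/stride values must be positive")
  convLen <- floor((m - kernel) / stride) + 1
  .check(convLen >= 1, "input too short for the convolution window")
  poolLen <- floor((convLen - pool) / poolStride) + 1
  .check(poolLen >= 1, "convolution output too short for the pooling window")
  list(convLen = as.integer(convLen), poolLen = as.integer(poolLen))
}

#' Convolutional network configuration
#'
#' Defaults are the tuned reference settings: one convolutional layer of 16
#' filters (window 1x5, stride 1x3, ReLU), max pooling (window 1x2, stride
#' 1x2) with dropout 0.3, a 32-unit fully connected softReLU layer with
#' dropout 0.3, a 1-unit softReLU layer, and a linear output; SGD with
#' learning rate 0.01, momentum 0.5, weight decay 1e-5, batch size 64,
#' 200 epochs.
#'
#' @param nFilters,kernelSize,convStride convolution settings.
#' @param poolSize,poolStride max-pooling settings.
#' @param dropoutConv,dropoutFc dropout rates after pooling / after the
#'   32-unit layer.
#' @param fc1Units fully connected layer width.
#' @param learningRate,momentum,weightDecay,batchSize,epochs SGD settings.
#' @param validationFraction fraction held out for the training curve.
#' @param seed integer RNG seed.
#' @return A validated config list of class `cnnConfig`.
#' @export
cnnConfig <- function(nFilters = 16, kernelSize = 5, convStride = 3,
                      poolSize = 2, poolStride = 2,
                      dropoutConv = 0.3, dropoutFc = 0.3, fc1Units = 32,
                      learningRate = 0.01, momentum = 0.5,
                      weightDecay = 1e-5, batchSize = 64, epochs = 200,
                      validationFraction = 0.1, seed = 1) {
  .check(nFilters >= 1 && kernelSize >= 1 && convStride >= 1,
         "convolution settings must be positive")
  structure(list(nFilters = as.integer(nFilters),
                 kernelSize = as.integer(kernelSize),
                 convStride = as.integer(convStride),
                 poolSize = as.integer(poolSize),
                 poolStride = as.integer(poolStride),
                 dropoutConv = dropoutConv, dropoutFc = dropoutFc,
                 fc1Units = as.integer(fc1Units),
                 learningRate = learningRate, momentum = momentum,
                 weightDecay = weightDecay, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 validationFraction = validationFraction,
                 seed = as.integer(seed)),
            class = "cnnConfig")
}

# forward pass through conv -> ReLU -> maxpool; returns pooled activations
# (B x poolLen x F) plus caches for backprop
.cnnConvForward <- function(Xb, params, geo, cfg) {
  B <- nrow(Xb); Lc <- geo$convLen; Lp <- geo$poolLen; f <- cfg$nFilters
  starts <- (seq_len(Lc) - 1L) * cfg$convStride + 1L
  Xoff <- lapply(seq_len(cfg$kernelSize),
                 function(o) Xb[, starts + o - 1L, drop = FALSE])
  Cpre <- array(0, c(B, Lc, f))
  for (ff in seq_len(f)) {
    acc <- matrix(params$bc[ff], B, Lc)
    for (o in seq_len(cfg$kernelSize))
      acc <- acc + Xoff[[o]] * params$Wc[o, ff]
    Cpre[, , ff] <- acc
  }
  Crelu <- pmax(Cpre, 0)
  oddIdx <- (seq_len(Lp) - 1L) * cfg$poolStride + 1L
  A1 <- Crelu[, oddIdx, , drop = FALSE]
  A2 <- Crelu[, oddIdx + 1L, , drop = FALSE]
  P <- pmax(A1, A2)
  mask1 <- (A1 >= A2)
  list(Xoff = Xoff, Cpre = Cpre, P = P, mask1 = mask1,
       oddIdx = oddIdx, starts = starts)
}

.cnnForward <- function(Xb, params, geo, cfg, train = FALSE) {
  B <- nrow(Xb); Lp <- geo$poolLen; f <- cfg$nFilters
  conv <- .cnnConvForward(Xb, params, geo, cfg)
  Pf <- matrix(conv$P, B, Lp * f)      # flatten, pool index fastest
  mC <- if (train) .dropMask(B, Lp * f, cfg$dropoutConv) else NULL
  Pd <- if (is.null(mC)) Pf else Pf * mC
  sp <- .actFun("softplus")
  z1 <- sweep(Pd %*% params$W1, 2, params$b1, "+")
  h1 <- sp$f(z1)
  mF <- if (train) .dropMask(B, ncol(h1), cfg$dropoutFc) else NULL
  h1d <- if (is.null(mF)) h1 else h1 * mF
  z2 <- h1d %*% params$W2 + params$b2
  h2 <- sp$f(z2)
  out <- drop(h2 %*% params$W3 + params$b3)
  list(conv = conv, Pd = Pd, mC = mC, z1 = z1, h1d = h1d, mF = mF,
       z2 = z2, h2 = h2, out = out)
}

#' Fit a one-dimensional convolutional network regressor
#'
#' The marker vector is treated as a 1-D sequence: convolution (16
#' filters, window 5, stride 3, ReLU), max pooling (window 2, stride 2),
#' dropout, a 32-unit softReLU layer, dropout, a 1-unit softReLU layer and
#' a linear output unit, trained end-to-end by mini-batch SGD with
#' momentum and weight decay. Inputs and response are standardized as in
#' [fitMLP()].
#'
#' @param y numeric training phenotypes.
#' @param X training genotype-code matrix (samples x markers, complete);
#'   the marker count must be compatible with the conv/pool geometry (see
#'   [convGeometry()]).
#' @param config a [cnnConfig()].
#' @return A [CNNModel-class].
#' @export
fitCNN <- function(y, X, config = cnnConfig()) {
  stopifnot(inherits(config, "cnnConfig"))
  X <- as.matrix(X)
  .check(!anyNA(X), "training genotypes must be complete")
  n <- nrow(X); m <- ncol(X)
  .check(config$poolSize == 2 && config$poolStride == 2,
         "the pooling implementation supports window 2 / stride 2")
  geo <- convGeometry(m, config$kernelSize, config$convStride,
                      config$poolSize, config$poolStride)
  set.seed(config$seed)
  sc <- .fitScaler(X)
  Xs <- .applyScaler(X, sc)
  yC <- mean(y); yS <- sd(y); if (yS < 1e-12) yS <- 1
  ys <- (y - yC) / yS

  nVal <- max(2L, round(config$validationFraction * n))
  valIdx <- sample.int(n, nVal)
  Xtr <- Xs[-valIdx, , drop = FALSE]; ytr <- ys[-valIdx]
  Xva <- Xs[valIdx, , drop = FALSE]; yva <- ys[valIdx]
  ntr <- nrow(Xtr)

  f <- config$nFilters; Lp <- geo$poolLen
  params <- list(Wc = .initW(config$kernelSize, f), bc = numeric(f),
                 W1 = .initW(Lp * f, config$fc1Units),
                 b1 = numeric(config$fc1Units),
                 W2 = .initW(config$fc1Units, 1), b2 = 0,
                 W3 = matrix(0, 1, 1), b3 = 0)
  vel <- lapply(params, function(p) p * 0)
  decaySet <- c("Wc", "W1", "W2", "W3")
  sp <- .actFun("softplus")

  curve <- data.frame(epoch = integer(0), trainMSE = numeric(0),
                      valMSE = numeric(0))
  if (config$epochs > 0) for (ep in seq_len(config$epochs)) {
    ord <- sample.int(ntr)
    startsB <- seq(1, ntr, by = config$batchSize)
    for (s in startsB) {
      idx <- ord[s:min(s + config$batchSize - 1L, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
      B <- length(idx)
      fw <- .cnnForward(Xb, params, geo, config, train = TRUE)
      if (anyNA(fw$out) || any(!is.finite(fw$out)))
        stop(sprintf("CNN: non-finite loss at epoch %d", ep))
      dOut <- matrix((fw$out - yb) / B, ncol = 1)
      gW3 <- crossprod(fw$h2, dOut); gb3 <- sum(dOut)
      dH2 <- dOut %*% t(params$W3)
      dZ2 <- dH2 * sp$grad(fw$z2)
      gW2 <- crossprod(fw$h1d, dZ2); gb2 <- sum(dZ2)
      dH1 <- dZ2 %*% t(params$W2)
      if (!is.null(fw$mF)) dH1 <- dH1 * fw$mF
      dZ1 <- dH1 * sp$grad(fw$z1)
      gW1 <- crossprod(fw$Pd, dZ1); gb1 <- colSums(dZ1)
      dPd <- dZ1 %*% t(params$W1)
      if (!is.null(fw$mC)) dPd <- dPd * fw$mC
      dP <- array(dPd, c(B, Lp, f))
      # route through max pool and ReLU
      dCpre <- array(0, c(B, geo$convLen, f))
      m1 <- fw$conv$mask1
      oddIdx <- fw$conv$oddIdx
      dCpre[, oddIdx, ] <- dP * m1
      dCpre[, oddIdx + 1L, ] <- dP * (1 - m1)
      dCpre <- dCpre * (fw$conv$Cpre > 0)
      gWc <- matrix(0, config$kernelSize, f); gbc <- numeric(f)
      for (ff in seq_len(f)) {
        dC <- dCpre[, , ff]
        gbc[ff] <- sum(dC)
        for (o in seq_len(config$kernelSize))
          gWc[o, ff] <- sum(fw$conv$Xoff[[o]] * dC)
      }
      st <- .sgdStep(params,
                     list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1,
                          W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3),
                     vel, config$learningRate, config$momentum,
                     config$weightDecay, decaySet)
      params <- st$params; vel <- st$vel
    }
    predTr <- .cnnForward(Xtr, params, geo, config)$out
    predVa <- .cnnForward(Xva, params, geo, config)$out
    curve <- rbind(curve, data.frame(
      epoch = ep,
      trainMSE = mean((predTr - ytr)^2) * yS^2,
      valMSE = mean((predVa - yva)^2) * yS^2))
  }
  new("CNNModel", method = "cnn", nFeatures = m, params = params,
      center = sc$center, scale = sc$scale, yCenter = yC, yScale = yS,
      curve = curve, geometry = geo, config = unclass(config))
}

#' @describeIn fitCNN prediction (dropout disabled) on the original
#'   response scale.
#' @param object a fitted [CNNModel-class].
#' @param newdata genotype-code matrix (samples x markers).
#' @export
setMethod("predict", "CNNModel", function(object, newdata) {
  newdata <- as.matrix(newdata)
  .check(ncol(newdata) == object@nFeatures,
         "column mismatch: model expects %d markers", object@nFeatures)
  Xs <- .applyScaler(newdata, list(center = object@center, scale = object@scale))
  out <- .cnnForward(Xs, object@params, object@geometry, object@config)$out
  out * object@yScale + object@yCenter
})
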