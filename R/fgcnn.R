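#' @include AllClasses.R signal_io.R features.R
NULL

#' Construct an FG-CNN configuration
#'
#' See [FGCNNConfig-class] for the meaning of each field. Defaults are the
#' reference architecture for 50 ms windows at 5 kHz (250-sample input):
#' conv filters 2/4/8/16/32 with kernel lengths 5/4/3/2/1, pairwise max
#' pooling after each layer (250 -> 125 -> 62 -> 31 -> 15 -> 7), FC layers of
#' 192 and 14 units, tanh fusion with the 14 handcrafted features, MSE loss,
#' Adam with learning rate 0.001 for 50 epochs.
#'
#' @param inputLen,convFilters,convKernels,poolLen,fcSizes,pDim architecture.
#' @param leakySlope initial learnable LeakyReLU slope.
#' @param learningRate,epochs,batchSize,beta1,beta2,epsilon training.
#' @param standardizeP z-score the handcrafted vector (training statistics)
#'   before it enters the fusion layer.
#' @param seed seed for weight initialisation and batch shuffling.
#' @return an [FGCNNConfig-class].
#' @export
FGCNNConfig <- function(inputLen = 250L, convFilters = c(2L, 4L, 8L, 16L, 32L),
                        convKernels = c(5L, 4L, 3L, 2L, 1L), poolLen = 2L,
                        fcSizes = c(192L, 14L), pDim = 14L, leakySlope = 0.1,
                        learningRate = 0.001, epochs = 50L, batchSize = 64L,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        standardizeP = TRUE, seed = 1L) {
  cfg <- new("FGCNNConfig", inputLen = as.integer(inputLen),
             convFilters = as.integer(convFilters),
             convKernels = as.integer(convKernels),
             poolLen = as.integer(poolLen), fcSizes = as.integer(fcSizes),
             pDim = as.integer(pDim), leakySlope = leakySlope,
             learningRate = learningRate, epochs = as.integer(epochs),
             batchSize = as.integer(batchSize), beta1 = beta1, beta2 = beta2,
             epsilon = epsilon, standardizeP = standardizeP,
             seed = as.integer(seed))
  layerLengths(cfg)  # errors early if some layer would be too short to pool
  cfg
}

#' Baseline (unguided) CNN configuration
#'
#' Same convolutional stack as the FG-CNN, but the feature head is widened to
#' 28 units and no handcrafted vector enters the model: the output is
#' tanh(w . l) over the 28 learned features.
#'
#' @param fcSizes FC layer sizes; the head defaults to 28 learned features.
#' @param ... further overrides passed to [FGCNNConfig()].
#' @export
baselineCNNConfig <- function(fcSizes = c(192L, 28L), ...) {
  FGCNNConfig(fcSizes = fcSizes, pDim = 0L, ...)
}

# Per-layer input lengths and pooled lengths under 'same' conv + pairwise
# pooling; errors if any layer's input drops below 2.
layerLengths <- function(config) {
  L <- config@inputLen
  nIn <- integer(0); nOut <- integer(0)
  for (i in seq_along(config@convFilters)) {
    stopIf(L < 2L, sprintf(
      "conv layer %d input length %d is too short to pool; increase inputLen",
      i, L), class = "fgcnnDimensionError")
    nIn <- c(nIn, L)
    L <- L %/% 2L
    nOut <- c(nOut, L)
  }
  list(convIn = nIn, pooled = nOut,
       flat = nOut[length(nOut)] * config@convFilters[length(config@convFilters)])
}

# Trainable tensor names in the fixed registry order shared with the C++ core.
weightNames <- function(config) {
  nc <- length(config@convFilters)
  nm <- character(0)
  for (i in seq_len(nc)) {
    nm <- c(nm, paste0(c("Wconv", "bconv", "gamma", "beta", "slope"), i))
  }
  nm <- c(nm, "W1", "b1", "slopeFc", "W2", "b2", "wl")
  if (config@pDim > 0L) nm <- c(nm, "wp")
  nm
}

# Config list handed to the C++ core.
cppConfig <- function(config, freezeWl = FALSE) {
  list(convFilters = config@convFilters, convKernels = config@convKernels,
       inputLen = config@inputLen, fc1 = config@fcSizes[1L],
       outDim = config@fcSizes[2L], pDim = config@pDim,
       learningRate = config@learningRate, beta1 = config@beta1,
       beta2 = config@beta2, epsilon = config@epsilon, freezeWl = freezeWl)
}

#' Initialise FG-CNN parameters
#'
#' Weights are drawn uniformly on +/- 1/sqrt(fan-in) under the config seed;
#' biases start at zero, batch-norm scale/shift at 1/0, LeakyReLU slopes at
#' the configured initial value, and all Adam moment accumulators at zero
#' (step counter t = 0).
#'
#' @param config an [FGCNNConfig-class].
#' @return named list with elements `weights`, `bn`, `adam`.
#' @export
initFGCNNParams <- function(config) {
  geo <- layerLengths(config)
  nc <- length(config@convFilters)
  withSeed(deriveSeed(config@seed, 1L), {
    w <- list(); bn <- list()
    din <- 1L
    for (i in seq_len(nc)) {
      dout <- config@convFilters[i]
      kl <- config@convKernels[i]
      fan <- kl * din
      w[[paste0("Wconv", i)]] <-
        matrix(runif(fan * dout, -1, 1) / sqrt(fan), fan, dout)
      w[[paste0("bconv", i)]] <- matrix(0, 1, dout)
      w[[paste0("gamma", i)]] <- matrix(1, 1, dout)
      w[[paste0("beta", i)]] <- matrix(0, 1, dout)
      w[[paste0("slope", i)]] <- matrix(config@leakySlope, 1, 1)
      bn[[paste0("rmean", i)]] <- matrix(0, 1, dout)
      bn[[paste0("rvar", i)]] <- matrix(1, 1, dout)
      din <- dout
    }
    fc1 <- config@fcSizes[1L]; outDim <- config@fcSizes[2L]
    w$W1 <- matrix(runif(geo$flat * fc1, -1, 1) / sqrt(geo$flat),
                   geo$flat, fc1)
    w$b1 <- matrix(0, 1, fc1)
    w$slopeFc <- matrix(config@leakySlope, 1, 1)
    w$W2 <- matrix(runif(fc1 * outDim, -1, 1) / sqrt(fc1), fc1, outDim)
    w$b2 <- matrix(0, 1, outDim)
    w$wl <- matrix(runif(outDim, -1, 1) / sqrt(outDim), outDim, 1)
    if (config@pDim > 0L) {
      w$wp <- matrix(runif(config@pDim, -1, 1) / sqrt(config@pDim),
                     config@pDim, 1)
    }
    nm <- weightNames(config)
    zeros <- lapply(w[nm], function(x) array(0, dim(x)))
    list(weights = w, bn = bn,
         adam = list(m = zeros, v = zeros, t = 0))
  })
}

#' LeakyReLU activation
#'
#' f(x) = x for x > 0 and a*x otherwise, with slope `a`.
#'
#' @param x numeric vector/matrix.
#' @param slope the slope a for non-positive inputs.
#' @export
leakyReLU <- function(x, slope = 0.1) {
  ifelse(x > 0, x, slope * x)
}

#' One convolutional layer (same padding) with optional LeakyReLU
#'
#' Computes `leakyReLU(k * x + w)` for a single input: a 'same'-zero-padded
#' 1-D convolution with kernel matrix `W` ((kl*Din) x Dout, row index
#' tap*Din + channel), bias `bias`, and LeakyReLU slope `slope`
#' (`activation = FALSE` returns the linear response). Batch normalisation is
#' a training-time construct and is not applied here.
#'
#' @param x L x Din input matrix (a vector is treated as L x 1).
#' @param W kernel matrix, (kl*Din) x Dout.
#' @param bias length-Dout bias.
#' @param kl kernel length.
#' @param slope LeakyReLU slope.
#' @param activation apply the LeakyReLU.
#' @return L x Dout output.
#' @export
convLayer <- function(x, W, bias = NULL, kl, slope = 0.1, activation = TRUE) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  if (!is.matrix(W)) W <- matrix(as.numeric(W), ncol = 1L)
  if (is.null(bias)) bias <- rep(0, ncol(W))
  stopIf(nrow(W) != kl * ncol(x),
         "kernel matrix must have kl * Din rows",
         class = "fgcnnDimensionError")
  stopIf(kl > nrow(x), "kernel longer than the input",
         class = "fgcnnDimensionError")
  out <- cpp_conv1d_same(x, W, matrix(bias, nrow = 1L), as.integer(kl))
  if (activation) out <- leakyReLU(out, slope)
  out
}

#' Pairwise max pooling
#'
#' Output row i is the elementwise maximum of input rows 2i-1 and 2i
#' (non-overlapping pairs); an odd final row is dropped.
#'
#' @param y L x D matrix (vector treated as L x 1).
#' @return floor(L/2) x D matrix (vector input returns a vector).
#' @export
maxPool <- function(y) {
  vec <- !is.matrix(y)
  if (vec) y <- matrix(as.numeric(y), ncol = 1L)
  stopIf(nrow(y) < 2L, "pooling needs at least two rows",
         class = "fgcnnDimensionError")
  out <- cpp_maxpool_pairs(y)
  if (vec) as.numeric(out) else out
}

#' Mean squared error loss
#'
#' @param y,yhat equal-length numeric vectors.
#' @export
mseLoss <- function(y, yhat) {
  stopIf(length(y) == 0L, "empty batch", class = "fgcnnEmptyInputError")
  stopIf(length(y) != length(yhat), "y and yhat lengths differ",
         class = "fgcnnDimensionError")
  mean((y - yhat)^2)
}

#' Analytic fusion-layer gradients
#'
#' For the fusion output yhat_i = tanh(wp . p_i + wl . l_i) and the MSE loss
#' over a batch, the gradients are
#' dMSE/dwp = -(2/N) sum_i p_i (y_i - yhat_i)(1 - yhat_i^2) and the same
#' expression with l_i for wl.
#'
#' @param p N x dp matrix of handcrafted vectors.
#' @param l N x dl matrix of CNN feature vectors.
#' @param wp,wl fusion weight vectors.
#' @param y length-N scaled targets.
#' @return list with `dwp`, `dwl`, `yhat` and `loss`.
#' @export
fusionGradients <- function(p, l, wp, wl, y) {
  p <- as.matrix(p); l <- as.matrix(l)
  N <- length(y)
  stopIf(nrow(p) != N || nrow(l) != N, "batch sizes differ",
         class = "fgcnnDimensionError")
  stopIf(ncol(p) != length(wp) || ncol(l) != length(wl),
         "weight lengths do not match feature widths",
         class = "fgcnnDimensionError")
  yhat <- tanh(as.numeric(p %*% wp + l %*% wl))
  resid <- (y - yhat) * (1 - yhat^2)
  list(dwp = as.numeric(-(2 / N) * crossprod(p, resid)),
       dwl = as.numeric(-(2 / N) * crossprod(l, resid)),
       yhat = yhat, loss = mean((y - yhat)^2))
}

#' One Adam update step
#'
#' Bias-corrected Adam: first and second moment accumulators decay with
#' beta1/beta2, the corrected moments drive a step of size `lr`, and the
#' denominator is sqrt(vhat) + eps with eps = 1e-8 by default. This is the
#' same arithmetic the training loop applies to every tensor, including the
#' fusion weights.
#'
#' @param weight,gradient numeric (vector or matrix, same shape).
#' @param state list(m, v, t): moment accumulators and step counter; pass
#'   `NULL` for zero-initialised state.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return list(weight, state) after the update.
#' @export
adamStep <- function(weight, gradient, state = NULL, lr = 0.001,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  assertFinite(gradient, "gradient")
  wMat <- as.matrix(weight)
  gMat <- as.matrix(gradient)
  stopIf(!all(dim(wMat) == dim(gMat)), "gradient shape mismatch",
         class = "fgcnnDimensionError")
  if (is.null(state)) {
    state <- list(m = array(0, dim(wMat)), v = array(0, dim(wMat)), t = 0)
  }
  res <- cpp_adam_step(wMat, gMat, as.matrix(state$m), as.matrix(state$v),
                       state$t, lr, beta1, beta2, eps)
  out <- res$weight
  if (!is.matrix(weight)) out <- as.numeric(out)
  list(weight = out, state = list(m = res$m, v = res$v, t = res$t))
}

# Shared training driver for the guided and unguided networks.
trainNetwork <- function(dataset, config, p, type, freezeWl = FALSE) {
  X <- dataset@windows
  stopIf(nrow(X) == 0L, "dataset is empty", class = "fgcnnEmptyInputError")
  stopIf(ncol(X) != config@inputLen,
         sprintf("windows have %d samples but config inputLen is %d",
                 ncol(X), config@inputLen), class = "fgcnnDimensionError")
  y <- dataset@targetsScaled
  stopIf(length(y) != nrow(X),
         "dataset has no scaled targets; fit an AngleScaler first",
         class = "fgcnnPreconditionError")
  stopIf(any(abs(y) > 1 + 1e-9), "scaled targets must lie within [-1, 1]",
         class = "fgcnnPreconditionError")
  assertFinite(X, "window matrix")
  pStats <- list()
  if (config@pDim > 0L) {
    stopIf(is.null(p), "handcrafted feature matrix required",
           class = "fgcnnPreconditionError")
    p <- as.matrix(p)
    stopIf(ncol(p) != config@pDim,
           sprintf("handcrafted matrix has %d columns but pDim is %d",
                   ncol(p), config@pDim), class = "fgcnnDimensionError")
    assertFinite(p, "handcrafted matrix")
    if (config@standardizeP) {
      pStats <- columnStats(p)
      p <- applyColumnStats(p, pStats)
    }
  } else {
    p <- matrix(0, nrow(X), 0L)
  }
  params <- initFGCNNParams(config)
  if (freezeWl) params$weights$wl[] <- 0
  orders <- withSeed(deriveSeed(config@seed, 2L), {
    t(vapply(seq_len(config@epochs),
             function(e) sample.int(nrow(X)) - 1L, integer(nrow(X))))
  })
  res <- cpp_train(X, p, y, params, cppConfig(config, freezeWl), orders,
                   config@batchSize, weightNames(config))
  new("FGCNNModel", config = config, params = res$params, pStats = pStats,
      lossHistory = as.numeric(res$lossHistory), type = type, trained = TRUE)
}

#' Train the feature-guided CNN
#'
#' Trains the full network (conv stack, FC head, fusion layer) with MSE loss
#' and Adam on scaled targets in [-1, 1]. The handcrafted matrix guides
#' training through the fusion layer; by default it is z-scored with
#' training-set statistics (stored in the model for inference). Training is
#' deterministic given `config@seed`.
#'
#' @param dataset a [WindowedDataset-class] whose `targetsScaled` slot has
#'   been filled (see [fitAngleScaler()]).
#' @param config an [FGCNNConfig()].
#' @param p N x 14 handcrafted feature matrix; computed with
#'   [handcraftedFeatures()] when omitted.
#' @param freezeWl keep the CNN-side fusion weights at their initial value
#'   (used to reduce the model to a tanh GLM on p; mainly diagnostic).
#' @return a trained [FGCNNModel-class] with per-epoch `lossHistory`.
#' @export
trainFGCNN <- function(dataset, config = FGCNNConfig(), p = NULL,
                       freezeWl = FALSE) {
  if (is.null(p) && config@pDim > 0L) {
    p <- handcraftedFeatures(dataset@windows)
  }
  trainNetwork(dataset, config, p, "fgcnn", freezeWl)
}

#' Train the unguided baseline CNN
#'
#' Identical conv stack but a 28-unit feature head and no handcrafted input;
#' the training signal is tanh of a single weight vector over the 28 learned
#' features, with the same loss and optimizer as the guided model.
#'
#' @param dataset a [WindowedDataset-class] with scaled targets.
#' @param config a [baselineCNNConfig()].
#' @return a trained [FGCNNModel-class].
#' @export
trainBaselineCNN <- function(dataset, config = baselineCNNConfig()) {
  stopIf(config@pDim != 0L, "baseline CNN takes no handcrafted input",
         class = "fgcnnParameterError")
  trainNetwork(dataset, config, NULL, "cnn")
}

# Inference pass shared by the feature extractors; BN uses running stats.
networkForward <- function(model, windows, p) {
  stopIf(!model@trained, "model has not been trained",
         class = "fgcnnStateError")
  stopIf(ncol(windows) != model@config@inputLen,
         "window length does not match the model's input length",
         class = "fgcnnDimensionError")
  if (model@config@pDim > 0L) {
    pIn <- as.matrix(p)
    if (length(model@pStats)) pIn <- applyColumnStats(pIn, model@pStats)
  } else {
    pIn <- matrix(0, nrow(windows), 0L)
  }
  cpp_predict(windows, pIn, model@params, cppConfig(model@config))
}

#' Forward pass of a trained model
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' returns the learned feature vectors and the fusion output
#' yhat = tanh(wp.p + wl.l) on the scaled [-1, 1] angle axis.
#'
#' @param model a trained [FGCNNModel-class].
#' @param windows N x inputLen matrix.
#' @param p N x 14 handcrafted matrix (computed when omitted; ignored by the
#'   baseline CNN).
#' @return list with `l` (N x 14 or N x 28) and `yhatScaled` (length N).
#' @export
fgcnnForward <- function(model, windows, p = NULL) {
  if (!is.matrix(windows)) windows <- matrix(windows, nrow = 1L)
  assertFinite(windows, "window matrix")
  if (is.null(p) && model@config@pDim > 0L) {
    p <- handcraftedFeatures(windows)
  }
  res <- networkForward(model, windows, p)
  list(l = res$l, yhatScaled = as.numeric(res$yhat))
}

#' Extract fused FG-CNN features
#'
#' Row i is the 28-vector [p_i, l_i]: the 14 handcrafted features exactly as
#' supplied (unstandardized) followed by the 14 learned features from the
#' trained network in inference mode.
#'
#' @param model a trained guided [FGCNNModel-class].
#' @param windows N x inputLen matrix.
#' @param p N x 14 handcrafted matrix (computed when omitted).
#' @return N x 28 feature matrix.
#' @export
extractFGCNNFeatures <- function(model, windows, p = NULL) {
  stopIf(model@type != "fgcnn", "model is not a feature-guided network",
         class = "fgcnnStateError")
  if (is.null(p)) p <- handcraftedFeatures(windows)
  res <- networkForward(model, windows, p)
  out <- cbind(as.matrix(p), res$l)
  pNames <- if (ncol(out) - ncol(res$l) == 14L) HANDCRAFTED_FEATURE_NAMES
            else paste0("p", seq_len(ncol(out) - ncol(res$l)))
  colnames(out) <- c(pNames, paste0("cnn", seq_len(ncol(res$l))))
  out
}

#' Extract baseline CNN features
#'
#' @param model a trained baseline [FGCNNModel-class].
#' @param windows N x inputLen matrix.
#' @return N x 28 matrix of learned features.
#' @export
extractCNNFeatures <- function(model, windows) {
  stopIf(model@type != "cnn", "model is not a baseline CNN",
         class = "fgcnnStateError")
  res <- networkForward(model, windows, NULL)
  out <- res$l
  colnames(out) <- paste0("cnn", seq_len(ncol(out)))
  out
}
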