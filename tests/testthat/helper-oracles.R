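# Independent oracles and small fixtures shared across the test files.
# Every oracle here is a direct, loop-based transcription of the defining
# formula, kept deliberately separate from the package's vectorised /
# compiled implementations.

# --- handcrafted feature bank, one window, plain loops -----------------------
naiveFeatures <- function(x, thZc = 0, thSsc = 0) {
  n <- length(x)
  iemg <- sum(abs(x))
  mu <- mean(x)
  xc <- x - mu
  m2 <- mean(xc^2); m3 <- mean(xc^3); m4 <- mean(xc^4)
  zc <- 0
  for (i in 1:(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= thZc) zc <- zc + 1
  }
  ssc <- 0
  for (i in 2:(n - 1)) {
    dl <- x[i] - x[i - 1]; dr <- x[i] - x[i + 1]
    if (dl * dr > 0 && max(abs(dl), abs(dr)) >= thSsc) ssc <- ssc + 1
  }
  # AR(4) by direct Yule-Walker linear solve (not Levinson-Durbin)
  r <- vapply(0:4, function(k) sum(xc[1:(n - k)] * xc[(1 + k):n]) / n, 0)
  ar <- if (r[1] <= 0) rep(0, 4) else solve(toeplitz(r[1:4]), r[2:5])
  c(iemg = iemg, mav = iemg / n, mean = mu, rms = sqrt(mean(x^2)),
    var = sum(xc^2) / (n - 1),
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    zc = zc, ssc = ssc, wl = sum(abs(diff(x))),
    ar1 = ar[1], ar2 = ar[2], ar3 = ar[3], ar4 = ar[4])
}

# --- 'same'-padded sliding-dot-product convolution ---------------------------
naiveConvSame <- function(x, W, bias, kl) {
  L <- nrow(x); Din <- ncol(x); Dout <- ncol(W)
  pl <- (kl - 1) %/% 2
  out <- matrix(0, L, Dout)
  for (t in 1:L) for (d in 1:Dout) {
    s <- bias[d]
    for (u in 1:kl) for (cch in 1:Din) {
      src <- t + (u - 1) - pl
      if (src >= 1 && src <= L) s <- s + W[(u - 1) * Din + cch, d] * x[src, cch]
    }
    out[t, d] <- s
  }
  out
}

# --- reference transcription of the bias-corrected Adam recursion ------------
referenceAdam <- function(w, g, m, v, t, lr = 0.001, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  t <- t + 1
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  w <- w - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
  list(w = w, m = m, v = v, t = t)
}

# --- rank-sum Kruskal-Wallis H with tie correction ---------------------------
naiveKruskalH <- function(groups) {
  allv <- unlist(groups)
  N <- length(allv)
  rk <- rank(allv)
  sizes <- vapply(groups, length, 1L)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(j)
      sum(rk[starts[j]:ends[j]])^2 / sizes[j], 0)) - 3 * (N + 1)
  ties <- table(allv)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# --- tiny network configuration for fast structural tests --------------------
tinyNetConfig <- function(pDim = 4L, epochs = 5L, seed = 3L, ...) {
  FGCNNConfig(inputLen = 32L, convFilters = c(2L, 3L, 2L, 2L, 2L),
              convKernels = c(3L, 3L, 3L, 2L, 1L), fcSizes = c(8L, 4L),
              pDim = pDim, epochs = epochs, batchSize = 8L, seed = seed, ...)
}

# WindowedDataset with random windows and scaled targets already attached.
toyScaledDataset <- function(N, n = 32L, targets = NULL, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(N * n), N)
  if (is.null(targets)) targets <- runif(N, -0.9, 0.9)
  new("WindowedDataset", windows = X, targetsDeg = targets * 30 + 30,
      targetsScaled = targets, windowEndTimes = seq_len(N) * 0.02,
      trialIds = rep("T1", N), sourceChannel = "LG", emgRate = 5000)
}

# Small synthetic recording reused by several files.
smallGaitConfig <- function(...) {
  defaultGaitConfig(nTrials = 2L, trialDurationS = 8, seed = 11L, ...)
}
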