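# Structural and numerical tests of the network: layer operations against
# naive oracles, analytic gradients against finite differences, the Adam
# recursion against an independent transcription, and training behaviour on
# data that is learnable by construction.

test_that("convolution layer matches the sliding-dot-product oracle", {
  # identity: single 1-tap filter, unit weight, zero bias, non-negative input
  x <- abs(rnorm(20))
  out <- convLayer(x, matrix(1, 1, 1), kl = 1)
  expect_equal(as.numeric(out), x)

  # LeakyReLU values straight from the definition
  expect_equal(leakyReLU(2, 0.1), 2)
  expect_equal(leakyReLU(-2, 0.1), -0.2)

  set.seed(21)
  for (rep in 1:20) {
    L <- sample(6:30, 1); Din <- sample(1:4, 1); Dout <- sample(1:5, 1)
    kl <- sample(1:5, 1)
    x <- matrix(rnorm(L * Din), L)
    W <- matrix(rnorm(kl * Din * Dout), kl * Din, Dout)
    b <- rnorm(Dout)
    got <- convLayer(x, W, b, kl, activation = FALSE)
    expect_equal(got, naiveConvSame(x, W, b, kl), tolerance = 1e-12)
  }
  expect_error(convLayer(rnorm(3), matrix(rnorm(5), 5, 1), kl = 5),
               class = "fgcnnDimensionError")
})

test_that("pairwise max pooling halves the length and drops odd tails", {
  expect_equal(maxPool(c(3, 1, 4, 1, 5, 9)), c(3, 4, 9))
  expect_equal(maxPool(c(-1, -2)), -1)
  expect_equal(maxPool(c(1, 2, 3, 4, 5, 6, 7)), c(2, 4, 6))
  expect_error(maxPool(matrix(1, 1, 3)), class = "fgcnnDimensionError")
  set.seed(22)
  for (rep in 1:25) {
    L <- sample(2:40, 1); D <- sample(1:6, 1)
    y <- matrix(rnorm(L * D), L)
    got <- maxPool(y)
    expect_identical(nrow(got), L %/% 2L)
    for (i in seq_len(L %/% 2)) {
      expect_equal(got[i, ], pmax(y[2 * i - 1, ], y[2 * i, ]))
    }
  }
})

test_that("fusion forward obeys the tanh closed forms", {
  cfgT <- tinyNetConfig()
  params <- initFGCNNParams(cfgT)
  params$weights$wp[] <- 0
  params$weights$wl[] <- 0
  model <- new("FGCNNModel", config = cfgT, params = params, trained = TRUE,
               type = "fgcnn", pStats = list())
  X <- matrix(rnorm(3 * 32), 3)
  P <- matrix(rnorm(3 * 4), 3)
  out <- fgcnnForward(model, X, P)
  expect_equal(out$yhatScaled, rep(0, 3))

  # wp . p = 0.5 constructed directly
  params$weights$wp[1, 1] <- 1
  model@params <- params
  P05 <- matrix(0, 3, 4); P05[, 1] <- 0.5
  out <- fgcnnForward(model, X, P05)
  expect_equal(out$yhatScaled, rep(tanh(0.5), 3), tolerance = 1e-12)

  # saturation
  P20 <- matrix(0, 3, 4); P20[, 1] <- 25
  out <- fgcnnForward(model, X, P20)
  expect_true(all(abs(out$yhatScaled) >= 1 - 1e-8))
  expect_true(all(abs(out$yhatScaled) <= 1))
  expect_error(fgcnnForward(model, matrix(NaN, 1, 32), P[1, , drop = FALSE]),
               class = "fgcnnNumericError")
})

test_that("mse loss evaluates, rejects empty batches and ignores order", {
  expect_equal(mseLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(mseLoss(c(1, 0), c(0, 0)), 0.5)
  set.seed(23)
  y <- rnorm(50); yh <- rnorm(50)
  o <- sample(50)
  expect_equal(mseLoss(y, yh), mseLoss(y[o], yh[o]))
  expect_error(mseLoss(numeric(0), numeric(0)),
               class = "fgcnnEmptyInputError")
})

test_that("analytic fusion gradients match hand values and finite differences", {
  # zero residual -> exactly zero gradients
  set.seed(24)
  p <- matrix(rnorm(6 * 14), 6); l <- matrix(rnorm(6 * 14), 6)
  wp <- rnorm(14, sd = 0.1); wl <- rnorm(14, sd = 0.1)
  yExact <- tanh(as.numeric(p %*% wp + l %*% wl))
  g0 <- fusionGradients(p, l, wp, wl, yExact)
  expect_equal(g0$dwp, rep(0, 14))
  expect_equal(g0$dwl, rep(0, 14))

  # scalar hand case: p = l = 1, wp = wl = 0, y = 1 -> dMSE/dwp = -2
  g1 <- fusionGradients(matrix(1), matrix(1), 0, 0, 1)
  expect_equal(g1$dwp, -2)
  expect_equal(g1$dwl, -2)

  # central finite differences of the loss in every coordinate
  for (rep in 1:10) {
    N <- sample(2:8, 1); d <- sample(2:14, 1)
    p <- matrix(rnorm(N * d), N); l <- matrix(rnorm(N * d), N)
    wp <- rnorm(d, sd = 0.3); wl <- rnorm(d, sd = 0.3)
    y <- runif(N, -0.95, 0.95)
    g <- fusionGradients(p, l, wp, wl, y)
    h <- 1e-6
    lossAt <- function(wp2, wl2) {
      mean((y - tanh(as.numeric(p %*% wp2 + l %*% wl2)))^2)
    }
    for (k in seq_len(d)) {
      ep <- replace(wp, k, wp[k] + h); em <- replace(wp, k, wp[k] - h)
      fd <- (lossAt(ep, wl) - lossAt(em, wl)) / (2 * h)
      expect_equal(g$dwp[k], fd, tolerance = 1e-5)
      ep <- replace(wl, k, wl[k] + h); em <- replace(wl, k, wl[k] - h)
      fd <- (lossAt(wp, ep) - lossAt(wp, em)) / (2 * h)
      expect_equal(g$dwl[k], fd, tolerance = 1e-5)
    }
  }
})

test_that("the Adam step matches an independent transcription exactly", {
  # null update
  st0 <- list(m = matrix(0, 2, 2), v = matrix(0, 2, 2), t = 0)
  w <- matrix(c(1, -1, 2, 0.5), 2)
  up <- adamStep(w, matrix(0, 2, 2), st0)
  expect_identical(up$weight, w)

  # bias-corrected first step is ~ -lr * sign(g)
  up1 <- adamStep(5, 1, NULL, lr = 0.001)
  expect_equal(up1$weight, 5 - 0.001 * 1 / (1 + 1e-8), tolerance = 1e-12)
  up1n <- adamStep(5, -3, NULL, lr = 0.001)
  expect_equal(up1n$weight, 5 + 0.001 * 3 / (3 + 1e-8), tolerance = 1e-9)

  # multi-step trajectory vs the reference recursion, to 1e-12
  set.seed(25)
  w <- rnorm(6); g1 <- rnorm(6); g2 <- rnorm(6); g3 <- rnorm(6)
  mine <- list(weight = w, state = NULL)
  ref <- list(w = w, m = rep(0, 6), v = rep(0, 6), t = 0)
  for (g in list(g1, g2, g3)) {
    mine <- adamStep(mine$weight, g, mine$state)
    ref <- referenceAdam(ref$w, g, ref$m, ref$v, ref$t)
    expect_equal(mine$weight, ref$w, tolerance = 1e-12)
    expect_equal(as.numeric(mine$state$m), ref$m, tolerance = 1e-12)
    expect_equal(as.numeric(mine$state$v), ref$v, tolerance = 1e-12)
  }
  expect_error(adamStep(1, NaN, NULL), class = "fgcnnNumericError")
})

test_that("backpropagated gradients of the full network pass finite differences", {
  cfgT <- tinyNetConfig(seed = 31L)
  set.seed(31)
  N <- 24
  X <- matrix(rnorm(N * 32), N)
  P <- matrix(rnorm(N * 4), N)
  y <- tanh(rowMeans(X) + 0.5 * P[, 1])
  params <- initFGCNNParams(cfgT)
  wn <- fgcnn:::weightNames(cfgT)
  cl <- fgcnn:::cppConfig(cfgT)
  res <- fgcnn:::cpp_loss_grads(X, P, y, params, cl, wn, TRUE)
  for (nm in wn) {
    W <- params$weights[[nm]]
    for (i in sample(length(W), min(3, length(W)))) {
      h <- 1e-6 * max(1, abs(W[i]))
      p2 <- params
      p2$weights[[nm]][i] <- W[i] + h
      lp <- fgcnn:::cpp_loss_grads(X, P, y, p2, cl, wn, FALSE)$loss
      p2$weights[[nm]][i] <- W[i] - h
      lm <- fgcnn:::cpp_loss_grads(X, P, y, p2, cl, wn, FALSE)$loss
      fd <- (lp - lm) / (2 * h)
      expect_equal(res$grads[[nm]][i], fd,
                   tolerance = 1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("training fits a constant target and is seed-deterministic", {
  cfgT <- tinyNetConfig(epochs = 50L, seed = 5L)
  ds <- toyScaledDataset(200, targets = rep(0.3, 200), seed = 51)
  set.seed(51)
  P <- matrix(rnorm(200 * 4), 200)
  m1 <- trainFGCNN(ds, cfgT, p = P)
  expect_length(m1@lossHistory, 50L)
  expect_lt(tail(m1@lossHistory, 1), 0.01)
  m2 <- trainFGCNN(ds, cfgT, p = P)
  expect_identical(m1@lossHistory, m2@lossHistory)
  expect_identical(m1@params$weights$W1, m2@params$weights$W1)

  # unscaled targets are rejected up front
  dsBad <- ds
  dsBad@targetsScaled <- ds@targetsScaled * 4
  expect_error(suppressWarnings(trainFGCNN(dsBad, cfgT, p = P)),
               class = "fgcnnPreconditionError")
})

test_that("true labels train to lower loss than shuffled labels", {
  finals <- vapply(1:3, function(s) {
    set.seed(100 + s)
    N <- 160
    X <- matrix(rnorm(N * 32), N)
    P <- matrix(rnorm(N * 4), N)
    y <- tanh(1.5 * tanh(rowMeans(X[, 1:8])) + 0.8 * P[, 1])
    ds <- toyScaledDataset(N, seed = 100 + s)
    ds@windows <- X
    ds@targetsScaled <- y
    cfgT <- tinyNetConfig(epochs = 30L, seed = s)
    mTrue <- trainFGCNN(ds, cfgT, p = P)
    dsShuf <- ds
    dsShuf@targetsScaled <- y[sample(N)]
    mShuf <- trainFGCNN(dsShuf, cfgT, p = P)
    tail(mTrue@lossHistory, 1) - tail(mShuf@lossHistory, 1)
  }, 0)
  expect_lt(median(finals), 0)
})

test_that("freezing the CNN path reduces training to a tanh GLM on p", {
  set.seed(61)
  N <- 300
  P <- matrix(rnorm(N * 4), N)
  beta <- c(0.8, -0.5, 0.3, 0)
  y <- tanh(as.numeric(P %*% beta) + rnorm(N, sd = 0.2))
  y <- pmin(pmax(y, -1), 1)
  ds <- toyScaledDataset(N, seed = 61)
  ds@targetsScaled <- y
  cfgT <- tinyNetConfig(epochs = 60L, seed = 6L,
                        learningRate = 0.01, standardizeP = FALSE)
  m <- trainFGCNN(ds, cfgT, p = P, freezeWl = TRUE)
  expect_equal(as.numeric(m@params$weights$wl), rep(0, 4))
  # direct tanh GLM fit of the same loss
  direct <- optim(rep(0, 4), function(b)
    mean((y - tanh(as.numeric(P %*% b)))^2), method = "BFGS")
  expect_lt(tail(m@lossHistory, 1), direct$value * 1.05)
})

test_that("feature extraction is a 28-wide concatenation, handcrafted first", {
  cfgT <- tinyNetConfig(epochs = 3L)
  ds <- toyScaledDataset(50)
  set.seed(71)
  P <- matrix(rnorm(50 * 4), 50)
  m <- trainFGCNN(ds, cfgT, p = P)
  f1 <- extractFGCNNFeatures(m, ds@windows, P)
  expect_identical(dim(f1), c(50L, 8L))  # pDim + head width of the tiny net
  expect_true(all(f1[, 1:4] == P))
  f2 <- extractFGCNNFeatures(m, ds@windows, P)
  expect_identical(f1, f2)  # inference mode: BN frozen

  # the canonical architecture yields 14 + 14 = 28 columns
  cfg <- FGCNNConfig(epochs = 1L, seed = 2L)
  dsBig <- toyScaledDataset(40, n = 250L, seed = 72)
  mBig <- trainFGCNN(dsBig, cfg)
  fBig <- extractFGCNNFeatures(mBig, dsBig@windows)
  expect_identical(ncol(fBig), 28L)
  expect_identical(colnames(fBig)[1:14], HANDCRAFTED_FEATURE_NAMES)

  untrained <- new("FGCNNModel", config = cfgT,
                   params = initFGCNNParams(cfgT), type = "fgcnn")
  expect_error(extractFGCNNFeatures(untrained, ds@windows, P),
               class = "fgcnnStateError")
})

test_that("the baseline CNN trains unguided to a 28-wide feature head", {
  cfgC <- baselineCNNConfig(inputLen = 32L,
                            convFilters = c(2L, 3L, 2L, 2L, 2L),
                            convKernels = c(3L, 3L, 3L, 2L, 1L),
                            fcSizes = c(8L, 28L), epochs = 20L,
                            batchSize = 8L, seed = 4L)
  set.seed(81)
  N <- 120
  ds <- toyScaledDataset(N, seed = 81)
  ds@targetsScaled <- tanh(2 * tanh(rowMeans(ds@windows[, 1:8])))
  m1 <- trainBaselineCNN(ds, cfgC)
  expect_lt(tail(m1@lossHistory, 1), m1@lossHistory[1])
  f <- extractCNNFeatures(m1, ds@windows)
  expect_identical(ncol(f), 28L)
  m2 <- trainBaselineCNN(ds, cfgC)
  expect_identical(m1@lossHistory, m2@lossHistory)
  expect_error(trainBaselineCNN(ds, tinyNetConfig()),
               class = "fgcnnParameterError")
  # a guided model cannot serve as the unguided extractor and vice versa
  expect_error(extractFGCNNFeatures(m1, ds@windows),
               class = "fgcnnStateError")
})
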