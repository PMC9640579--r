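test_that("NRMSE matches hand-evaluated closed forms", {
  y <- runif(20, 0, 60)
  expect_equal(nrmse(y, y), 0)
  expect_equal(nrmse(c(0, 4, 8), c(1, 4, 7)), 100 * sqrt(2 / 3) / 8,
               tolerance = 1e-12)
  expect_equal(round(nrmse(c(0, 4, 8), c(1, 4, 7)), 2), 10.21)
  # translation invariance
  yh <- y + rnorm(20)
  expect_equal(nrmse(y, yh), nrmse(y + 13.7, yh + 13.7))
  expect_error(nrmse(rep(1, 5), rnorm(5)),
               class = "fgcnnDegenerateScaleError")
})

test_that("CC is Pearson correlation with its closed-form properties", {
  set.seed(31)
  y <- rnorm(40)
  expect_equal(cc(y, 2 * y + 3), 1)
  expect_equal(cc(y, -y), -1)
  expect_equal(cc(c(1, 2, 3, 4), c(1, 2, 4, 3)), cc(c(1, 2, 4, 3), c(1, 2, 3, 4)))
  expect_error(cc(rep(2, 5), rnorm(5)), class = "fgcnnDegenerateScaleError")
})

test_that("nrmse and cc agree with direct textbook-formula oracles", {
  set.seed(32)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    y <- rnorm(n, 30, 15)
    yh <- y + rnorm(n, 0, 5)
    # oracles written straight from the definitions
    oracleN <- 100 * sqrt(sum((y - yh)^2) / n) / (max(y) - min(y))
    cyy <- sum((y - mean(y)) * (yh - mean(yh))) / (n - 1)
    oracleC <- cyy / (sd(y) * sd(yh))
    expect_equal(nrmse(y, yh), oracleN, tolerance = 1e-10)
    expect_equal(cc(y, yh), oracleC, tolerance = 1e-10)
  }
})

test_that("fold assignment partitions windows without leaking trials", {
  ds <- toyScaledDataset(100)
  ds@trialIds <- rep(sprintf("T%02d", 1:10), each = 10)

  dsW <- makeFolds(ds, k = 5, scheme = "window", seed = 3)
  sizes <- table(foldIds(dsW))
  expect_identical(sum(sizes), 100L)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(unique(foldIds(dsW)), 1:5)

  dsT <- makeFolds(ds, k = 5, scheme = "trial")
  # every trial lives in exactly one fold
  byTrial <- tapply(foldIds(dsT), dsT@trialIds, function(v) length(unique(v)))
  expect_true(all(byTrial == 1))
  # near-equal trial counts per fold
  trialsPerFold <- table(tapply(foldIds(dsT), dsT@trialIds, unique))
  expect_lte(diff(range(trialsPerFold)), 1)
  # union of test folds is the full index set, pairwise disjoint
  idx <- split(seq_len(100), foldIds(dsT))
  expect_identical(sort(unname(unlist(idx))), 1:100)
  expect_identical(sum(lengths(idx)), 100L)

  ds3 <- ds
  ds3@trialIds <- rep(c("A", "B", "C"), length.out = 100)
  expect_error(makeFolds(ds3, k = 5, scheme = "trial"),
               class = "fgcnnPartitionError")
})

test_that("stride averaging resamples and averages cycles correctly", {
  cycle <- sin(2 * pi * seq(0, 1, length.out = 101))
  y <- c(rep(cycle[-101], 4), cycle[1])
  b <- seq(1, length(y), by = 100)
  sa <- strideAverage(y, b)
  expect_equal(sa$profile, sin(2 * pi * sa$grid), tolerance = 1e-6)

  # two cycles, one offset by +1: pointwise midway (the terminal grid point
  # is the next cycle's start by construction, so compare the interior)
  y2 <- c(cycle[-101], cycle + 1)
  sa2 <- strideAverage(y2, c(1, 101, 201))
  expect_equal(sa2$profile[-101], (sin(2 * pi * sa2$grid) + 0.5)[-101],
               tolerance = 1e-6)

  expect_error(strideAverage(cycle, 1), class = "fgcnnEmptyInputError")
})

test_that("stride-averaged synthetic angles recover the generating template", {
  cfg <- smallGaitConfig(angleNoiseDeg = 0.5)
  rec <- generateTrial(cfg, 1)
  # cycle boundaries from the stored ground-truth phase wraps
  wraps <- which(diff(rec@phase) < -0.5) + 1L
  sa <- strideAverage(angleStream(rec), wraps)
  template <- kneeAngleProfile(sa$grid, cfg@angleTemplate)
  expect_lt(mean(abs(sa$profile - template)), 1)
  expect_lt(max(abs(sa$profile - template)), 3)
})

test_that("Kruskal-Wallis matches the rank-sum oracle and handles nulls", {
  g3 <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskalWallisTest(g3)
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$H, naiveKruskalH(g3), tolerance = 1e-12)
  expect_identical(kw$df, 2L)

  # identical groups: equal mean ranks, H = 0
  same <- list(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(kruskalWallisTest(same)$H, 0)

  # null simulation: identically distributed groups rarely reject
  set.seed(33)
  ps <- vapply(1:20, function(i) {
    kruskalWallisTest(list(rnorm(40), rnorm(40)))$p
  }, 0)
  expect_gt(median(ps), 0.1)

  # oracle agreement with ties present
  set.seed(34)
  gt <- list(sample(1:5, 20, TRUE), sample(1:5, 20, TRUE))
  expect_equal(kruskalWallisTest(gt)$H, naiveKruskalH(gt), tolerance = 1e-10)

  expect_error(kruskalWallisTest(list(rep(1, 5), rep(1, 4))),
               class = "fgcnnDegenerateRanksError")
  expect_error(kruskalWallisTest(list(rnorm(3))),
               class = "fgcnnParameterError")
})
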