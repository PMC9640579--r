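#' @include AllClasses.R
NULL

#' Normalised root-mean-squared error, in percent
#'
#' RMSE between measured and estimated angles divided by the measured-angle
#' range (max - min of `y`), reported as a percentage. Translation of both
#' series by a common constant leaves it unchanged.
#'
#' @param y measured angles, degrees.
#' @param yhat estimated angles, degrees.
#' @return NRMSE in percent.
#' @export
nrmse <- function(y, yhat) {
  stopIf(length(y) != length(yhat), "y and yhat lengths differ",
         class = "fgcnnDimensionError")
  rng <- max(y) - min(y)
  stopIf(rng <= 0, "measured angles are constant; NRMSE undefined",
         class = "fgcnnDegenerateScaleError")
  100 * sqrt(mean((y - yhat)^2)) / rng
}

#' Pearson correlation between measured and estimated angles
#'
#' The covariance of the two series over the product of their standard
#' deviations; symmetric in its arguments and invariant to positive affine
#' transforms of either.
#'
#' @param y,yhat equal-length numeric vectors, both non-constant.
#' @return correlation in [-1, 1].
#' @export
cc <- function(y, yhat) {
  stopIf(length(y) != length(yhat), "y and yhat lengths differ",
         class = "fgcnnDimensionError")
  stopIf(stats::sd(y) == 0 || stats::sd(yhat) == 0,
         "correlation undefined for a constant series",
         class = "fgcnnDegenerateScaleError")
  stats::cor(y, yhat)
}

#' Assign cross-validation folds
#'
#' `scheme = "trial"` (default) groups all windows of a trial into the same
#' fold, assigning contiguous blocks of trials to folds of near-equal trial
#' count -- this keeps overlapping windows from the same trial out of
#' train/test pairs. `scheme = "window"` shuffles windows individually
#' (fold sizes differ by at most one window); it is provided for leakage
#' ablation only.
#'
#' @param dataset a [WindowedDataset-class].
#' @param k number of folds (default 5).
#' @param scheme `"trial"` or `"window"`.
#' @param seed shuffle seed for the window scheme.
#' @return the dataset with its `foldIds` slot filled (values 1..k).
#' @export
makeFolds <- function(dataset, k = 5L, scheme = c("trial", "window"),
                      seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nWindows(dataset)
  stopIf(n < k, "fewer windows than folds", class = "fgcnnPartitionError")
  if (scheme == "trial") {
    trials <- unique(dataset@trialIds)
    stopIf(length(trials) < k,
           sprintf("%d folds requested but only %d trials present", k,
                   length(trials)), class = "fgcnnPartitionError")
    # contiguous blocks of near-equal trial count
    foldOfTrial <- rep(seq_len(k), times = diff(round(seq(0, length(trials),
                                                          length.out = k + 1))))
    ids <- foldOfTrial[match(dataset@trialIds, trials)]
  } else {
    ids <- integer(n)
    ids[withSeed(seed, sample.int(n))] <-
      rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
  }
  dataset@foldIds <- as.integer(ids)
  validObject(dataset)
  dataset
}

#' Average a periodic signal across gait cycles
#'
#' Each complete cycle (between consecutive boundaries) is resampled by
#' linear interpolation onto a fixed 0-100% gait grid and the cycles are
#' averaged pointwise.
#'
#' @param y numeric time series (e.g. knee angle in degrees).
#' @param boundaries indices into `y` marking cycle starts (the last value
#'   closes the final cycle); at least one complete cycle is required.
#' @param nGrid number of grid points across the cycle (default 101,
#'   i.e. 0, 1, ..., 100% of the gait cycle).
#' @return list with `profile` (mean cycle), `grid` (0..1 phase fractions)
#'   and `cycles` (the resampled cycles, one row each).
#' @export
strideAverage <- function(y, boundaries, nGrid = 101L) {
  boundaries <- sort(as.integer(boundaries))
  stopIf(length(boundaries) < 2L, "no complete cycle between boundaries",
         class = "fgcnnEmptyInputError")
  grid <- seq(0, 1, length.out = nGrid)
  cycles <- matrix(NA_real_, length(boundaries) - 1L, nGrid)
  for (i in seq_len(length(boundaries) - 1L)) {
    lo <- boundaries[i]; hi <- boundaries[i + 1L]
    stopIf(hi - lo < 2L, "cycle too short to resample",
           class = "fgcnnEmptyInputError")
    seg <- y[lo:hi]
    phase <- seq(0, 1, length.out = length(seg))
    cycles[i, ] <- stats::approx(phase, seg, xout = grid)$y
  }
  list(profile = colMeans(cycles), grid = grid, cycles = cycles)
}

#' Kruskal-Wallis rank test across method groups
#'
#' Rank-based comparison of two or more groups of evaluation scores (the
#' tie-corrected H statistic with a chi-square null on #groups - 1 degrees
#' of freedom), as used to compare estimation methods at significance level
#' 0.05.
#'
#' @param groups named list of numeric vectors, one per method.
#' @return list with `H`, `p`, `df` and the group names.
#' @export
kruskalWallisTest <- function(groups) {
  stopIf(length(groups) < 2L, "need at least two groups",
         class = "fgcnnParameterError")
  stopIf(any(!vapply(groups, length, 1L)), "groups must be non-empty",
         class = "fgcnnEmptyInputError")
  allv <- unlist(groups)
  stopIf(length(unique(allv)) == 1L,
         "all observations identical; ranks are degenerate",
         class = "fgcnnDegenerateRanksError")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), groups = names(groups))
}

#' Tabulate per-fold scores
#'
#' Small helper constructing one row of the standard results table.
#' @param subject,muscle,featureSet,regressor,fold identifiers.
#' @param y,yhat measured and estimated angles for the fold's test windows.
#' @return one-row data.frame with `nrmse` and `cc` columns.
#' @export
scoreFold <- function(subject, muscle, featureSet, regressor, fold, y, yhat) {
  data.frame(subject = subject, muscle = muscle, feature_set = featureSet,
             regressor = regressor, fold = fold,
             nrmse = nrmse(y, yhat), cc = cc(y, yhat),
             stringsAsFactors = FALSE)
}
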