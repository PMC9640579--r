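#' @include utils.R
NULL

#' Names of the 14 handcrafted features, in their fixed order
#' @export
HANDCRAFTED_FEATURE_NAMES <- c(
  "iemg", "mav", "mean", "rms", "var", "kurtosis", "skewness",
  "zc", "ssc", "wl", "ar1", "ar2", "ar3", "ar4")

#' Handcrafted time-domain feature bank
#'
#' Computes, for each sEMG analysis window, the 14 classical time-domain
#' features used to guide the network: integrated EMG (sum of absolute
#' values), mean absolute value, mean, RMS, variance (n-1 denominator),
#' Pearson kurtosis m4/m2^2 and skewness m3/m2^(3/2) (biased central
#' moments), zero crossings and slope sign changes (thresholded counts),
#' waveform length (sum of absolute successive differences), and the four
#' Yule-Walker autoregressive coefficients.
#'
#' Degenerate windows (zero variance) return 0 for kurtosis, skewness and
#' the AR coefficients so downstream regressors never see non-finite values;
#' such windows are flagged in the `"degenerate"` attribute.
#'
#' @param windows numeric matrix (N windows x n samples) or a single numeric
#'   vector (one window). Windows must have at least 8 samples so the
#'   order-4 AR fit is determined.
#' @param zcThreshold,sscThreshold amplitude thresholds for the zero-crossing
#'   and slope-sign-change counts (default 0).
#' @return an N x 14 matrix (or named length-14 vector for vector input)
#'   with columns in the order of [HANDCRAFTED_FEATURE_NAMES], carrying a
#'   logical `"degenerate"` attribute.
#' @examples
#' handcraftedFeatures(c(1, -2, 3, -4, 5, -6, 7, -8))
#' @export
handcraftedFeatures <- function(windows, zcThreshold = 0, sscThreshold = 0) {
  vec <- !is.matrix(windows)
  w <- if (vec) matrix(as.numeric(windows), nrow = 1L) else windows
  n <- ncol(w)
  stopIf(n < 8L, "windows must have at least 8 samples (order-4 AR fit)",
         class = "fgcnnWindowSizeError")
  assertFinite(w, "window matrix")

  iemg <- rowSums(abs(w))
  mav <- iemg / n
  mu <- rowMeans(w)
  rms <- sqrt(rowMeans(w * w))
  wc <- w - mu
  ssd <- rowSums(wc * wc)
  varr <- ssd / (n - 1)
  m2 <- ssd / n
  m3 <- rowMeans(wc^3)
  m4 <- rowMeans(wc^4)
  ok <- m2 > 0
  skew <- ifelse(ok, m3 / m2^1.5, 0)
  kurt <- ifelse(ok, m4 / m2^2, 0)

  a <- w[, -n, drop = FALSE]
  b <- w[, -1L, drop = FALSE]
  zc <- rowSums((a * b < 0) & (abs(a - b) >= zcThreshold))
  if (n >= 3L) {
    mid <- w[, 2:(n - 1L), drop = FALSE]
    dl <- mid - w[, 1:(n - 2L), drop = FALSE]
    dr <- mid - w[, 3:n, drop = FALSE]
    ssc <- rowSums((dl * dr > 0) & (pmax(abs(dl), abs(dr)) >= sscThreshold))
  } else ssc <- rep(0, nrow(w))
  wl <- rowSums(abs(b - a))

  arc <- arCoefficients(w, order = 4L)
  out <- cbind(iemg, mav, mean = mu, rms, var = varr, kurtosis = kurt,
               skewness = skew, zc, ssc, wl, arc)
  colnames(out) <- HANDCRAFTED_FEATURE_NAMES
  attr(out, "degenerate") <- attr(arc, "degenerate")
  if (vec) {
    res <- out[1L, ]
    attr(res, "degenerate") <- attr(out, "degenerate")[1L]
    return(res)
  }
  out
}

#' Yule-Walker autoregressive coefficients via Levinson-Durbin
#'
#' Fits an AR(`order`) model x_t = a1 x_(t-1) + ... + a_order x_(t-order) + e
#' to each (demeaned) window by solving the Yule-Walker equations with the
#' Levinson-Durbin recursion on biased (1/n) autocovariances. Constant
#' windows cannot support an AR fit; they yield all-zero coefficients and
#' are flagged in the `"degenerate"` attribute.
#'
#' @param windows numeric matrix (rows = windows) or a single vector.
#' @param order AR model order (default 4).
#' @return N x order matrix (or length-`order` vector) of coefficients with
#'   a logical `"degenerate"` attribute.
#' @export
arCoefficients <- function(windows, order = 4L) {
  vec <- !is.matrix(windows)
  w <- if (vec) matrix(as.numeric(windows), nrow = 1L) else windows
  n <- ncol(w)
  order <- as.integer(order)
  stopIf(n <= order, "window length must exceed the AR order",
         class = "fgcnnWindowSizeError")
  wc <- w - rowMeans(w)
  # biased autocovariances to lag `order`
  r <- matrix(0, nrow(w), order + 1L)
  r[, 1L] <- rowSums(wc * wc) / n
  for (k in seq_len(order)) {
    r[, k + 1L] <- rowSums(wc[, 1:(n - k), drop = FALSE] *
                             wc[, (k + 1L):n, drop = FALSE]) / n
  }
  degen <- r[, 1L] <= 0
  a <- matrix(0, nrow(w), order)
  e <- ifelse(degen, 1, r[, 1L])  # placeholder avoids 0/0; rows masked later
  for (k in seq_len(order)) {
    acc <- r[, k + 1L]
    if (k > 1L) {
      for (j in seq_len(k - 1L)) acc <- acc - a[, j] * r[, k - j + 1L]
    }
    kap <- ifelse(e > 0, acc / e, 0)
    prev <- a
    a[, k] <- kap
    if (k > 1L) {
      for (j in seq_len(k - 1L)) a[, j] <- prev[, j] - kap * prev[, k - j]
    }
    e <- e * (1 - kap * kap)
  }
  a[degen, ] <- 0
  colnames(a) <- paste0("ar", seq_len(order))
  attr(a, "degenerate") <- degen
  if (vec) {
    res <- a[1L, ]
    attr(res, "degenerate") <- degen[1L]
    return(res)
  }
  a
}

#' Write a handcrafted feature matrix to a delimited table
#'
#' One row per window, the 14 named feature columns in their fixed order.
#'
#' @param features matrix from [handcraftedFeatures()].
#' @param path output CSV path.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
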