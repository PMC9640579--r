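#' @include AllClasses.R
NULL

#' Create an EMGRecording
#'
#' @param emg numeric matrix, samples x channels (millivolts).
#' @param emgRate sEMG sampling rate, Hz.
#' @param channelLabels muscle label per column.
#' @param angle knee-angle stream, degrees.
#' @param angleRate angle sampling rate, Hz.
#' @param subjectId,trialId identifiers.
#' @param phase optional ground-truth gait phase at the angle rate.
#' @return an [EMGRecording-class].
#' @export
EMGRecording <- function(emg, emgRate, channelLabels, angle, angleRate,
                         subjectId = "S1", trialId = "T1",
                         phase = numeric(0)) {
  emg <- as.matrix(emg)
  storage.mode(emg) <- "double"
  colnames(emg) <- channelLabels
  new("EMGRecording", emg = emg, emgRate = as.numeric(emgRate),
      channelLabels = as.character(channelLabels),
      angle = as.numeric(angle), angleRate = as.numeric(angleRate),
      subjectId = as.character(subjectId), trialId = as.character(trialId),
      phase = as.numeric(phase))
}

#' Read / write a recording in the on-disk dialect
#'
#' A recording is stored as three plain-text files sharing a stem:
#' `<stem>.emg.csv` (one column per muscle), `<stem>.angle.csv` (single
#' `angle_deg` column, plus `phase` when ground truth is available) and
#' `<stem>.meta.json` with keys `emg_rate`, `angle_rate`, `channel_labels`,
#' `subject_id`, `trial_id`. Numeric values are written at full precision so
#' a write/read round trip reproduces the recording exactly.
#'
#' @param stem path stem (no extension).
#' @param rec an [EMGRecording-class] (write).
#' @return `readRecording` returns an [EMGRecording-class];
#'   `writeRecording` returns `stem` invisibly.
#' @export
readRecording <- function(stem) {
  metaPath <- paste0(stem, ".meta.json")
  emgPath <- paste0(stem, ".emg.csv")
  anglePath <- paste0(stem, ".angle.csv")
  stopIf(!file.exists(metaPath), "missing metadata sidecar: ", metaPath,
         class = "fgcnnFormatError")
  stopIf(!file.exists(emgPath), "missing sEMG table: ", emgPath,
         class = "fgcnnFormatError")
  stopIf(!file.exists(anglePath), "missing angle table: ", anglePath,
         class = "fgcnnFormatError")
  meta <- jsonlite::fromJSON(metaPath)
  for (k in c("emg_rate", "angle_rate", "channel_labels")) {
    stopIf(is.null(meta[[k]]), "metadata sidecar lacks key '", k, "'",
           class = "fgcnnFormatError")
  }
  stopIf(meta$emg_rate <= 0 || meta$angle_rate <= 0,
         "sampling rates must be positive", class = "fgcnnFormatError")
  emgTab <- utils::read.csv(emgPath, check.names = FALSE)
  angTab <- utils::read.csv(anglePath, check.names = FALSE)
  stopIf(ncol(emgTab) != length(meta$channel_labels),
         sprintf("sEMG table has %d columns but %d channel labels",
                 ncol(emgTab), length(meta$channel_labels)),
         class = "fgcnnFormatError")
  stopIf(nrow(angTab) == 0L, "angle stream is empty",
         class = "fgcnnFormatError")
  rec <- EMGRecording(
    emg = as.matrix(emgTab), emgRate = meta$emg_rate,
    channelLabels = as.character(meta$channel_labels),
    angle = angTab$angle_deg, angleRate = meta$angle_rate,
    subjectId = if (is.null(meta$subject_id)) "S1" else meta$subject_id,
    trialId = if (is.null(meta$trial_id)) "T1" else meta$trial_id,
    phase = if ("phase" %in% names(angTab)) angTab$phase else numeric(0))
  validObject(rec)
  rec
}

#' @rdname readRecording
#' @export
writeRecording <- function(rec, stem) {
  stopifnot(is(rec, "EMGRecording"))
  validObject(rec)
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  emgTab <- as.data.frame(rec@emg)
  names(emgTab) <- rec@channelLabels
  writeNum <- function(df, path) {
    # full double precision so round trips are exact
    df[] <- lapply(df, function(col) sprintf("%.17g", col))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  writeNum(emgTab, paste0(stem, ".emg.csv"))
  angTab <- data.frame(angle_deg = rec@angle)
  if (length(rec@phase)) angTab$phase <- rec@phase
  writeNum(angTab, paste0(stem, ".angle.csv"))
  meta <- list(emg_rate = rec@emgRate, angle_rate = rec@angleRate,
               channel_labels = rec@channelLabels,
               subject_id = rec@subjectId, trial_id = rec@trialId)
  jsonlite::write_json(meta, paste0(stem, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Standard sEMG preprocessing: a Butterworth band-pass (default 10-500 Hz,
#' order 4) applied forward and backward (`signal::filtfilt`) so the filtered
#' signal has no phase lag relative to the angle stream.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate, Hz.
#' @param low,high cutoff frequencies, Hz; must satisfy 0 < low < high < fs/2.
#' @param order filter order (applied twice by the forward-backward pass).
#' @return filtered signal, same shape as `x`.
#' @export
bandpassFilter <- function(x, fs, low = 10, high = 500, order = 4) {
  stopIf(!(low > 0 && high > low), "need 0 < low < high",
         class = "fgcnnParameterError")
  stopIf(high >= fs / 2, "high cutoff must be below the Nyquist rate fs/2",
         class = "fgcnnParameterError")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filt1 <- function(v) {
    if (all(v == 0)) return(v)  # linearity: zero in, zero out, no edge fuzz
    signal::filtfilt(bf, v)
  }
  if (is.matrix(x)) apply(x, 2L, filt1) else filt1(as.numeric(x))
}

#' Segment a signal into overlapping analysis windows
#'
#' Cuts the signal into windows of `windowMs` milliseconds advanced by
#' `stepMs` (defaults 50 ms / 20 ms). The number of windows is
#' `floor((len - n) / step) + 1` with `n = round(windowMs * fs / 1000)`.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param windowMs window length, ms.
#' @param stepMs window increment, ms.
#' @return list with `windows` (N x n matrix) and `endTimes` (seconds, end of
#'   each window = index of its last sample / fs).
#' @export
segmentWindows <- function(x, fs, windowMs = 50, stepMs = 20) {
  n <- as.integer(round(windowMs * fs / 1000))
  step <- as.integer(round(stepMs * fs / 1000))
  stopIf(n < 1L || step < 1L, "window and step must be at least one sample",
         class = "fgcnnParameterError")
  len <- length(x)
  stopIf(len < n, sprintf(
    "signal (%d samples) shorter than one window (%d samples)", len, n),
    class = "fgcnnEmptyInputError")
  nWin <- (len - n) %/% step + 1L
  starts <- (seq_len(nWin) - 1L) * step
  idx <- outer(starts, seq_len(n), "+")
  windows <- matrix(x[idx], nrow = nWin, ncol = n)
  list(windows = windows, endTimes = (starts + n) / fs)
}

#' Align angle targets to window end times
#'
#' Each window is labelled with the knee angle linearly interpolated at the
#' window's end time (causal labelling: the target is the most recent joint
#' state the window could inform). The angle stream's sample i is taken at
#' time (i - 1) / angleRate; no extrapolation is performed.
#'
#' @param angle knee-angle stream, degrees.
#' @param angleRate angle sampling rate, Hz.
#' @param endTimes window end times, seconds.
#' @return numeric vector of per-window targets in degrees.
#' @export
alignTargets <- function(angle, angleRate, endTimes) {
  tAngle <- (seq_along(angle) - 1) / angleRate
  stopIf(any(endTimes < tAngle[1] - 1e-12) ||
           any(endTimes > tAngle[length(tAngle)] + 1e-12),
         "window end time outside the angle stream's time span",
         class = "fgcnnAlignmentError")
  out <- stats::approx(tAngle, angle, xout = pmin(pmax(endTimes, tAngle[1]),
                                                  tAngle[length(tAngle)]))$y
  out
}

#' Window one channel of a recording
#'
#' Convenience wrapper: band-pass filters the selected channel, segments it
#' into overlapping windows and aligns angle targets, returning a
#' [WindowedDataset-class].
#'
#' @param rec an [EMGRecording-class].
#' @param channel muscle label to window.
#' @param windowMs,stepMs see [segmentWindows()].
#' @param filter logical; apply [bandpassFilter()] first (default TRUE).
#' @param low,high,order band-pass parameters.
#' @return a [WindowedDataset-class].
#' @export
windowRecording <- function(rec, channel, windowMs = 50, stepMs = 20,
                            filter = TRUE, low = 10, high = 500, order = 4) {
  stopIf(!channel %in% rec@channelLabels,
         "channel '", channel, "' not present in recording",
         class = "fgcnnParameterError")
  x <- rec@emg[, match(channel, rec@channelLabels)]
  if (filter) x <- bandpassFilter(x, rec@emgRate, low, high, order)
  seg <- segmentWindows(x, rec@emgRate, windowMs, stepMs)
  targets <- alignTargets(rec@angle, rec@angleRate, seg$endTimes)
  new("WindowedDataset", windows = seg$windows, targetsDeg = targets,
      windowEndTimes = seg$endTimes,
      trialIds = rep(rec@trialId, nrow(seg$windows)),
      sourceChannel = channel, emgRate = rec@emgRate)
}

#' Concatenate windowed datasets from several trials
#'
#' @param datasets list of [WindowedDataset-class] objects from the same
#'   channel. End times are offset per trial so they remain strictly
#'   increasing across the concatenation.
#' @return a single [WindowedDataset-class] retaining per-window trial ids.
#' @export
bindWindowedDatasets <- function(datasets) {
  stopIf(length(datasets) == 0L, "no datasets to bind",
         class = "fgcnnEmptyInputError")
  ch <- unique(vapply(datasets, function(d) d@sourceChannel, character(1)))
  stopIf(length(ch) != 1L, "datasets come from different channels",
         class = "fgcnnParameterError")
  offset <- 0
  times <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    times[[i]] <- datasets[[i]]@windowEndTimes + offset
    offset <- max(times[[i]]) + 1
  }
  new("WindowedDataset",
      windows = do.call(rbind, lapply(datasets, function(d) d@windows)),
      targetsDeg = unlist(lapply(datasets, function(d) d@targetsDeg)),
      windowEndTimes = unlist(times),
      trialIds = unlist(lapply(datasets, function(d) d@trialIds)),
      sourceChannel = ch, emgRate = datasets[[1]]@emgRate)
}

#' Fit / apply the [-1, 1] angle scaler
#'
#' `fitAngleScaler` records the training-set extrema; `scaleAngles` maps
#' degrees affinely so the extrema land on -1 and +1 (test-set values may
#' exceed the range and are NOT clipped); `unscaleAngles` inverts the map,
#' optionally clipping the scaled input to [-1, 1] first.
#'
#' @param targetsDeg training-fold targets, degrees.
#' @param scaler an [AngleScaler-class].
#' @param y values to (un)scale.
#' @param clip clip scaled values to [-1, 1] before inverting.
#' @return `fitAngleScaler` an [AngleScaler-class]; the others numeric.
#' @export
fitAngleScaler <- function(targetsDeg) {
  yMin <- min(targetsDeg)
  yMax <- max(targetsDeg)
  stopIf(!is.finite(yMin) || !is.finite(yMax) || yMax <= yMin,
         "targets are constant; angle scaler is degenerate",
         class = "fgcnnDegenerateScaleError")
  new("AngleScaler", yMin = yMin, yMax = yMax)
}

#' @rdname fitAngleScaler
#' @export
scaleAngles <- function(scaler, y) {
  2 * (y - scaler@yMin) / (scaler@yMax - scaler@yMin) - 1
}

#' @rdname fitAngleScaler
#' @export
unscaleAngles <- function(scaler, y, clip = TRUE) {
  if (clip) y <- pmin(pmax(y, -1), 1)
  (y + 1) / 2 * (scaler@yMax - scaler@yMin) + scaler@yMin
}
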