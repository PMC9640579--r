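#' @include AllClasses.R
NULL

#' Accessors for recording and dataset objects
#'
#' `emg()` returns the sEMG matrix (samples x channels, millivolts);
#' `emgRate()` and `angleRate()` the sampling rates in Hz; `angleStream()`
#' the knee-angle vector in degrees; `channelLabels()` the muscle labels;
#' `windowsMatrix()` the N x n window matrix; `targetsDeg()` the per-window
#' angle targets; `nWindows()` the number of windows; `foldIds()` the
#' cross-validation fold assignment.
#'
#' @param object an [EMGRecording-class] or [WindowedDataset-class].
#' @return the slot value described above.
#' @name accessors
#' @aliases emg emgRate angleRate angleStream channelLabels windowsMatrix
#'   targetsDeg nWindows foldIds
NULL

#' @rdname accessors
#' @export
setGeneric("emg", function(object) standardGeneric("emg"))
#' @rdname accessors
#' @export
setGeneric("emgRate", function(object) standardGeneric("emgRate"))
#' @rdname accessors
#' @export
setGeneric("angleRate", function(object) standardGeneric("angleRate"))
#' @rdname accessors
#' @export
setGeneric("angleStream", function(object) standardGeneric("angleStream"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("windowsMatrix", function(object) standardGeneric("windowsMatrix"))
#' @rdname accessors
#' @export
setGeneric("targetsDeg", function(object) standardGeneric("targetsDeg"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("foldIds", function(object) standardGeneric("foldIds"))

#' @rdname accessors
setMethod("emg", "EMGRecording", function(object) object@emg)
#' @rdname accessors
setMethod("emgRate", "EMGRecording", function(object) object@emgRate)
#' @rdname accessors
setMethod("angleRate", "EMGRecording", function(object) object@angleRate)
#' @rdname accessors
setMethod("angleStream", "EMGRecording", function(object) object@angle)
#' @rdname accessors
setMethod("channelLabels", "EMGRecording",
          function(object) object@channelLabels)
#' @rdname accessors
setMethod("emgRate", "WindowedDataset", function(object) object@emgRate)
#' @rdname accessors
setMethod("windowsMatrix", "WindowedDataset", function(object) object@windows)
#' @rdname accessors
setMethod("targetsDeg", "WindowedDataset", function(object) object@targetsDeg)
#' @rdname accessors
setMethod("nWindows", "WindowedDataset",
          function(object) nrow(object@windows))
#' @rdname accessors
setMethod("foldIds", "WindowedDataset", function(object) object@foldIds)

setMethod("show", "EMGRecording", function(object) {
  cat(sprintf(
    "EMGRecording: subject %s, trial %s\n  sEMG: %d samples x %d channels @ %g Hz (%s)\n  angle: %d samples @ %g Hz, range [%.1f, %.1f] deg%s\n",
    object@subjectId, object@trialId, nrow(object@emg), ncol(object@emg),
    object@emgRate, paste(object@channelLabels, collapse = ", "),
    length(object@angle), object@angleRate,
    min(object@angle), max(object@angle),
    if (length(object@phase)) ", ground-truth phase attached" else ""))
})

setMethod("show", "WindowedDataset", function(object) {
  cat(sprintf(
    "WindowedDataset: %d windows x %d samples (%s @ %g Hz)\n  targets: [%.1f, %.1f] deg%s%s\n",
    nrow(object@windows), ncol(object@windows), object@sourceChannel,
    object@emgRate, min(object@targetsDeg), max(object@targetsDeg),
    if (length(object@targetsScaled)) ", scaled copy attached" else "",
    if (length(object@foldIds))
      sprintf(", %d folds", length(unique(object@foldIds))) else ""))
})

setMethod("show", "AngleScaler", function(object) {
  cat(sprintf("AngleScaler: [%.3f, %.3f] deg -> [-1, 1]\n",
              object@yMin, object@yMax))
})

setMethod("show", "FGCNNConfig", function(object) {
  cat(sprintf(
    "FGCNNConfig: input %d samples; conv filters %s (kernels %s); FC %s; pDim %d\n  lr %g, %d epochs, batch %d, Adam(beta1=%g, beta2=%g, eps=%g), seed %d\n",
    object@inputLen, paste(object@convFilters, collapse = "/"),
    paste(object@convKernels, collapse = "/"),
    paste(object@fcSizes, collapse = "/"), object@pDim,
    object@learningRate, object@epochs, object@batchSize,
    object@beta1, object@beta2, object@epsilon, object@seed))
})

setMethod("show", "FGCNNModel", function(object) {
  cat(sprintf("FGCNNModel (%s): %s; final training MSE %s\n",
              object@type,
              if (object@trained) "trained" else "untrained",
              if (length(object@lossHistory))
                format(tail(object@lossHistory, 1), digits = 4) else "NA"))
})

setMethod("show", "GaitSimConfig", function(object) {
  cat(sprintf(
    "GaitSimConfig: %d x %g s trials, cadence %g Hz (jitter %g)\n  sEMG %g Hz, angle %g Hz, SNR %g dB, angle noise %g deg, seed %d\n",
    object@nTrials, object@trialDurationS, object@cadenceHz,
    object@cadenceJitter, object@emgRate, object@angleRate, object@snrDb,
    object@angleNoiseDeg, object@seed))
})
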