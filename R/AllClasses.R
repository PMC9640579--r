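#' @include utils.R
NULL

#' The six recorded knee muscles: vastus lateralis/medialis, biceps femoris,
#' semitendinosus, lateral/medial gastrocnemius
#' @export
KNOWN_MUSCLES <- c("VL", "VM", "BF", "ST", "LG", "MG")

#' Paired sEMG / knee-angle recording
#'
#' Container for one walking trial: a multi-channel sEMG matrix (millivolts)
#' sampled at `emgRate` Hz and a knee-angle stream (degrees) sampled at the
#' typically much lower `angleRate` Hz. Channel columns are labelled by the
#' muscle they were recorded from (vastus lateralis VL, vastus medialis VM,
#' biceps femoris BF, semitendinosus ST, lateral/medial gastrocnemius LG/MG).
#' Recordings produced by the gait simulator additionally carry the
#' ground-truth gait phase at the angle rate in `phase`.
#'
#' @slot emg numeric matrix, samples x channels, millivolts.
#' @slot emgRate sEMG sampling rate in Hz.
#' @slot channelLabels character vector naming the muscle of each column.
#' @slot angle numeric vector of knee angles in degrees.
#' @slot angleRate angle sampling rate in Hz.
#' @slot subjectId,trialId identifiers.
#' @slot phase optional ground-truth gait phase in [0, 1) at the angle rate
#'   (length 0 when unknown).
#'
#' @seealso [readRecording()], [generateTrial()]
#' @export
setClass("EMGRecording",
  representation(
    emg = "matrix",
    emgRate = "numeric",
    channelLabels = "character",
    angle = "numeric",
    angleRate = "numeric",
    subjectId = "character",
    trialId = "character",
    phase = "numeric"
  ),
  prototype(phase = numeric(0))
)

setValidity("EMGRecording", function(object) {
  msg <- character(0)
  if (length(object@emgRate) != 1L || !is.finite(object@emgRate) ||
      object@emgRate <= 0) {
    msg <- c(msg, "emgRate must be a single positive number")
  }
  if (length(object@angleRate) != 1L || !is.finite(object@angleRate) ||
      object@angleRate <= 0) {
    msg <- c(msg, "angleRate must be a single positive number")
  }
  if (ncol(object@emg) != length(object@channelLabels)) {
    msg <- c(msg, sprintf("emg has %d columns but %d channel labels",
                          ncol(object@emg), length(object@channelLabels)))
  }
  if (anyDuplicated(object@channelLabels)) {
    msg <- c(msg, "channel labels must be unique")
  }
  if (length(object@angle) == 0L) {
    msg <- c(msg, "angle stream is empty")
  }
  if (length(msg) == 0L && nrow(object@emg) > 0L) {
    durEmg <- nrow(object@emg) / object@emgRate
    nAngleExpected <- durEmg * object@angleRate
    if (abs(length(object@angle) - nAngleExpected) > 1 + 1e-6) {
      msg <- c(msg, sprintf(
        "angle stream length %d inconsistent with duration %.3f s at %g Hz",
        length(object@angle), durEmg, object@angleRate))
    }
  }
  if (length(object@phase) > 0L &&
      length(object@phase) != length(object@angle)) {
    msg <- c(msg, "phase, when present, must match the angle stream length")
  }
  if (length(msg)) msg else TRUE
})

#' Windowed sEMG dataset with aligned angle targets
#'
#' Fixed-length overlapping sEMG windows (rows) from one muscle channel, each
#' paired with the knee angle interpolated at the window's end time. Targets
#' are kept in degrees; a scaled copy in [-1, 1] (training-fold extrema) is
#' attached before network training.
#'
#' @slot windows numeric matrix, N windows x n samples, millivolts.
#' @slot targetsDeg numeric vector of per-window knee angles, degrees.
#' @slot targetsScaled numeric vector in [-1, 1] (length 0 until scaling).
#' @slot windowEndTimes strictly increasing end times, seconds.
#' @slot foldIds integer cross-validation fold per window (length 0 until
#'   folds are assigned).
#' @slot trialIds factor-like character vector of source trial per window.
#' @slot sourceChannel muscle label the windows were cut from.
#' @slot emgRate sampling rate of the windowed signal, Hz.
#'
#' @seealso [windowRecording()], [makeFolds()]
#' @export
setClass("WindowedDataset",
  representation(
    windows = "matrix",
    targetsDeg = "numeric",
    targetsScaled = "numeric",
    windowEndTimes = "numeric",
    foldIds = "integer",
    trialIds = "character",
    sourceChannel = "character",
    emgRate = "numeric"
  ),
  prototype(targetsScaled = numeric(0), foldIds = integer(0))
)

setValidity("WindowedDataset", function(object) {
  msg <- character(0)
  n <- nrow(object@windows)
  if (length(object@targetsDeg) != n) {
    msg <- c(msg, "targetsDeg length must equal the number of windows")
  }
  if (length(object@windowEndTimes) != n) {
    msg <- c(msg, "windowEndTimes length must equal the number of windows")
  }
  if (n > 1L && any(diff(object@windowEndTimes) <= 0)) {
    msg <- c(msg, "windowEndTimes must be strictly increasing")
  }
  if (length(object@targetsScaled) > 0L) {
    if (length(object@targetsScaled) != n) {
      msg <- c(msg, "targetsScaled length must equal the number of windows")
    } else if (any(abs(object@targetsScaled) > 1 + 1e-9)) {
      msg <- c(msg, "targetsScaled must lie within [-1, 1]")
    }
  }
  if (length(object@foldIds) > 0L && length(object@foldIds) != n) {
    msg <- c(msg, "foldIds length must equal the number of windows")
  }
  if (length(object@trialIds) > 0L && length(object@trialIds) != n) {
    msg <- c(msg, "trialIds length must equal the number of windows")
  }
  if (length(msg)) msg else TRUE
})

#' Affine angle scaler mapping training extrema to [-1, 1]
#'
#' Fitted on training-fold targets only; the tanh output of the fusion layer
#' is bounded in (-1, 1), so network targets are mapped through this scaler
#' and predictions mapped back to degrees.
#'
#' @slot yMin,yMax training-set angle extrema in degrees.
#' @export
setClass("AngleScaler",
  representation(yMin = "numeric", yMax = "numeric"))

setValidity("AngleScaler", function(object) {
  if (length(object@yMin) != 1L || length(object@yMax) != 1L ||
      !is.finite(object@yMin) || !is.finite(object@yMax)) {
    return("yMin and yMax must be single finite numbers")
  }
  if (object@yMax <= object@yMin) return("yMax must exceed yMin")
  TRUE
})

#' FG-CNN architecture and training configuration
#'
#' Defaults follow the reference architecture: five convolutional layers with
#' 2, 4, 8, 16 and 32 filters of lengths 5, 4, 3, 2 and 1, each followed by
#' batch normalisation, LeakyReLU with a learnable slope, and length-2
#' non-overlapping max pooling; the flattened output feeds fully connected
#' layers of 192 and `pDim` (14) units, and a tanh fusion layer combines the
#' handcrafted vector p with the learned vector l. Training uses mean squared
#' error and Adam (learning rate 0.001, 50 epochs).
#'
#' @slot inputLen window length in samples (250 = 50 ms at 5 kHz).
#' @slot convFilters,convKernels integer vectors of length 5.
#' @slot poolLen pooling length (2).
#' @slot fcSizes sizes of the two fully connected layers, c(192, 14).
#' @slot pDim length of the handcrafted vector entering the fusion layer
#'   (14; 0 for the unguided baseline CNN).
#' @slot leakySlope initial LeakyReLU slope a (learnable, one per layer).
#' @slot learningRate,epochs,batchSize,beta1,beta2,epsilon Adam/MSE training
#'   hyperparameters; epsilon is the Adam denominator constant 1e-8.
#' @slot standardizeP z-score the handcrafted vector by training statistics
#'   before fusion (default TRUE).
#' @slot seed integer seed for weight initialisation and batch shuffling.
#' @export
setClass("FGCNNConfig",
  representation(
    inputLen = "integer",
    convFilters = "integer",
    convKernels = "integer",
    poolLen = "integer",
    fcSizes = "integer",
    pDim = "integer",
    leakySlope = "numeric",
    learningRate = "numeric",
    epochs = "integer",
    batchSize = "integer",
    beta1 = "numeric",
    beta2 = "numeric",
    epsilon = "numeric",
    standardizeP = "logical",
    seed = "integer"
  )
)

setValidity("FGCNNConfig", function(object) {
  msg <- character(0)
  if (length(object@convFilters) != length(object@convKernels)) {
    msg <- c(msg, "convFilters and convKernels must have equal length")
  }
  if (any(object@convFilters < 1L) || any(object@convKernels < 1L)) {
    msg <- c(msg, "filter counts and kernel lengths must be positive")
  }
  if (length(object@fcSizes) != 2L) {
    msg <- c(msg, "fcSizes must contain exactly two layer sizes")
  } else if (object@pDim > 0L && object@fcSizes[2L] != object@pDim) {
    msg <- c(msg, "fcSizes[2] must equal pDim so p and l can be fused")
  }
  if (object@poolLen != 2L) {
    msg <- c(msg, "poolLen must be 2 (pairwise max pooling)")
  }
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
  if (object@beta1 <= 0 || object@beta1 >= 1 ||
      object@beta2 <= 0 || object@beta2 >= 1) {
    msg <- c(msg, "beta1 and beta2 must lie in (0, 1)")
  }
  if (object@inputLen < max(object@convKernels)) {
    msg <- c(msg, "inputLen must be at least the longest kernel")
  }
  if (length(msg)) msg else TRUE
})

#' A trained FG-CNN (or baseline CNN) model
#'
#' @slot config the [FGCNNConfig-class] the model was built from.
#' @slot params named list of weight/batch-norm/optimizer tensors.
#' @slot pStats training-set mean/sd used to standardize the handcrafted
#'   vector (empty list for the baseline CNN).
#' @slot lossHistory per-epoch mean training MSE.
#' @slot type "fgcnn" or "cnn".
#' @slot trained logical.
#' @export
setClass("FGCNNModel",
  representation(
    config = "FGCNNConfig",
    params = "list",
    pStats = "list",
    lossHistory = "numeric",
    type = "character",
    trained = "logical"
  ),
  prototype(trained = FALSE, pStats = list())
)

#' Synthetic gait protocol configuration
#'
#' Describes the simulated acquisition the generator emulates: repeated 1-min
#' treadmill walking trials at fixed cadence, six-muscle sEMG at 5 kHz and a
#' knee-angle stream at 100 Hz. Muscle activation envelopes are sums of
#' wrapped Gaussian bumps placed at physiologically sensible gait phases,
#' mixed (per-muscle `coupling`) with the normalised knee-angle profile so
#' the gastrocnemius channels are the most informative about the angle. The
#' knee-angle template is stored as Fourier coefficients, guaranteeing
#' periodicity.
#'
#' @slot nTrials number of trials (11).
#' @slot trialDurationS trial duration in seconds (60).
#' @slot cadenceHz stride rate in Hz (0.93, a typical 1.25 m/s walk).
#' @slot cadenceJitter multiplicative per-stride duration jitter (0.03).
#' @slot muscles the six muscle labels.
#' @slot envelopeParams per-muscle list(centers, widths, amps) of wrapped
#'   Gaussian bumps (phase units).
#' @slot coupling per-muscle mixing weight in [0, 1] of the normalised angle
#'   profile into the envelope.
#' @slot angleTemplate list(a0, an, bn): Fourier cosine/sine coefficients of
#'   the knee-angle profile, degrees.
#' @slot emgRate,angleRate sampling rates, Hz (5000 and 100).
#' @slot snrDb sensor signal-to-noise ratio in dB (Inf disables noise).
#' @slot angleNoiseDeg additive angle measurement noise SD, degrees.
#' @slot seed base seed making generation a pure function of the config.
#' @export
setClass("GaitSimConfig",
  representation(
    nTrials = "integer",
    trialDurationS = "numeric",
    cadenceHz = "numeric",
    cadenceJitter = "numeric",
    muscles = "character",
    envelopeParams = "list",
    coupling = "numeric",
    angleTemplate = "list",
    emgRate = "numeric",
    angleRate = "numeric",
    snrDb = "numeric",
    angleNoiseDeg = "numeric",
    seed = "integer"
  )
)

setValidity("GaitSimConfig", function(object) {
  msg <- character(0)
  if (object@emgRate <= 0 || object@angleRate <= 0) {
    msg <- c(msg, "sampling rates must be positive")
  }
  if (object@cadenceHz <= 0) msg <- c(msg, "cadenceHz must be positive")
  if (object@cadenceJitter < 0 || object@cadenceJitter >= 1) {
    msg <- c(msg, "cadenceJitter must lie in [0, 1)")
  }
  if (!all(object@muscles %in% names(object@envelopeParams))) {
    msg <- c(msg, "envelopeParams must cover every muscle")
  }
  if (!all(object@muscles %in% names(object@coupling))) {
    msg <- c(msg, "coupling must cover every muscle")
  }
  for (m in object@muscles) {
    ep <- object@envelopeParams[[m]]
    if (!is.null(ep) && any(ep$amps < 0)) {
      msg <- c(msg, sprintf("envelope amplitudes for %s must be >= 0", m))
    }
  }
  if (length(msg)) msg else TRUE
})
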