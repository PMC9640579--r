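#' @include AllClasses.R signal_io.R
NULL

# Wrapped Gaussian bump on the unit circle (phase in [0, 1)).
wrappedGaussian <- function(phase, center, width) {
  out <- 0
  for (k in -1:1) out <- out + exp(-((phase - center + k)^2) / (2 * width^2))
  out
}

# Fourier-project a periodic curve sampled on a uniform phase grid.
fourierProject <- function(values, phase, nHarmonics) {
  a0 <- mean(values)
  an <- bn <- numeric(nHarmonics)
  for (k in seq_len(nHarmonics)) {
    an[k] <- 2 * mean(values * cos(2 * pi * k * phase))
    bn[k] <- 2 * mean(values * sin(2 * pi * k * phase))
  }
  list(a0 = a0, an = an, bn = bn)
}

#' Default synthetic gait configuration
#'
#' Emulates the acquisition protocol the estimation method targets: 11
#' one-minute treadmill trials at a 0.93 Hz stride rate (a typical 1.25 m/s
#' walk, ~56 strides/min), six-muscle sEMG at 5 kHz, knee angle at 100 Hz.
#' The knee-angle template is the classical double-bump flexion curve (small
#' stance-phase flexion peak near 18 degrees at ~15% of the cycle, large
#' swing flexion peak near 60 degrees at ~72%), stored as a 16-harmonic
#' Fourier series. Activation envelopes place quadriceps activity in early
#' stance, hamstring activity around the swing-stance transition and
#' gastrocnemius activity in mid-late stance (push-off); the per-muscle
#' `coupling` mixes in the normalised angle profile, making LG/MG the most
#' informative channels about the knee angle, mirroring their push-off role.
#'
#' @param ... slot overrides (e.g. `nTrials = 4L`, `trialDurationS = 20`,
#'   `seed = 7L`).
#' @return a [GaitSimConfig-class].
#' @export
defaultGaitConfig <- function(...) {
  grid <- (0:2047) / 2048
  shape <- 3 + 15 * wrappedGaussian(grid, 0.15, 0.05) +
    56 * wrappedGaussian(grid, 0.72, 0.09)
  tpl <- fourierProject(shape, grid, 16L)
  tpl$range <- range(evalFourier(grid, tpl))
  envelopeParams <- list(
    VL = list(centers = c(0.06, 0.96), widths = c(0.05, 0.04),
              amps = c(0.9, 0.3)),
    VM = list(centers = c(0.08, 0.97), widths = c(0.05, 0.04),
              amps = c(0.9, 0.25)),
    BF = list(centers = c(0.92, 0.05), widths = c(0.06, 0.04),
              amps = c(0.85, 0.4)),
    ST = list(centers = c(0.90, 0.04), widths = c(0.06, 0.04),
              amps = c(0.85, 0.35)),
    LG = list(centers = 0.35, widths = 0.10, amps = 0.9),
    MG = list(centers = 0.38, widths = 0.10, amps = 0.9))
  coupling <- c(VL = 0.15, VM = 0.15, BF = 0.15, ST = 0.15,
                LG = 0.8, MG = 0.8)
  args <- list(nTrials = 11L, trialDurationS = 60, cadenceHz = 0.93,
               cadenceJitter = 0.03, muscles = KNOWN_MUSCLES,
               envelopeParams = envelopeParams, coupling = coupling,
               angleTemplate = tpl, emgRate = 5000, angleRate = 100,
               snrDb = 20, angleNoiseDeg = 0.5, seed = 0L)
  over <- list(...)
  args[names(over)] <- over
  args$nTrials <- as.integer(args$nTrials)
  args$seed <- as.integer(args$seed)
  do.call(new, c(list(Class = "GaitSimConfig"), args))
}

evalFourier <- function(phase, tpl) {
  out <- rep(tpl$a0, length(phase))
  for (k in seq_along(tpl$an)) {
    out <- out + tpl$an[k] * cos(2 * pi * k * phase) +
      tpl$bn[k] * sin(2 * pi * k * phase)
  }
  out
}

#' Knee-angle profile over the gait cycle
#'
#' Evaluates the periodic Fourier angle template at the given phase
#' fractions. The default template has a stance flexion peak of 15-20
#' degrees and a swing flexion peak near 60 degrees.
#'
#' @param phase gait-cycle fractions (any real; evaluated periodically).
#' @param template Fourier template `list(a0, an, bn)`; default the
#'   [defaultGaitConfig()] template.
#' @return angles in degrees.
#' @export
kneeAngleProfile <- function(phase, template = NULL) {
  if (is.null(template)) template <- defaultGaitConfig()@angleTemplate
  evalFourier(phase %% 1, template)
}

#' Muscle activation envelope over the gait cycle
#'
#' Sum of wrapped Gaussian bumps for the muscle's burst timing, mixed with
#' the normalised knee-angle profile in proportion to the muscle's coupling
#' weight, clipped to [0, 1].
#'
#' @param muscle one of the configured muscle labels.
#' @param phase gait-cycle fractions.
#' @param config a [GaitSimConfig-class] (default [defaultGaitConfig()]).
#' @return envelope values in [0, 1].
#' @export
activationEnvelope <- function(muscle, phase, config = defaultGaitConfig()) {
  stopIf(!muscle %in% config@muscles, "unknown muscle '", muscle, "'",
         class = "fgcnnParameterError")
  ep <- config@envelopeParams[[muscle]]
  phase <- phase %% 1
  env <- 0
  for (i in seq_along(ep$centers)) {
    env <- env + ep$amps[i] * wrappedGaussian(phase, ep$centers[i],
                                              ep$widths[i])
  }
  cpl <- config@coupling[[muscle]]
  if (cpl > 0) {
    tpl <- config@angleTemplate
    rng <- if (!is.null(tpl$range)) tpl$range else
      range(evalFourier((0:511) / 512, tpl))
    if (diff(rng) > 0) {
      angNorm <- (evalFourier(phase, tpl) - rng[1]) / diff(rng)
      env <- (1 - cpl) * env + cpl * angNorm
    }
  }
  pmin(pmax(env, 0), 1)
}

#' Synthesize amplitude-modulated sEMG from an activation envelope
#'
#' The standard surrogate sEMG model: band-limited (10-500 Hz Butterworth,
#' zero-phase) unit-variance Gaussian noise is amplitude-modulated by the
#' envelope, and white sensor noise is added at `snrDb` relative to the
#' modulated signal's RMS (Inf disables it). The windowed RMS of the result
#' tracks the envelope.
#'
#' @param envelope non-negative envelope sampled at `emgRate`.
#' @param emgRate sampling rate, Hz.
#' @param band band-pass corners for the carrier, Hz.
#' @param snrDb sensor signal-to-noise ratio, dB.
#' @param seed RNG seed (generation is deterministic given it).
#' @return numeric vector, same length as `envelope` (millivolt scale).
#' @export
synthesizeEMG <- function(envelope, emgRate, band = c(10, 500), snrDb = Inf,
                          seed = NULL) {
  stopIf(any(envelope < 0), "envelope must be non-negative",
         class = "fgcnnParameterError")
  n <- length(envelope)
  withSeed(seed, {
    carrier <- bandpassFilter(rnorm(n), emgRate, band[1], band[2], order = 4)
    s <- stats::sd(carrier)
    if (s > 0) carrier <- carrier / s
    sig <- envelope * carrier
    if (is.finite(snrDb)) {
      rms <- sqrt(mean(sig^2))
      if (rms > 0) sig <- sig + rnorm(n, sd = rms / 10^(snrDb / 20))
    }
    sig
  })
}

# Per-stride jittered phase shared by the sEMG and angle streams. Returns
# phase evaluated at both sampling grids plus the stride boundary times.
stridePhase <- function(duration, cadenceHz, jitter, seed) {
  nominal <- 1 / cadenceHz
  withSeed(seed, {
    durs <- numeric(0)
    total <- 0
    while (total < duration) {
      d <- nominal * (1 + stats::runif(1, -jitter, jitter))
      durs <- c(durs, d)
      total <- total + d
    }
    starts <- cumsum(c(0, durs))
    phaseAt <- function(t) {
      i <- findInterval(t, starts, rightmost.closed = FALSE)
      (t - starts[i]) / durs[i]
    }
    list(phaseAt = phaseAt, strideStarts = starts)
  })
}

#' Generate one synthetic walking trial
#'
#' Produces a full [EMGRecording-class]: six sEMG channels at the configured
#' rate (activation envelopes evaluated on the per-stride jittered phase,
#' modulating band-limited noise) and a knee-angle stream with additive
#' measurement noise. The ground-truth phase at the angle rate is stored in
#' the recording. Generation is a pure function of (config, trial index).
#'
#' @param config a [GaitSimConfig-class].
#' @param trial trial index (1-based); determines the trial's seed stream.
#' @param subjectId subject label.
#' @return an [EMGRecording-class].
#' @export
generateTrial <- function(config, trial = 1L, subjectId = "SYN1") {
  validObject(config)
  sdT <- deriveSeed(config@seed, 1000L + trial)
  nE <- round(config@trialDurationS * config@emgRate)
  nA <- round(config@trialDurationS * config@angleRate)
  tE <- (seq_len(nE) - 1) / config@emgRate
  tA <- (seq_len(nA) - 1) / config@angleRate
  sp <- stridePhase(config@trialDurationS, config@cadenceHz,
                    config@cadenceJitter, deriveSeed(sdT, 1L))
  phE <- sp$phaseAt(tE)
  phA <- sp$phaseAt(tA)
  emgMat <- matrix(0, nE, length(config@muscles))
  for (m in seq_along(config@muscles)) {
    env <- activationEnvelope(config@muscles[m], phE, config)
    emgMat[, m] <- synthesizeEMG(env, config@emgRate, snrDb = config@snrDb,
                                 seed = deriveSeed(sdT, 10L + m))
  }
  angle <- kneeAngleProfile(phA, config@angleTemplate)
  if (config@angleNoiseDeg > 0) {
    angle <- angle + withSeed(deriveSeed(sdT, 99L),
                              rnorm(nA, sd = config@angleNoiseDeg))
  }
  EMGRecording(emg = emgMat, emgRate = config@emgRate,
               channelLabels = config@muscles, angle = angle,
               angleRate = config@angleRate, subjectId = subjectId,
               trialId = sprintf("T%02d", trial), phase = phA)
}

#' Generate a full synthetic subject
#'
#' @param config a [GaitSimConfig-class].
#' @param subjectId subject label.
#' @return list of [EMGRecording-class], one per trial.
#' @export
generateSubject <- function(config = defaultGaitConfig(),
                            subjectId = "SYN1") {
  lapply(seq_len(config@nTrials), function(i)
    generateTrial(config, i, subjectId))
}

#' Write a synthetic dataset to disk
#'
#' Writes each trial in the standard on-disk dialect plus a
#' `ground_truth.json` per trial containing the gait phase and the six
#' activation envelopes at the angle rate.
#'
#' @param recordings list of [EMGRecording-class] from [generateSubject()].
#' @param dir output directory.
#' @param config the generating [GaitSimConfig-class] (for envelopes).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(recordings, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in recordings) {
    stem <- file.path(dir, paste0(rec@subjectId, "_", rec@trialId))
    writeRecording(rec, stem)
    if (!is.null(config) && length(rec@phase)) {
      gt <- list(phase = rec@phase)
      for (m in config@muscles) {
        gt[[paste0("env_", m)]] <- activationEnvelope(m, rec@phase, config)
      }
      jsonlite::write_json(gt, paste0(stem, ".ground_truth.json"),
                           digits = 8)
    }
  }
  invisible(dir)
}
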