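#' @include signal_io.R features.R fgcnn.R regression.R evaluation.R
#' @include synthetic_gait.R
NULL

FEATURE_SETS <- c("HF", "CNN", "FGCNN")

# Resolve a user experiment config (R list or YAML path) against defaults.
resolveExperimentConfig <- function(config) {
  if (is.character(config)) {
    stopIf(!file.exists(config), "config file not found: ", config,
           class = "fgcnnConfigError")
    config <- yaml::read_yaml(config)
  }
  stopIf(!is.list(config), "config must be a list or a YAML path",
         class = "fgcnnConfigError")
  def <- list(
    sim = NULL, dataDir = NULL,
    muscle = "LG",
    featureSets = "HF",
    regressors = "RF",
    cv = list(k = 5L, scheme = "trial"),
    window = list(ms = 50, stepMs = 20),
    filter = list(low = 10, high = 500, order = 4),
    fgcnn = list(epochs = 50L, batchSize = 64L, learningRate = 0.001),
    seed = 0L, outDir = NULL)
  for (nm in names(config)) {
    bad <- !nm %in% names(def)
    stopIf(bad, "unknown config field '", nm, "'", class = "fgcnnConfigError")
    if (is.list(def[[nm]]) && is.list(config[[nm]])) {
      for (sub in names(config[[nm]])) {
        stopIf(!sub %in% names(def[[nm]]),
               "unknown config field '", nm, ".", sub, "'",
               class = "fgcnnConfigError")
        def[[nm]][[sub]] <- config[[nm]][[sub]]
      }
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  stopIf(is.null(def$sim) == is.null(def$dataDir),
         "exactly one data source required: set 'sim' or 'dataDir'",
         class = "fgcnnConfigError")
  if (!is.null(def$dataDir)) {
    stopIf(!dir.exists(def$dataDir), "dataDir does not exist: ", def$dataDir,
           class = "fgcnnConfigError")
  }
  if (identical(def$featureSets, "all")) def$featureSets <- FEATURE_SETS
  stopIf(!all(def$featureSets %in% FEATURE_SETS),
         "featureSets must be drawn from HF, CNN, FGCNN",
         class = "fgcnnConfigError")
  if (identical(def$muscle, "all")) def$muscle <- KNOWN_MUSCLES
  def$seed <- as.integer(def$seed)
  def
}

loadRecordings <- function(cfg) {
  if (!is.null(cfg$sim)) {
    simArgs <- cfg$sim
    if (is.null(simArgs$seed)) simArgs$seed <- cfg$seed
    gait <- do.call(defaultGaitConfig, simArgs)
    generateSubject(gait)
  } else {
    stems <- sub("\\.meta\\.json$", "",
                 list.files(cfg$dataDir, pattern = "\\.meta\\.json$",
                            full.names = TRUE))
    stopIf(length(stems) == 0L, "no recordings found in ", cfg$dataDir,
           class = "fgcnnConfigError")
    lapply(sort(stems), readRecording)
  }
}

subsetWindows <- function(dataset, idx) {
  new("WindowedDataset", windows = dataset@windows[idx, , drop = FALSE],
      targetsDeg = dataset@targetsDeg[idx],
      windowEndTimes = dataset@windowEndTimes[idx],
      trialIds = dataset@trialIds[idx],
      sourceChannel = dataset@sourceChannel, emgRate = dataset@emgRate)
}

# Train/extract one feature set for one fold; returns an N x d matrix over
# ALL windows (training used only the train subset).
foldFeatures <- function(set, dataset, trainIdx, pAll, scaler, netCfg) {
  if (set == "HF") return(pAll)
  train <- subsetWindows(dataset, trainIdx)
  train@targetsScaled <- scaleAngles(scaler, train@targetsDeg)
  if (set == "FGCNN") {
    model <- trainFGCNN(train, netCfg$fg, p = pAll[trainIdx, , drop = FALSE])
    extractFGCNNFeatures(model, dataset@windows, pAll)
  } else {
    model <- trainBaselineCNN(train, netCfg$cnn)
    extractCNNFeatures(model, dataset@windows)
  }
}

#' Run a full estimation experiment
#'
#' Orchestrates the complete pipeline: simulate (or load) recordings, filter
#' and window the selected muscle channels, compute handcrafted features,
#' train the guided/unguided networks per cross-validation fold as required
#' by the requested feature sets, fit the downstream regressors, and score
#' every (muscle, feature set, regressor, fold) cell with NRMSE and CC.
#' When several feature sets are evaluated, a Kruskal-Wallis test compares
#' them on both metrics.
#'
#' @param config experiment configuration: an R list or path to a YAML file.
#'   Fields (all optional except one data source): `sim` (overrides for
#'   [defaultGaitConfig()]) or `dataDir` (directory of recordings);
#'   `muscle` (label(s) or "all"); `featureSets` (subset of HF/CNN/FGCNN or
#'   "all"); `regressors` (kinds or [regressorSpec()] list); `cv` (k,
#'   scheme); `window` (ms, stepMs); `filter` (low, high, order); `fgcnn`
#'   (epochs, batchSize, learningRate); `seed`; `outDir`.
#' @return list with `results` (data.frame of per-fold scores), `stats`
#'   (Kruskal-Wallis comparisons or NULL), `config` (resolved), and `files`
#'   (paths written, when `outDir` is set).
#' @export
runExperiment <- function(config) {
  cfg <- resolveExperimentConfig(config)
  recs <- loadRecordings(cfg)
  subject <- recs[[1]]@subjectId
  regSpecs <- lapply(cfg$regressors, function(r) {
    if (inherits(r, "regressorSpec")) r
    else regressorSpec(r, seed = deriveSeed(cfg$seed, 7L))
  })
  inputLen <- as.integer(round(cfg$window$ms * recs[[1]]@emgRate / 1000))
  mkNetCfg <- function(fold) list(
    fg = FGCNNConfig(inputLen = inputLen,
                     epochs = as.integer(cfg$fgcnn$epochs),
                     batchSize = as.integer(cfg$fgcnn$batchSize),
                     learningRate = cfg$fgcnn$learningRate,
                     seed = deriveSeed(cfg$seed, 300L + fold)),
    cnn = baselineCNNConfig(inputLen = inputLen,
                            epochs = as.integer(cfg$fgcnn$epochs),
                            batchSize = as.integer(cfg$fgcnn$batchSize),
                            learningRate = cfg$fgcnn$learningRate,
                            seed = deriveSeed(cfg$seed, 600L + fold)))
  rows <- list()
  for (muscle in cfg$muscle) {
    ds <- bindWindowedDatasets(lapply(recs, function(r)
      windowRecording(r, muscle, windowMs = cfg$window$ms,
                      stepMs = cfg$window$stepMs,
                      low = cfg$filter$low, high = cfg$filter$high,
                      order = cfg$filter$order)))
    ds <- makeFolds(ds, k = as.integer(cfg$cv$k), scheme = cfg$cv$scheme,
                    seed = deriveSeed(cfg$seed, 5L))
    pAll <- handcraftedFeatures(ds@windows)
    for (fold in sort(unique(ds@foldIds))) {
      testIdx <- which(ds@foldIds == fold)
      trainIdx <- which(ds@foldIds != fold)
      stopIf(length(intersect(trainIdx, testIdx)) > 0L,
             "cross-validation fold leakage", class = "fgcnnInternalError")
      scaler <- fitAngleScaler(ds@targetsDeg[trainIdx])
      netCfg <- mkNetCfg(fold)
      for (set in cfg$featureSets) {
        feats <- foldFeatures(set, ds, trainIdx, pAll, scaler, netCfg)
        for (spec in regSpecs) {
          model <- fitRegressor(feats[trainIdx, , drop = FALSE],
                                ds@targetsDeg[trainIdx], spec)
          pred <- predictAngles(model, feats[testIdx, , drop = FALSE])
          rows[[length(rows) + 1L]] <-
            scoreFold(subject, muscle, set, spec$kind, fold,
                      ds@targetsDeg[testIdx], pred)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  stats <- NULL
  if (length(cfg$featureSets) >= 2L) {
    stats <- list()
    for (metric in c("cc", "nrmse")) {
      groups <- split(results[[metric]], results$feature_set)
      stats[[metric]] <- kruskalWallisTest(groups)
    }
  }
  files <- NULL
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    csvPath <- file.path(cfg$outDir, "results.csv")
    utils::write.csv(results, csvPath, row.names = FALSE)
    summaryPath <- file.path(cfg$outDir, "summary.json")
    echo <- cfg
    echo$regressors <- vapply(regSpecs, function(s) s$kind, character(1))
    jsonlite::write_json(
      list(config = echo, configHash = rlang::hash(echo),
           seed = cfg$seed,
           packageVersion = as.character(utils::packageVersion("fgcnn")),
           stats = stats),
      summaryPath, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(results = csvPath, summary = summaryPath)
  }
  list(results = results, stats = stats, config = cfg, files = files)
}

# ---------------------------------------------------------------------------
# Command-line interface (inst/cli/fgcnn.R delegates here).

cliUsage <- function() {
  paste(
    "usage: fgcnn.R <command> [options]",
    "",
    "commands:",
    "  simulate --out DIR [--trials N] [--duration S] [--seed N]",
    "      write a synthetic subject in the on-disk recording dialect",
    "  run --config FILE [--seed N] [--out DIR]",
    "      run a full experiment from a YAML config",
    "  features --data DIR --muscle M --out FILE",
    "      band-pass, window and export the 14 handcrafted features",
    sep = "\n")
}

parseFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    stopIf(!startsWith(args[i], "--"), "unexpected argument: ", args[i],
           class = "fgcnnConfigError")
    stopIf(i + 1L > length(args), "flag ", args[i], " needs a value",
           class = "fgcnnConfigError")
    flags[[substring(args[i], 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `run` and `features` subcommands used by the
#' shipped CLI script (`system.file("cli", "fgcnn.R", package = "fgcnn")`).
#' Returns an exit status instead of quitting so it can be driven
#' programmatically: 0 on success, 1 for user errors (bad flags, missing
#' files), 2 for internal errors.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cliMain <- function(args) {
  status <- tryCatch({
    if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
      message(cliUsage())
      return(invisible(0L))
    }
    cmd <- args[1]
    flags <- parseFlags(args[-1])
    if (cmd == "simulate") {
      stopIf(is.null(flags$out), "simulate needs --out",
             class = "fgcnnConfigError")
      cfgArgs <- list()
      if (!is.null(flags$trials)) cfgArgs$nTrials <- as.integer(flags$trials)
      if (!is.null(flags$duration))
        cfgArgs$trialDurationS <- as.numeric(flags$duration)
      if (!is.null(flags$seed)) cfgArgs$seed <- as.integer(flags$seed)
      gait <- do.call(defaultGaitConfig, cfgArgs)
      writeDataset(generateSubject(gait), flags$out, gait)
      message("wrote ", gait@nTrials, " trials to ", flags$out)
      0L
    } else if (cmd == "run") {
      stopIf(is.null(flags$config), "run needs --config",
             class = "fgcnnConfigError")
      cfg <- resolveExperimentConfig(flags$config)
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
      if (!is.null(flags$out)) cfg$outDir <- flags$out
      res <- runExperiment(cfg)
      message(sprintf("%d result rows; mean CC %.3f, mean NRMSE %.1f%%",
                      nrow(res$results), mean(res$results$cc),
                      mean(res$results$nrmse)))
      0L
    } else if (cmd == "features") {
      stopIf(is.null(flags$data) || is.null(flags$muscle) ||
               is.null(flags$out),
             "features needs --data, --muscle and --out",
             class = "fgcnnConfigError")
      recs <- loadRecordings(list(dataDir = flags$data, sim = NULL))
      ds <- bindWindowedDatasets(lapply(recs, windowRecording,
                                        channel = flags$muscle))
      writeFeatureTable(handcraftedFeatures(ds@windows), flags$out)
      message("wrote ", nWindows(ds), " feature rows to ", flags$out)
      0L
    } else {
      stopIf(TRUE, "unknown command '", cmd, "'", class = "fgcnnConfigError")
    }
  },
  fgcnnError = function(e) { message("error: ", conditionMessage(e)); 1L },
  error = function(e) { message("internal error: ", conditionMessage(e)); 2L })
  invisible(status)
}
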