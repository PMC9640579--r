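# Orchestration: config resolution, the full pipeline contract, and the CLI.
# Networks run at reduced depth (few epochs, short trials) -- the full-scale
# study conditions are exercised by the acceptance suite.

miniSim <- list(nTrials = 5L, trialDurationS = 5)

test_that("config resolution validates fields and data sources", {
  expect_error(runExperiment(list(featureSets = "HF")),
               class = "fgcnnConfigError")   # no data source
  expect_error(runExperiment(list(sim = miniSim, dataDir = ".")),
               class = "fgcnnConfigError")   # two data sources
  expect_error(runExperiment(list(sim = miniSim, bogus = 1)),
               class = "fgcnnConfigError")
  expect_error(runExperiment(list(sim = miniSim, cv = list(bogus = 2))),
               class = "fgcnnConfigError")
  expect_error(runExperiment(list(sim = miniSim, featureSets = "XXX")),
               class = "fgcnnConfigError")
})

test_that("a handcrafted-features experiment produces one row per fold", {
  res <- runExperiment(list(sim = miniSim, muscle = "LG",
                            featureSets = "HF", seed = 2L))
  expect_identical(nrow(res$results), 5L)
  expect_setequal(res$results$fold, 1:5)
  expect_true(all(res$results$feature_set == "HF"))
  expect_true(all(res$results$nrmse >= 0))
  expect_true(all(abs(res$results$cc) <= 1))
  expect_null(res$stats)
})

test_that("all feature sets yield the cartesian results plus statistics", {
  dir <- withr::local_tempdir()
  cfg <- list(sim = miniSim, muscle = "LG", featureSets = "all",
              regressors = "RF", fgcnn = list(epochs = 3L), seed = 3L,
              outDir = dir)
  res <- runExperiment(cfg)
  expect_identical(nrow(res$results), 15L)  # 3 feature sets x 5 folds
  expect_setequal(unique(res$results$feature_set), c("HF", "CNN", "FGCNN"))
  expect_false(is.null(res$stats))
  expect_true(all(c("cc", "nrmse") %in% names(res$stats)))
  expect_true(file.exists(res$files["results"]))
  expect_true(file.exists(res$files["summary"]))
  js <- jsonlite::fromJSON(res$files["summary"])
  expect_identical(js$seed, 3L)
  expect_true(nchar(js$configHash) > 0)
})

test_that("rerunning an identical config reproduces the results byte-for-byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  base <- list(sim = miniSim, muscle = "LG", featureSets = "FGCNN",
               fgcnn = list(epochs = 2L), seed = 4L)
  r1 <- runExperiment(c(base, list(outDir = d1)))
  r2 <- runExperiment(c(base, list(outDir = d2)))
  expect_identical(readBin(file.path(d1, "results.csv"), "raw", 1e6),
                   readBin(file.path(d2, "results.csv"), "raw", 1e6))
  # and a different seed changes the numbers
  r3 <- runExperiment(c(base[-length(base)], list(seed = 5L)))
  expect_false(identical(r1$results$cc, r3$results$cc))
})

test_that("experiment configs load from YAML", {
  dir <- withr::local_tempdir()
  cfgPath <- file.path(dir, "exp.yaml")
  yaml::write_yaml(list(sim = list(nTrials = 5, trialDurationS = 5),
                        muscle = "LG", featureSets = "HF", seed = 2),
                   cfgPath)
  res <- runExperiment(cfgPath)
  expect_identical(nrow(res$results), 5L)
})

test_that("the CLI dispatches, validates and reports exit codes", {
  expect_identical(suppressMessages(cliMain(character(0))), 0L)
  expect_identical(suppressMessages(cliMain("--help")), 0L)
  expect_identical(suppressMessages(cliMain("frobnicate")), 1L)
  expect_identical(suppressMessages(cliMain(c("simulate", "--trials"))), 1L)

  dir <- withr::local_tempdir()
  simDir <- file.path(dir, "sim")
  st <- suppressMessages(cliMain(c("simulate", "--out", simDir,
                                   "--trials", "5", "--duration", "3",
                                   "--seed", "9")))
  expect_identical(st, 0L)
  expect_length(list.files(simDir, pattern = "meta\\.json$"), 5L)

  featPath <- file.path(dir, "feat.csv")
  st <- suppressMessages(cliMain(c("features", "--data", simDir,
                                   "--muscle", "LG", "--out", featPath)))
  expect_identical(st, 0L)
  feats <- utils::read.csv(featPath)
  expect_identical(names(feats), HANDCRAFTED_FEATURE_NAMES)

  cfgPath <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(dataDir = simDir, muscle = "LG",
                        featureSets = "HF"), cfgPath)
  st <- suppressMessages(cliMain(c("run", "--config", cfgPath,
                                   "--seed", "3", "--out",
                                   file.path(dir, "out"))))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(dir, "out", "results.csv")))
})
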