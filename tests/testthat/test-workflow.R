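test_that("run configurations round-trip through YAML", {
  cfg <- runConfig(task = taskConfig(nBlocks = 5L),
                   nPerGroup = 3L,
                   effects = effectSpec(n2pc = -2, noiseSd = 4),
                   fs = 250, montage = "compact",
                   pipeline = list(tbt = FALSE), seed = 42L)
  path <- tempfile(fileext = ".yaml")
  writeRunConfig(cfg, path)
  back <- readRunConfig(path)
  expect_equal(back$task, cfg$task)
  expect_equal(back$effects, cfg$effects)
  expect_equal(back$pipeline, cfg$pipeline)
  expect_equal(back$seed, cfg$seed)
  expect_equal(lapply(back$agents, unclass), lapply(cfg$agents, unclass))
  expect_identical(prlerp:::configHash(back), prlerp:::configHash(cfg))
})

test_that("simulated cohorts write complete, reproducible run directories", {
  cfg <- runConfig(task = taskConfig(nBlocks = 2L), nPerGroup = 1L,
                   effects = effectSpec(noiseSd = 2, pinkSd = 2),
                   fs = 250, seed = 7L)
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  m1 <- runSimulate(cfg, d1)
  m2 <- runSimulate(cfg, d2)
  expect_identical(m1, m2)                 # same seed, same manifests
  expect_true(file.exists(file.path(d1, "trials.csv")))
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  tr <- read.csv(file.path(d1, "trials.csv"))
  expect_equal(nrow(tr), 2L * 2L * 18L)
  expect_true(all(c("subject", "block", "trial", "set_winner",
                    "left_stimulus", "right_stimulus", "choice",
                    "chosen_side", "feedback", "strategy_next")
                  %in% names(tr)))
  # trial-log round trip preserves the sessions
  sess <- readTrialLogs(file.path(d1, "trials.csv"))
  expect_length(sess, 2L)
  expect_equal(nrow(trialLog(sess[[1]])), 36L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("behaviour-only simulation writes 30 subjects x 360 trials by default", {
  cfg <- runConfig(seed = 3L)
  d <- file.path(tempdir(), "runC")
  runSimulate(cfg, d, epochs = FALSE)
  tr <- read.csv(file.path(d, "trials.csv"))
  expect_equal(length(unique(tr$subject)), 30L)
  expect_equal(nrow(tr), 30L * 360L)
  unlink(d, recursive = TRUE)
})

test_that("practice-mode cohorts run 36 trials per subject", {
  cfg <- runConfig(task = taskConfig(practice = TRUE), nPerGroup = 2L,
                   seed = 5L)
  d <- file.path(tempdir(), "runD")
  runSimulate(cfg, d, epochs = FALSE)
  tr <- read.csv(file.path(d, "trials.csv"))
  expect_equal(as.vector(table(tr$subject)), rep(36L, 4L))
  unlink(d, recursive = TRUE)
})

test_that("analysis runs are pure functions of config and data", {
  cfg <- runConfig(task = taskConfig(nBlocks = 3L), nPerGroup = 2L,
                   effects = effectSpec(noiseSd = 3, pinkSd = 3,
                                        blinkRate = 0),
                   fs = 250, montage = "compact",
                   pipeline = list(filter = NULL, resampleTo = NULL,
                                   tbt = FALSE), seed = 11L)
  a <- runAnalyze(cfg)
  b <- runAnalyze(cfg)
  expect_identical(a$measures, b$measures)
  expect_identical(a$profiles, b$profiles)
  expect_equal(nrow(a$measures), 4L)
  expect_true(all(c("rewp_diff", "n2pc_chosen", "learner_class")
                  %in% names(a$measures)))
  # result tables are written on request
  out <- file.path(tempdir(), "resE")
  runAnalyze(cfg, outDir = out)
  expect_true(all(file.exists(file.path(out,
    c("behavior_profiles.csv", "learning_curve.csv", "erp_measures.csv",
      "strategy_by_half.csv", "p300_anova.csv", "behavior_anova.csv")))))
  unlink(out, recursive = TRUE)
})

test_that("analysis reads back a simulated run directory", {
  cfg <- runConfig(task = taskConfig(nBlocks = 3L), nPerGroup = 2L,
                   effects = effectSpec(noiseSd = 3, pinkSd = 3,
                                        blinkRate = 0),
                   fs = 250, montage = "compact",
                   pipeline = list(filter = NULL, resampleTo = NULL,
                                   tbt = FALSE), seed = 11L)
  d <- file.path(tempdir(), "runF")
  runSimulate(cfg, d)
  res <- runAnalyze(cfg, dir = d)
  direct <- runAnalyze(cfg)
  expect_equal(res$measures[order(res$measures$subject),
                            setdiff(names(res$measures), "subject")],
               direct$measures[order(direct$measures$subject),
                               setdiff(names(direct$measures), "subject")],
               tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
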