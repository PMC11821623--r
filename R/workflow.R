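# Reproducible end-to-end workflow: a run is a pure function of its
# RunConfig and seed. One master seed fans out to per-subject,
# per-repetition substreams (see subSeed()) so stages can be re-run
# independently.

#' Compact analysis montage
#'
#' The full montage restricted to the channels the standard measurement
#' stage uses: the frontal, centro-parietal and occipital ROIs plus the
#' mastoid pair (27 channels). Reduced-channel synthesis with this montage
#' makes Monte-Carlo recovery studies cheap without changing any ROI
#' definition.
#'
#' @return a [Montage-class].
#' @export
compactMontage <- function() {
  m <- hydrocelMontage()
  subsetMontage(m, unique(c(unlist(m@rois), m@mastoids)))
}

# Rescorla-Wagner parameters per learner group, chosen so the simulated
# groups reproduce roughly the observed good/poor overall accuracies
# (~73% / ~56%) of the task at its default contingency.
defaultGroupAgents <- function() {
  list(good = agentSpec("rescorla_wagner", alpha = 0.25, beta = 3,
                        group = "good"),
       poor = agentSpec("rescorla_wagner", alpha = 0.06, beta = 1.8,
                        group = "poor"))
}

#' Workflow configuration
#'
#' Bundles everything a run depends on: task, agent cohort (a named list
#' of [agentSpec()], one per learner group), effect/noise specification,
#' synthesis sampling rate, montage choice and pipeline toggles. A run is
#' a pure function of its configuration and seed.
#'
#' @param task a [taskConfig()].
#' @param agents named list of [agentSpec()].
#' @param nPerGroup subjects per group.
#' @param effects an [effectSpec()].
#' @param fs synthesis sampling rate, Hz.
#' @param montage \code{"full"} (129 channels), \code{"compact"} (ROI
#'   channels + mastoids) or a [Montage-class].
#' @param pipeline list of stage toggles: \code{removeOuterRing},
#'   \code{detectBadChannels}, \code{resampleTo} (Hz or NULL),
#'   \code{filter} (c(low, high) or NULL), \code{notch} (logical),
#'   \code{reref}, \code{baseline} (window or NULL), \code{tbt},
#'   \code{n2pcWindow} (175--225 default; the 175--275 variant is also
#'   accepted), \code{strategyMode}.
#' @param seed master seed.
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(task = taskConfig(),
                      agents = defaultGroupAgents(),
                      nPerGroup = 15L,
                      effects = effectSpec(),
                      fs = 250,
                      montage = "compact",
                      pipeline = list(),
                      seed = 1L) {
  defaults <- list(removeOuterRing = TRUE, detectBadChannels = FALSE,
                   resampleTo = 250, filter = c(0.1, 30), notch = FALSE,
                   reref = TRUE, baseline = c(-200, 0), tbt = TRUE,
                   n2pcWindow = c(175, 225), strategyMode = "conditional")
  pipeline <- utils::modifyList(defaults, pipeline)
  stopifnot(inherits(task, "TaskConfig"), inherits(effects, "EffectSpec"),
            is.list(agents), length(names(agents)) == length(agents))
  structure(list(task = task, agents = agents,
                 nPerGroup = as.integer(nPerGroup), effects = effects,
                 fs = fs, montage = montage, pipeline = pipeline,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

.resolveMontage <- function(montage) {
  if (is(montage, "Montage")) return(montage)
  switch(montage,
         full = hydrocelMontage(),
         compact = compactMontage(),
         stop("unknown montage: ", montage))
}

#' Write / read a workflow configuration
#'
#' Round-trips a [runConfig()] through YAML so a full synthetic-cohort run
#' is driven by one structured config file.
#'
#' @param config a [runConfig()].
#' @param path file path.
#' @return \code{readRunConfig} returns the [runConfig()].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  y <- list(
    task = unclass(config$task),
    agents = lapply(config$agents, unclass),
    nPerGroup = config$nPerGroup,
    effects = lapply(unclass(config$effects), function(v)
      if (is.null(names(v))) v else as.list(v)),
    fs = config$fs,
    montage = if (is.character(config$montage)) config$montage else "custom",
    pipeline = config$pipeline,
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  eff <- y$effects
  eff$rewpDiffByGroup <- unlist(eff$rewpDiffByGroup)
  eff$p300ByCell <- unlist(eff$p300ByCell)
  runConfig(
    task = do.call(taskConfig, y$task),
    agents = lapply(y$agents, function(a) do.call(agentSpec, a)),
    nPerGroup = y$nPerGroup,
    effects = do.call(effectSpec, eff),
    fs = y$fs,
    montage = y$montage,
    pipeline = lapply(y$pipeline, function(v) if (is.list(v)) unlist(v) else v),
    seed = y$seed)
}

# md5 of the canonical YAML serialization
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeRunConfig(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write cohort trial logs as CSV
#'
#' One row per trial with columns subject, block, trial, set_winner,
#' left_stimulus, right_stimulus, choice, chosen_side, feedback,
#' strategy_next (plus the descriptive rt_ms).
#'
#' @param sessions list of [SubjectSession-class].
#' @param path CSV path.
#' @export
writeTrialLogs <- function(sessions, path) {
  rows <- lapply(sessions, function(s)
    cbind(subject = s@subject, s@trials))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cohort trial logs
#'
#' Rebuilds one [SubjectSession-class] per subject from a CSV written by
#' [writeTrialLogs()] (or any file with that schema). The generating agent
#' is unknown for real data, so the agent slot records kind
#' \code{"data"}; learner groups are derived downstream by the median
#' split, never read from the file.
#'
#' @param path CSV path.
#' @return named list of [SubjectSession-class].
#' @export
readTrialLogs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject), function(tr) {
    new("SubjectSession", subject = tr$subject[1],
        trials = tr[setdiff(names(tr), "subject")],
        agent = list(kind = "data", group = "all"),
        task = list(nBlocks = max(tr$block),
                    trialsPerBlock = max(tr$trial)))
  })
  out[order(names(out))]
}

#' Simulate a cohort and write its data to disk
#'
#' Writes \code{trials.csv} (all subjects), per-subject epoch containers
#' (\code{epochs/<id>.rds} holding the cue/feedback [EpochSet-class] pair,
#' with a \code{epochs/<id>_events.csv} metadata sidecar), and a
#' \code{manifest.yaml} carrying the config, its hash and per-file md5
#' sums. Re-running with the same config and seed reproduces every file
#' bit for bit.
#'
#' @param config a [runConfig()].
#' @param dir output directory (created if needed).
#' @param epochs logical; also synthesize and store EEG epochs (set
#'   \code{FALSE} for behaviour-only runs).
#' @return the manifest, invisibly.
#' @export
runSimulate <- function(config, dir, epochs = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  montage <- .resolveMontage(config$montage)
  sessions <- simulateCohort(config$task, config$agents,
                             config$nPerGroup, seed = config$seed)
  files <- character(0)
  writeTrialLogs(sessions, file.path(dir, "trials.csv"))
  files <- c(files, "trials.csv")
  if (epochs) {
    epDir <- file.path(dir, "epochs")
    if (!dir.exists(epDir)) dir.create(epDir)
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      ep <- synthesizeEpochs(s, config$effects, montage, fs = config$fs,
                             seed = subSeed(config$seed, i, 1000L))
      saveRDS(ep, file.path(epDir, paste0(s@subject, ".rds")))
      utils::write.csv(epochInfo(ep$feedback),
                       file.path(epDir, paste0(s@subject, "_events.csv")),
                       row.names = FALSE)
      files <- c(files, file.path("epochs", paste0(s@subject, ".rds")),
                 file.path("epochs", paste0(s@subject, "_events.csv")))
    }
  }
  md5 <- vapply(file.path(dir, files), function(f)
    unname(tools::md5sum(f)), "")
  manifest <- list(config_hash = configHash(config),
                   seed = config$seed,
                   n_subjects = length(sessions),
                   files = as.list(stats::setNames(md5, files)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

# full cleaning path for one subject's epoch pair, per pipeline toggles
.cleanEpochSet <- function(ep, montage, pl) {
  if (isTRUE(pl$removeOuterRing)) ep <- removeOuterRing(ep, montage)
  m <- subsetMontage(montage, channelNames(ep))
  if (isTRUE(pl$detectBadChannels)) {
    bad <- unique(detectBadChannels(ep, m)$channel)
    bad <- setdiff(bad, mastoids(m))
    if (length(bad) && length(bad) < nChannels(ep) - 4)
      ep <- interpolateSpherical(ep, bad, m)
  }
  if (!is.null(pl$resampleTo) && pl$resampleTo < ep@fs)
    ep <- resampleEpochs(ep, pl$resampleTo)
  if (!is.null(pl$filter))
    ep <- bandpassEpochs(ep, pl$filter[1], pl$filter[2])
  if (isTRUE(pl$notch)) ep <- notchEpochs(ep)
  if (isTRUE(pl$reref)) ep <- rereferenceMastoids(ep, m)
  if (!is.null(pl$baseline)) ep <- baselineCorrect(ep, pl$baseline)
  report <- NULL
  if (isTRUE(pl$tbt)) {
    res <- rejectEpochsTBT(ep, m)
    ep <- res$epochs
    report <- res$report
  }
  list(epochs = ep, montage = m, report = report)
}

#' Run the full analysis on a simulated (or loaded) cohort
#'
#' Behaviour: strategy proportions, learning curve, per-subject learning
#' rates, the good/poor median split, and the block-half contrast. EEG:
#' the cleaning pipeline per the config toggles, then the standard
#' measurement table per subject, then the group statistics (learner-group
#' t-test on the reward-positivity difference; the strategy x feedback x
#' learner mixed ANOVA on P300 cell means; one-sample t-tests on the
#' chosen-side and winner-side N2pc; the strategy x block-half x learner
#' ANOVA on behaviour).
#'
#' @param config a [runConfig()].
#' @param dir optional directory written by [runSimulate()]; when NULL the
#'   cohort is simulated in memory from the config.
#' @param outDir optional directory for the result tables (CSV).
#' @return list with \code{profiles}, \code{learningCurve}, \code{halves},
#'   \code{measures}, \code{cleaning}, \code{stats}.
#' @export
runAnalyze <- function(config, dir = NULL, outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  montage <- .resolveMontage(config$montage)
  pl <- config$pipeline

  if (is.null(dir)) {
    sessions <- simulateCohort(config$task, config$agents,
                               config$nPerGroup, seed = config$seed)
    epochsOf <- function(i) synthesizeEpochs(
      sessions[[i]], config$effects, montage, fs = config$fs,
      seed = subSeed(config$seed, i, 1000L))
  } else {
    sessions <- readTrialLogs(file.path(dir, "trials.csv"))
    epochsOf <- function(i) readRDS(
      file.path(dir, "epochs", paste0(sessions[[i]]@subject, ".rds")))
  }

  profiles <- medianSplit(behaviorProfiles(sessions,
                                           mode = pl$strategyMode))
  curve <- learningCurve(sessions)
  halves <- halvesContrast(sessions, mode = pl$strategyMode)

  measures <- list()
  cleaning <- list()
  for (i in seq_along(sessions)) {
    ep <- epochsOf(i)
    fb <- .cleanEpochSet(ep$feedback, montage, pl)
    cu <- .cleanEpochSet(ep$cue, montage, pl)
    measures[[i]] <- subjectErpMeasures(cu$epochs, fb$epochs, fb$montage,
                                        n2pcWindow = pl$n2pcWindow)
    cleaning[[i]] <- fb$report
  }
  measures <- do.call(rbind, measures)
  measures <- merge(measures,
                    profiles[c("subject", "learner_class", "learning_rate")],
                    by = "subject")

  stats <- cohortStats(measures, halves, profiles)
  out <- list(profiles = profiles, learningCurve = curve, halves = halves,
              measures = measures, cleaning = cleaning, stats = stats)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.csv(profiles, file.path(outDir, "behavior_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(outDir, "learning_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(halves, file.path(outDir, "strategy_by_half.csv"),
                     row.names = FALSE)
    utils::write.csv(measures, file.path(outDir, "erp_measures.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(stats$p300Anova),
                     file.path(outDir, "p300_anova.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(stats$halvesAnova),
                     file.path(outDir, "behavior_anova.csv"),
                     row.names = FALSE)
    cl <- do.call(rbind, lapply(seq_along(cleaning), function(i) {
      if (is.null(cleaning[[i]])) return(NULL)
      cbind(subject = measures$subject[i], cleaning[[i]]@epochs)
    }))
    if (!is.null(cl))
      utils::write.csv(cl, file.path(outDir, "cleaning_report.csv"),
                       row.names = FALSE)
    con <- file(file.path(outDir, "stats_summary.txt"), "w")
    sink(con)
    cat("Reward positivity, poor vs good learners (independent t):\n")
    print(stats$rewpGroupT)
    cat("\nP300 mixed ANOVA (strategy x feedback x learner):\n")
    print(stats$p300Anova)
    cat("\nN2pc, chosen-side reference (one-sample t):\n")
    print(stats$n2pcChosenT)
    cat("\nN2pc, set-winner reference (one-sample t):\n")
    print(stats$n2pcWinnerT)
    if (!is.null(stats$halvesAnova)) {
      cat("\nBehaviour mixed ANOVA (strategy x block-half x learner):\n")
      print(stats$halvesAnova)
    }
    sink()
    close(con)
  }
  out
}

#' Group-level statistics on a cohort measurement table
#'
#' @param measures per-subject measurement table (from [runAnalyze()] or
#'   the recovery harness) with a \code{learner_class} column.
#' @param halves block-half strategy table from [halvesContrast()]
#'   (optional).
#' @param profiles behaviour profile table (optional, for the behaviour
#'   ANOVA grouping).
#' @return list of test results.
#' @export
cohortStats <- function(measures, halves = NULL, profiles = NULL) {
  good <- measures$rewp_diff[measures$learner_class == "good"]
  poor <- measures$rewp_diff[measures$learner_class == "poor"]
  enough <- length(good) >= 2 && length(poor) >= 2
  rewp <- if (enough) tTestD(poor, good, kind = "independent") else NULL

  long <- stats::reshape(
    measures[c("subject", "learner_class", "p300_gain_stay",
               "p300_gain_shift", "p300_loss_stay", "p300_loss_shift")],
    direction = "long",
    varying = c("p300_gain_stay", "p300_gain_shift",
                "p300_loss_stay", "p300_loss_shift"),
    v.names = "p300", timevar = "cell",
    times = c("gain_stay", "gain_shift", "loss_stay", "loss_shift"))
  long$feedback <- sub("_.*", "", long$cell)
  long$strategy <- sub(".*_", "", long$cell)
  p300Anova <- if (enough) suppressMessages(
    mixedAnova(long, "p300", within = c("strategy", "feedback"),
               between = "learner_class")) else NULL

  n2 <- nrow(measures) >= 2
  n2pcChosen <- if (n2) tTestD(measures$n2pc_chosen, kind = "one_sample")
  n2pcWinner <- if (n2) tTestD(measures$n2pc_winner, kind = "one_sample")

  halvesAnova <- NULL
  if (!is.null(halves) && !is.null(profiles) &&
      "learner_class" %in% names(profiles)) {
    hl <- stats::reshape(halves, direction = "long",
                         varying = c("ws", "ls"), v.names = "prop",
                         timevar = "strategy", times = c("ws", "ls"))
    hl <- merge(hl, profiles[c("subject", "learner_class")], by = "subject")
    halvesAnova <- suppressMessages(
      mixedAnova(hl, "prop", within = c("strategy", "half"),
                 between = "learner_class"))
  }
  list(rewpGroupT = rewp, p300Anova = p300Anova,
       n2pcChosenT = n2pcChosen, n2pcWinnerT = n2pcWinner,
       halvesAnova = halvesAnova)
}
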