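# Monte-Carlo parameter-recovery and type-I-error calibration harnesses.
#
# Problem sizes inside the repetition loop: synthesis runs directly at the
# analysis rate on lean ROI montages — the full frontal ROI plus the
# midline centro-parietal subset for feedback epochs, the occipital
# homologue pairs for cue epochs, plus the mastoid pair — with mastoid
# re-referencing and baseline correction but no filtering or trial
# rejection (the loop injects no artifacts and its noise is already
# band-limited). The lateral
# centro-parietal pairs only average down the channel-private noise the
# ROI mean has already suppressed, so the midline subset carries the same
# injected amplitude at almost identical measurement noise. The
# full-fidelity path stays available through runAnalyze(). See the
# methods vignette.

.feedbackMontage <- function(montage) {
  mid <- intersect(montage@rois$centroparietal, montage@midline)
  subsetMontage(montage, unique(c(montage@rois$frontal, mid,
                                  montage@mastoids)))
}

.cueMontage <- function(montage) {
  subsetMontage(montage, unique(c(montage@rois$occipital_left,
                                  montage@rois$occipital_right,
                                  montage@mastoids)))
}

# chosen- and winner-referenced N2pc window means for one cue EpochSet
.cueN2pc <- function(cue, montage, window) {
  bySide <- suppressMessages(binAverage(cue, "chosen_side"))
  byWin <- suppressMessages(binAverage(cue, "winner_side"))
  ci <- function(bins) {
    if (is.null(bins[["left"]]) || is.null(bins[["right"]]))
      return(NA_real_)
    contraIpsi(bins[["left"]], bins[["right"]], montage, window)$mean
  }
  c(chosen = ci(bySide), winner = ci(byWin))
}

# one cohort repetition -> per-subject measures + battery statistics
.recoveryRep <- function(config, repIdx, probeWinner = TRUE) {
  base <- .resolveMontage(config$montage)
  mFb <- .feedbackMontage(base)
  mCue <- .cueMontage(base)
  pl <- config$pipeline
  sessions <- simulateCohort(config$task, config$agents, config$nPerGroup,
                             seed = subSeed(config$seed, repIdx, 1L))
  rows <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    fb <- synthesizeEpochs(s, config$effects, mFb, fs = config$fs,
                           seed = subSeed(config$seed, repIdx, i, 2L),
                           span = c(-200, 800), which = "feedback")$feedback
    cu <- synthesizeEpochs(s, config$effects, mCue, fs = config$fs,
                           seed = subSeed(config$seed, repIdx, i, 3L),
                           span = c(-200, 800), which = "cue")$cue
    fb <- baselineCorrect(rereferenceMastoids(fb, mFb), pl$baseline)
    cu <- baselineCorrect(rereferenceMastoids(cu, mCue), pl$baseline)

    win <- erpWindows()
    bins <- suppressMessages(binAverage(fb, "feedback"))
    rewpGain <- roiWindowMean(bins[["gain"]], "frontal", win$rewp, mFb)
    rewpLoss <- roiWindowMean(bins[["loss"]], "frontal", win$rewp, mFb)
    ok <- which(epochInfo(fb)$strat_next != "none")
    cells <- suppressMessages(binAverage(fb[ok, ],
                                         c("feedback", "strat_next")))
    p300 <- vapply(c("gain&stay", "gain&shift", "loss&stay", "loss&shift"),
                   function(cell)
                     if (is.null(cells[[cell]])) NA_real_
                     else roiWindowMean(cells[[cell]], "centroparietal",
                                        win$p300, mFb), 0)
    n2 <- .cueN2pc(cu, mCue, pl$n2pcWindow)

    rows[[i]] <- data.frame(
      subject = s@subject, gen_group = s@agent$group,
      learning_rate = as.numeric(fitLearningRate(s)),
      rewp_diff = rewpGain - rewpLoss,
      p300_gain_stay = p300[["gain&stay"]],
      p300_gain_shift = p300[["gain&shift"]],
      p300_loss_stay = p300[["loss&stay"]],
      p300_loss_shift = p300[["loss&shift"]],
      n2pc_chosen = n2[["chosen"]], n2pc_winner = n2[["winner"]],
      n_gain = bins[["gain"]]@n, n_loss = bins[["loss"]]@n,
      stringsAsFactors = FALSE)
  }
  meas <- medianSplit(do.call(rbind, rows))
  st <- cohortStats(meas)

  winnerP <- st$n2pcWinnerT$p
  winnerEst <- mean(meas$n2pc_winner)
  if (probeWinner) {
    # winner-referenced null check on an unbiased-choice cohort: with no
    # winner preference the chosen-side injection cancels by symmetry
    probeAgents <- list(all = agentSpec("random"))
    probeTask <- do.call(taskConfig,
                         utils::modifyList(unclass(config$task),
                                           list(nBlocks = 6L)))
    probeSessions <- simulateCohort(probeTask, probeAgents,
                                    2L * config$nPerGroup,
                                    seed = subSeed(config$seed, repIdx, 4L))
    pw <- vapply(seq_along(probeSessions), function(i) {
      cu <- synthesizeEpochs(probeSessions[[i]], config$effects, mCue,
                             fs = config$fs,
                             seed = subSeed(config$seed, repIdx, i, 5L),
                             span = c(-200, 800), which = "cue")$cue
      cu <- baselineCorrect(rereferenceMastoids(cu, mCue), pl$baseline)
      .cueN2pc(cu, mCue, pl$n2pcWindow)[["winner"]]
    }, 0)
    probeT <- tTestD(pw, kind = "one_sample")
    winnerP <- probeT$p
    winnerEst <- mean(pw)
  }

  an <- st$p300Anova
  pv <- stats::setNames(an$p, paste0("p_p300_",
                                     gsub(":", "_", an$effect)))
  good <- meas$rewp_diff[meas$learner_class == "good"]
  poor <- meas$rewp_diff[meas$learner_class == "poor"]
  c(list(
    p_rewp_group = st$rewpGroupT$p,
    est_rewp_good = mean(good), est_rewp_poor = mean(poor),
    est_rewp_good_gen = mean(meas$rewp_diff[meas$gen_group == "good"]),
    est_rewp_poor_gen = mean(meas$rewp_diff[meas$gen_group == "poor"]),
    rewp_poor_gt_good = mean(poor) > mean(good),
    p_n2pc_chosen = st$n2pcChosenT$p,
    est_n2pc_chosen = mean(meas$n2pc_chosen),
    p_n2pc_winner = winnerP, est_n2pc_winner = winnerEst,
    split_accuracy = mean(meas$learner_class == meas$gen_group),
    mean_n_gain = mean(meas$n_gain), mean_n_loss = mean(meas$n_loss)),
    as.list(pv),
    as.list(stats::setNames(
      colMeans(meas[c("p300_gain_stay", "p300_gain_shift",
                      "p300_loss_stay", "p300_loss_shift")]),
      c("est_p300_gain_stay", "est_p300_gain_shift",
        "est_p300_loss_stay", "est_p300_loss_shift"))))
}

#' Monte-Carlo effect-recovery study
#'
#' Repeats the whole chain — simulate a cohort, synthesize its epochs,
#' measure every subject, split learners at the median, run the group
#' statistics — \code{nReps} times under seeded substreams, and summarises
#' rejection rates (power under injected effects, type-I error under
#' null effects), estimate means (bias) and learner-split accuracy.
#'
#' The winner-referenced N2pc test is evaluated on an unbiased-choice
#' probe cohort of the same size; with a learning agent the chosen-side
#' component leaks into the winner-referenced average in proportion to
#' \code{2 P(choose winner) - 1}, so only an unbiased cohort isolates the
#' winner-driven component (see the methods vignette).
#'
#' @param config a [runConfig()]; \code{config$effects} defines the
#'   injected truth.
#' @param nReps repetitions.
#' @param alpha nominal level for the rejection-rate summary.
#' @param probeWinner evaluate the winner-referenced N2pc on the unbiased
#'   probe cohort (default TRUE).
#' @return list with \code{reps} (one row per repetition) and
#'   \code{summary} (rejection rate per test; mean estimate per measure).
#' @export
runRecover <- function(config, nReps = 100L, alpha = 0.05,
                       probeWinner = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  rows <- vector("list", nReps)
  for (r in seq_len(nReps))
    rows[[r]] <- as.data.frame(.recoveryRep(config, r, probeWinner))
  reps <- do.call(rbind, rows)
  pCols <- grep("^p_", names(reps), value = TRUE)
  rates <- vapply(pCols, function(cc)
    mean(reps[[cc]] < alpha, na.rm = TRUE), 0)
  estCols <- grep("^est_", names(reps), value = TRUE)
  ests <- vapply(estCols, function(cc) mean(reps[[cc]], na.rm = TRUE), 0)
  list(reps = reps,
       summary = list(alpha = alpha, nReps = nReps,
                      rejection_rate = rates, mean_estimate = ests,
                      split_accuracy = mean(reps$split_accuracy)))
}

#' Null configuration for type-I-error calibration
#'
#' All effect amplitudes zero, unbiased (random) agents in both nominal
#' groups, and a shortened session (6 blocks, 10 subjects per group) on
#' single-channel ROIs so hundreds of repetitions stay cheap; the
#' statistics' nominal level does not depend on those sizes.
#'
#' @param seed master seed.
#' @return a [runConfig()].
#' @export
nullRunConfig <- function(seed = 1L) {
  m <- hydrocelMontage()
  mini <- subsetMontage(m, c("E11", "E62", "E50", "E101", "E57", "E100"))
  runConfig(
    task = taskConfig(nBlocks = 6L),
    agents = list(good = agentSpec("random", group = "good"),
                  poor = agentSpec("random", group = "poor")),
    nPerGroup = 10L,
    effects = effectSpec(rewpDiffByGroup = c(good = 0, poor = 0),
                         p300ByCell = c(gain_stay = 0, gain_shift = 0,
                                        loss_stay = 0, loss_shift = 0),
                         n2pc = 0, n2pcWinner = 0,
                         lineAmp = 0, blinkRate = 0),
    fs = 250, montage = mini, seed = seed)
}

#' Type-I-error calibration of the statistical battery
#'
#' Runs the full battery over \code{nReps} cohorts generated under an
#' all-zero effect specification and reports, per test, the empirical
#' rejection rate with a binomial acceptance region around the nominal
#' level.
#'
#' @param nReps repetitions (default 500).
#' @param alpha nominal level.
#' @param seed master seed.
#' @param config the null configuration (default [nullRunConfig()]).
#' @param level coverage of the binomial acceptance region.
#' @return data.frame: test, rejection rate, acceptance bounds, pass.
#' @export
type1Calibration <- function(nReps = 500L, alpha = 0.05, seed = 1L,
                             config = NULL, level = 0.998) {
  if (is.null(config)) config <- nullRunConfig(seed)
  config$seed <- as.integer(seed)
  rec <- runRecover(config, nReps = nReps, alpha = alpha,
                    probeWinner = FALSE)
  rates <- rec$summary$rejection_rate
  lo <- stats::qbinom((1 - level) / 2, nReps, alpha) / nReps
  hi <- stats::qbinom(1 - (1 - level) / 2, nReps, alpha) / nReps
  data.frame(test = names(rates), rate = unname(rates),
             lower = lo, upper = hi,
             pass = unname(rates >= lo & rates <= hi))
}
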