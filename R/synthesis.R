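# Synthetic epoched EEG generator. Condition-dependent ERP components are
# injected as raised-cosine bumps confined to their measurement windows and
# normalized so the in-window mean equals the requested amplitude, which
# makes recovery targets exact in the noise-free case. Background activity
# is 1/f ("pink") noise with a spatially shared part plus white sensor
# noise, optional line noise, blinks, and optionally faulty channels.

#' Effect and noise specification for epoch synthesis
#'
#' Amplitudes of the three injected ERP effects and the parameters of the
#' background-activity model. All amplitudes are microvolts and refer to
#' the mean over the component's measurement window and ROI:
#' \describe{
#'   \item{rewpDiffByGroup}{named vector, gain-minus-loss frontal amplitude
#'     (275--375 ms) per learner group. The gain bin carries the bump, the
#'     loss bin none, so the difference wave equals the stated value.}
#'   \item{p300ByCell}{named vector with cells \code{gain_stay},
#'     \code{gain_shift}, \code{loss_stay}, \code{loss_shift}:
#'     centro-parietal amplitude (400--600 ms) by feedback and next-trial
#'     strategy. Block-final trials (no next trial) receive no P300 bump.}
#'   \item{n2pc}{occipital deflection (175--225 ms, cue-locked) added to
#'     channels contralateral to the chosen side; negative for the
#'     conventional N2pc polarity.}
#'   \item{n2pcWinner}{same, relative to the side of the set winner;
#'     default 0 (no winner-driven attention shift).}
#' }
#' The noise model: per-channel pink noise of standard deviation
#' \code{pinkSd} and exponent \code{pinkSlope}, of which the variance
#' fraction \code{spatialShared} is a single epoch-wide field common to all
#' channels (EEG background activity is spatially coherent; this also keeps
#' neighbouring channels correlated, which the low-correlation bad-channel
#' criterion presumes); white sensor noise \code{noiseSd}; line noise at
#' \code{lineFreq} with per-channel amplitudes around \code{lineAmp};
#' blink transients at \code{blinkRate} events per epoch, amplitude
#' \code{blinkAmp} weighted towards anterior channels; and
#' \code{nBadChannels} faulty channels (alternately flat and high-noise),
#' drawn from outside the ROIs and mastoids.
#'
#' @param rewpDiffByGroup named numeric vector (see above).
#' @param p300ByCell named numeric vector (see above).
#' @param n2pc,n2pcWinner scalars, microvolts.
#' @param noiseSd white-noise SD per sample.
#' @param pinkSd pink-noise SD per sample.
#' @param pinkSlope 1/f exponent (power ~ f^-slope).
#' @param pinkMaxHz upper band edge of the 1/f model (the analysis band
#'   ends at 30 Hz; above \code{pinkMaxHz} the background is white).
#' @param spatialShared fraction of pink variance shared across channels.
#' @param lineAmp,lineFreq line-noise amplitude (microvolts) and frequency (Hz).
#' @param blinkRate expected blinks per epoch; \code{blinkAmp} their peak.
#' @param blinkAmp blink peak amplitude, microvolts.
#' @param nBadChannels number of faulty channels to emulate.
#' @return a validated list of class \code{"EffectSpec"}.
#' @export
effectSpec <- function(rewpDiffByGroup = c(good = -1, poor = 2),
                       p300ByCell = c(gain_stay = 4, gain_shift = 5,
                                      loss_stay = 5, loss_shift = 6),
                       n2pc = -1.5, n2pcWinner = 0,
                       noiseSd = 8, pinkSd = 12, pinkSlope = 1,
                       pinkMaxHz = 45, spatialShared = 0.8,
                       lineAmp = 1, lineFreq = 60,
                       blinkRate = 0.05, blinkAmp = 120,
                       nBadChannels = 0L) {
  amps <- c(rewpDiffByGroup, p300ByCell, n2pc, n2pcWinner)
  if (!all(is.finite(amps))) stop("effect amplitudes must be finite")
  need <- c("gain_stay", "gain_shift", "loss_stay", "loss_shift")
  if (!all(need %in% names(p300ByCell)))
    stop("p300ByCell needs cells: ", paste(need, collapse = ", "))
  nn <- c(noiseSd, pinkSd, lineAmp, blinkRate, blinkAmp, nBadChannels)
  if (any(!is.finite(nn)) || any(nn < 0))
    stop("noise parameters must be finite and >= 0")
  if (spatialShared < 0 || spatialShared > 1)
    stop("spatialShared must lie in [0, 1]")
  structure(list(rewpDiffByGroup = rewpDiffByGroup, p300ByCell = p300ByCell,
                 n2pc = n2pc, n2pcWinner = n2pcWinner,
                 noiseSd = noiseSd, pinkSd = pinkSd, pinkSlope = pinkSlope,
                 pinkMaxHz = pinkMaxHz, spatialShared = spatialShared,
                 lineAmp = lineAmp, lineFreq = lineFreq,
                 blinkRate = blinkRate, blinkAmp = blinkAmp,
                 nBadChannels = as.integer(nBadChannels)),
            class = "EffectSpec")
}

# measurement windows (ms) of the injected components; also the defaults of
# the measurement stage
erpWindows <- function() {
  list(rewp = c(275, 375), p300 = c(400, 600), n2pc = c(175, 225))
}

#' Columns of 1/f ("pink") noise
#'
#' Unit-variance coloured Gaussian noise with power spectrum proportional
#' to \code{f^-slope} over the epoch's harmonic frequencies up to
#' \code{maxHz} (default: the full band to Nyquist).
#'
#' @param S samples per column.
#' @param m number of columns.
#' @param slope spectral exponent.
#' @param fs sampling rate in Hz (only needed when \code{maxHz} is set).
#' @param maxHz upper band edge of the 1/f model.
#' @return an S x m numeric matrix.
#' @export
pinkNoiseMatrix <- function(S, m, slope = 1, fs = S, maxHz = fs / 2) {
  if (m == 0L) return(matrix(0, S, 0))
  B <- .pinkBasis(S, fs, slope, maxHz)
  B %*% matrix(stats::rnorm(ncol(B) * m), ncol(B))
}

# anterior weighting for blink topography
.blinkWeights <- function(montage, channels) {
  y <- montage@pos[channels, "y"]
  z <- montage@pos[channels, "z"]
  w <- pmax(y, 0)^2 * pmax(z + 0.2, 0)
  if (max(w) > 0) w / max(w) else w
}

# Fourier basis for unit-variance band-limited 1/f noise: columns are
# cosine/sine pairs at the epoch's harmonic frequencies up to maxHz,
# scaled so that (basis %*% standard-normal matrix) has unit sample
# variance and power ~ f^-slope. Synthesizing through the basis (one BLAS
# multiply) is much cheaper than per-column FFTs and is exact for the
# band-limited model.
.pinkBasis <- function(S, fs, slope, maxHz) {
  f1 <- fs / S                             # fundamental of the epoch
  K <- max(1L, min(floor(maxHz / f1), (S - 1L) %/% 2L))
  k <- seq_len(K)
  c2 <- k^(-slope)
  c2 <- c2 / sum(c2)
  ang <- outer(seq_len(S) - 1L, k) * (2 * pi / S)
  B <- cbind(cos(ang), sin(ang))
  B * rep(sqrt(c2), 2L)[col(B)]
}

# background-activity array (epochs x channels x samples)
.noiseArray <- function(e, channels, times, fs, spec, montage) {
  C <- length(channels)
  S <- length(times)
  sdOwn <- spec$pinkSd * sqrt(1 - spec$spatialShared)
  sdShared <- spec$pinkSd * sqrt(spec$spatialShared)
  N <- if (spec$noiseSd > 0)
    matrix(stats::rnorm(S * C * e, sd = spec$noiseSd), S, C * e)
  else matrix(0, S, C * e)
  if (sdOwn > 0 || sdShared > 0)
    B <- .pinkBasis(S, fs, spec$pinkSlope, spec$pinkMaxHz)
  if (sdOwn > 0) {
    Z <- matrix(stats::rnorm(ncol(B) * C * e), ncol(B))
    N <- N + sdOwn * (B %*% Z)
  }
  epIdx <- rep(seq_len(e), each = C)
  if (sdShared > 0) {
    Zs <- matrix(stats::rnorm(ncol(B) * e), ncol(B))
    N <- N + (sdShared * (B %*% Zs))[, epIdx, drop = FALSE]
  }
  if (spec$lineAmp > 0) {
    ampCh <- spec$lineAmp * stats::runif(C, 0.5, 1.5)
    phase <- stats::runif(e, 0, 2 * pi)
    carrier <- sin(outer(times / 1000 * 2 * pi * spec$lineFreq, phase, "+"))
    N <- N + carrier[, epIdx, drop = FALSE] *
      rep(rep(ampCh, e), each = S)
  }
  arr <- aperm(array(N, c(S, C, e)), c(3L, 2L, 1L))
  dimnames(arr) <- list(NULL, channels, NULL)
  if (spec$blinkRate > 0 && spec$blinkAmp > 0) {
    w <- .blinkWeights(montage, channels)
    nBlink <- stats::rpois(e, spec$blinkRate)
    for (ep in which(nBlink > 0)) {
      for (b in seq_len(nBlink[ep])) {
        ctr <- stats::runif(1, min(times) + 150, max(times) - 150)
        wave <- raisedCosine(times, c(ctr - 200, ctr + 200))
        wave <- wave / max(wave) * spec$blinkAmp
        arr[ep, , ] <- arr[ep, , ] + outer(w, wave)
      }
    }
  }
  arr
}

# add outer(amp_by_epoch, wave) to a set of channels
.injectBump <- function(arr, channels, amp, wave) {
  hit <- which(amp != 0)
  if (!length(hit) || !length(channels)) return(arr)
  add <- outer(amp[hit], wave)            # hit x S
  nc <- length(channels)
  arr[hit, channels, ] <- arr[hit, channels, , drop = FALSE] +
    aperm(array(add, c(length(hit), length(wave), nc)), c(1L, 3L, 2L))
  arr
}

#' Synthesize cue-locked and feedback-locked epochs for one session
#'
#' Per trial, one epoch aligned to the choice-cue pair and one to the
#' feedback screen, both spanning \code{span} (default -400..800 ms)
#' at sampling rate \code{fs}. Feedback epochs carry the frontal
#' reward-positivity bump (gain trials only, so the gain-minus-loss
#' difference equals the group's \code{rewpDiffByGroup} entry) and the
#' centro-parietal P300 bump with amplitude \code{p300ByCell} of the
#' trial's (feedback, next-trial strategy) cell. Cue epochs carry the
#' occipital deflection \code{n2pc} on channels contralateral to the
#' chosen side and \code{n2pcWinner} contralateral to the set-winner side.
#' Background noise is added per the [effectSpec()] noise model.
#'
#' @param session a [SubjectSession-class].
#' @param spec an [effectSpec()].
#' @param montage a [Montage-class]; only its channels are synthesized.
#' @param fs sampling rate in Hz (>= 250 so the component windows are
#'   resolved).
#' @param seed integer seed; same seed, same epochs.
#' @param span epoch span in ms relative to the event.
#' @param which \code{"both"} (default), or only \code{"cue"} /
#'   \code{"feedback"} — restricting synthesis to the epoch set a study
#'   needs halves the cost without changing the other set's content.
#' @return list with elements \code{cue} and \code{feedback}
#'   ([EpochSet-class]; \code{NULL} if not requested) and
#'   \code{badChannels} (ground-truth faulty channels, possibly empty).
#' @export
synthesizeEpochs <- function(session, spec, montage, fs = 1000,
                             seed = NULL, span = c(-400, 800),
                             which = c("both", "cue", "feedback")) {
  which <- match.arg(which)
  stopifnot(is(session, "SubjectSession"), inherits(spec, "EffectSpec"),
            is(montage, "Montage"))
  if (fs < 250) stop("fs must be >= 250 Hz to resolve the component windows")
  win <- erpWindows()
  # Kinderman-Ramage: exact Gaussian, ~25% faster than inversion at the
  # draw volumes epoch synthesis needs
  runWithSeed(seed, normalKind = "Kinderman-Ramage", expr = {
    tr <- session@trials
    e <- nrow(tr)
    channels <- montage@channels
    S <- round(diff(span) * fs / 1000)
    times <- span[1] + (seq_len(S) - 1) * 1000 / fs

    group <- session@agent$group
    if (is.null(group)) group <- "all"

    winnerSide <- ifelse(tr$left_stimulus == tr$set_winner, "left", "right")
    stratNext <- ifelse(tr$strategy_next == "none", "none",
                        ifelse(tr$strategy_next %in% c("win-stay", "lose-stay"),
                               "stay", "shift"))
    info <- data.frame(
      subject = session@subject, block = tr$block, trial = tr$trial,
      set_winner = tr$set_winner, choice = tr$choice,
      chosen_side = tr$chosen_side, winner_side = winnerSide,
      feedback = tr$feedback, strategy_next = tr$strategy_next,
      strat_next = stratNext, group = group,
      stringsAsFactors = FALSE)

    badCh <- character(0)
    if (spec$nBadChannels > 0) {
      eligible <- setdiff(channels,
                          c(unlist(montage@rois), montage@mastoids))
      badCh <- sample(eligible, min(spec$nBadChannels, length(eligible)))
    }

    applyBadChannels <- function(arr) {
      if (!length(badCh)) return(arr)
      flat <- badCh[seq_along(badCh) %% 2L == 1L]
      for (ch in flat) arr[, ch, ] <- 0
      for (ch in setdiff(badCh, flat))
        arr[, ch, ] <- arr[, ch, ] +
          stats::rnorm(e * S, sd = 10 * max(spec$noiseSd, 5))
      arr
    }

    fbSet <- NULL
    if (which %in% c("both", "feedback")) {
      rewpDiff <- spec$rewpDiffByGroup[group]
      if (is.na(rewpDiff)) {
        if (length(spec$rewpDiffByGroup) == 1L)
          rewpDiff <- unname(spec$rewpDiffByGroup[1L])
        else stop("no rewpDiffByGroup entry for group '", group, "'")
      }
      fb <- .noiseArray(e, channels, times, fs, spec, montage)
      wR <- raisedCosine(times, win$rewp)
      ampRewp <- ifelse(tr$feedback == "gain", rewpDiff, 0)
      fb <- .injectBump(fb, intersect(montage@rois$frontal, channels),
                        ampRewp, wR)
      wP <- raisedCosine(times, win$p300)
      cell <- paste(tr$feedback, stratNext, sep = "_")
      ampP <- ifelse(stratNext == "none", 0, spec$p300ByCell[cell])
      fb <- .injectBump(fb,
                        intersect(montage@rois$centroparietal, channels),
                        ampP, wP)
      fbSet <- new("EpochSet", data = applyBadChannels(fb), fs = fs,
                   t0 = span[1], eventKind = "feedback", info = info)
    }

    cueSet <- NULL
    if (which %in% c("both", "cue")) {
      cue <- .noiseArray(e, channels, times, fs, spec, montage)
      wN <- raisedCosine(times, win$n2pc)
      ampLeftChans <- spec$n2pc * (tr$chosen_side == "right") +
        spec$n2pcWinner * (winnerSide == "right")
      ampRightChans <- spec$n2pc * (tr$chosen_side == "left") +
        spec$n2pcWinner * (winnerSide == "left")
      cue <- .injectBump(cue,
                         intersect(montage@rois$occipital_left, channels),
                         ampLeftChans, wN)
      cue <- .injectBump(cue,
                         intersect(montage@rois$occipital_right, channels),
                         ampRightChans, wN)
      cueSet <- new("EpochSet", data = applyBadChannels(cue), fs = fs,
                    t0 = span[1], eventKind = "cue_pair", info = info)
    }

    list(cue = cueSet, feedback = fbSet, badChannels = badCh)
  })
}

#' Inject deterministic artifacts into epochs
#'
#' Fixture generator for the trial-by-trial rejection stage: applies a
#' hand-specified artifact plan so the expected kept / interpolated /
#' rejected outcomes are enumerable. Kinds:
#' \describe{
#'   \item{spike}{alternating +A/2, -A/2 deflection lasting 100 ms from
#'     \code{onset_ms}, i.e. peak-to-peak amplitude A within any 200 ms
#'     window covering it.}
#'   \item{offset}{constant A added to the whole epoch.}
#'   \item{flat}{the channel is replaced by a constant 0.}
#' }
#' An empty plan returns the epochs unchanged.
#'
#' @param epochs an [EpochSet-class].
#' @param plan data.frame with columns \code{epoch}, \code{channel},
#'   \code{kind}, \code{amplitude} and optionally \code{onset_ms}.
#' @return the modified [EpochSet-class].
#' @export
injectArtifacts <- function(epochs, plan) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(plan) || nrow(plan) == 0L) return(epochs)
  need <- c("epoch", "channel", "kind", "amplitude")
  if (!all(need %in% names(plan)))
    stop("plan needs columns: ", paste(need, collapse = ", "))
  if (is.null(plan$onset_ms)) plan$onset_ms <- 0
  times <- sampleTimes(epochs)
  dat <- epochs@data
  for (i in seq_len(nrow(plan))) {
    ep <- plan$epoch[i]
    ch <- plan$channel[i]
    if (ep < 1 || ep > nEpochs(epochs)) stop("plan epoch out of range: ", ep)
    if (!ch %in% channelNames(epochs)) stop("plan channel unknown: ", ch)
    kind <- plan$kind[i]
    A <- plan$amplitude[i]
    if (kind == "spike") {
      idx <- windowIndices(times, plan$onset_ms[i] + c(0, 100))
      dat[ep, ch, idx] <- dat[ep, ch, idx] +
        A / 2 * (-1)^(seq_along(idx))
    } else if (kind == "offset") {
      dat[ep, ch, ] <- dat[ep, ch, ] + A
    } else if (kind == "flat") {
      dat[ep, ch, ] <- 0
    } else stop("unknown artifact kind: ", kind)
  }
  epochs@data <- dat
  epochs
}
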