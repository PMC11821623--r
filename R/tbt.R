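# Trial-by-trial (per-epoch) artifact handling: flag channels per epoch by
# three criteria, interpolate small channel sets within the epoch only,
# reject epochs with widespread artifacts.

# rolling peak-to-peak: TRUE where any 200 ms window sliding in 20 ms steps
# exceeds the limit; computed on 20 ms chunk extrema for speed
.p2pFlags <- function(X, fs, limit, winMs, stepMs) {
  # X: rows = traces, cols = samples
  st <- max(1L, round(stepMs * fs / 1000))
  w <- max(1L, round(winMs * fs / 1000))
  nchunk <- ncol(X) %/% st
  perWin <- max(1L, w %/% st)
  cmax <- cmin <- matrix(0, nrow(X), nchunk)
  for (j in seq_len(nchunk)) {
    blk <- X[, (j - 1L) * st + seq_len(st), drop = FALSE]
    cmax[, j] <- do.call(pmax, asplit(blk, 2L))
    cmin[, j] <- do.call(pmin, asplit(blk, 2L))
  }
  nwin <- nchunk - perWin + 1L
  if (nwin < 1L) {
    nwin <- 1L
    perWin <- nchunk
  }
  flag <- rep(FALSE, nrow(X))
  for (s in seq_len(nwin)) {
    wmax <- do.call(pmax, asplit(cmax[, s + seq_len(perWin) - 1L,
                                      drop = FALSE], 2L))
    wmin <- do.call(pmin, asplit(cmin[, s + seq_len(perWin) - 1L,
                                      drop = FALSE], 2L))
    flag <- flag | (wmax - wmin > limit)
  }
  flag
}

#' Trial-by-trial artifact rejection
#'
#' Flags, per epoch, every channel meeting any of:
#' \enumerate{
#'   \item peak-to-peak amplitude above \code{p2pLimit} within 200 ms
#'     windows sliding across the epoch in 20 ms steps;
#'   \item absolute voltage below \code{-absLimit} or above
#'     \code{+absLimit};
#'   \item improbable activity: z-score of the channel's epoch
#'     log-variance above \code{jointZ}, against the same channel's
#'     distribution over epochs (local) or against all channels and
#'     epochs (global).
#' }
#' An epoch with at least \code{rejectAt} flagged channels is rejected;
#' an epoch with 1 to \code{rejectAt - 1} flagged channels is kept and the
#' flagged channels are replaced by spherical-spline interpolation from
#' the remaining channels, for that epoch only.
#'
#' @param epochs a baseline-corrected [EpochSet-class].
#' @param montage a [Montage-class] (positions for interpolation).
#' @param p2pLimit peak-to-peak limit, microvolts (default 100).
#' @param p2pWindow,p2pStep sliding-window length and step, ms.
#' @param absLimit absolute-voltage limit, microvolts (default 150).
#' @param jointZ improbability threshold in standard deviations (default 3).
#' @param rejectAt flagged-channel count at which the epoch is rejected
#'   (default 10).
#' @return list with \code{epochs} (the cleaned [EpochSet-class], rejected
#'   epochs removed) and \code{report} (a [CleaningReport-class]).
#' @export
rejectEpochsTBT <- function(epochs, montage, p2pLimit = 100,
                            p2pWindow = 200, p2pStep = 20,
                            absLimit = 150, jointZ = 3, rejectAt = 10L) {
  stopifnot(is(epochs, "EpochSet"))
  e <- nEpochs(epochs)
  C <- nChannels(epochs)
  S <- nSamples(epochs)
  ch <- channelNames(epochs)
  X <- matrix(epochs@data, nrow = e * C)     # rows ordered (epoch, channel)

  fP2p <- .p2pFlags(X, epochs@fs, p2pLimit, p2pWindow, p2pStep)
  mx <- do.call(pmax, asplit(X, 2L))
  mn <- do.call(pmin, asplit(X, 2L))
  fAbs <- mx > absLimit | mn < -absLimit

  lv <- log(pmax(rowMeans(X^2) - rowMeans(X)^2, 1e-30))
  LV <- matrix(lv, e, C)
  zLocal <- scale(LV)                         # per channel, across epochs
  zGlobal <- (LV - mean(LV)) / stats::sd(LV)
  zLocal[!is.finite(zLocal)] <- 0
  zGlobal[!is.finite(zGlobal)] <- 0
  fJp <- as.vector(zLocal > jointZ) | as.vector(zGlobal > jointZ)

  crit <- matrix("", e * C, 3)
  crit[fP2p, 1] <- "peak-to-peak"
  crit[fAbs, 2] <- "absolute-voltage"
  crit[fJp, 3] <- "joint-probability"
  anyFlag <- matrix(fP2p | fAbs | fJp, e, C)

  nFlagged <- rowSums(anyFlag)
  outcome <- ifelse(nFlagged >= rejectAt, "rejected",
                    ifelse(nFlagged > 0, "kept-with-interpolation", "kept"))
  flagged <- lapply(seq_len(e), function(ep) {
    idx <- which(anyFlag[ep, ])
    if (!length(idx))
      return(data.frame(channel = character(0), criterion = character(0)))
    rows <- (idx - 1L) * e + ep
    reason <- apply(crit[rows, , drop = FALSE], 1L, function(r)
      paste(r[nzchar(r)], collapse = "+"))
    data.frame(channel = ch[idx], criterion = reason,
               stringsAsFactors = FALSE)
  })

  keep <- which(outcome != "rejected")
  cleaned <- epochs[keep, ]
  for (ep in keep[nFlagged[keep] > 0]) {
    bad <- ch[anyFlag[ep, ]]
    one <- interpolateSpherical(epochs[ep, ], bad, montage)
    cleaned@data[match(ep, keep), , ] <- one@data[1L, , ]
  }

  report <- new("CleaningReport",
                epochs = data.frame(epoch = seq_len(e), outcome = outcome,
                                    n_flagged = nFlagged),
                flagged = flagged,
                badChannels = data.frame(channel = character(0),
                                         criterion = character(0)))
  list(epochs = cleaned, report = report)
}
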