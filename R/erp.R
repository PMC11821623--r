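# Condition binning and ERP measurement.

#' Average epochs into condition bins
#'
#' Splits the epochs by the metadata columns in \code{by} (e.g.
#' \code{"feedback"}, \code{c("feedback", "strat_next")},
#' \code{"chosen_side"}) and returns the arithmetic mean ERP per bin.
#' Bin labels join the cell values with \code{"&"}; counts are attached
#' as the \code{"counts"} attribute and always sum to the number of
#' epochs. Empty cells of the factor crossing are dropped with a message.
#'
#' @param epochs an [EpochSet-class].
#' @param by metadata column names to bin on.
#' @return named list of [Erp-class], with a \code{"counts"} attribute.
#' @export
binAverage <- function(epochs, by) {
  info <- epochInfo(epochs)
  miss <- setdiff(by, names(info))
  if (length(miss)) stop("unknown metadata column(s): ",
                         paste(miss, collapse = ", "))
  key <- interaction(info[by], sep = "&", drop = FALSE)
  counts <- table(key)
  if (any(counts == 0))
    message("empty bin(s) dropped: ",
            paste(names(counts)[counts == 0], collapse = ", "))
  ch <- channelNames(epochs)
  out <- list()
  for (lev in names(counts)[counts > 0]) {
    idx <- which(key == lev)
    m <- colMeans(matrix(epochs@data[idx, , , drop = FALSE],
                         nrow = length(idx)))
    m <- matrix(m, nChannels(epochs), nSamples(epochs),
                dimnames = list(ch, NULL))
    out[[lev]] <- new("Erp", data = m, fs = epochs@fs, t0 = epochs@t0,
                      n = length(idx), label = lev)
  }
  attr(out, "counts") <- counts[counts > 0]
  out
}

#' Pointwise difference wave
#'
#' \code{a - b} on matching channels and time base (e.g. the gain-minus-
#' loss reward-positivity difference).
#'
#' @param a,b [Erp-class] objects on the same channels and time base.
#' @return an [Erp-class]; \code{n} is the smaller of the two bin counts.
#' @export
differenceWave <- function(a, b) {
  stopifnot(is(a, "Erp"), is(b, "Erp"))
  if (!identical(rownames(a@data), rownames(b@data)))
    stop("channel sets differ")
  if (a@fs != b@fs || a@t0 != b@t0 || ncol(a@data) != ncol(b@data))
    stop("time bases differ")
  new("Erp", data = a@data - b@data, fs = a@fs, t0 = a@t0,
      n = min(a@n, b@n), label = paste(a@label, "-", b@label))
}

#' Mean amplitude over an ROI and time window
#'
#' Mean over the ROI channels and the window samples; the window is
#' closed-open \code{[t0, t1)} on the sample grid.
#'
#' @param erp an [Erp-class].
#' @param roi channel names, or the name of a catalogued ROI if
#'   \code{montage} is given.
#' @param window time window in ms.
#' @param montage optional [Montage-class] to resolve an ROI name.
#' @return mean amplitude in microvolts.
#' @export
roiWindowMean <- function(erp, roi, window, montage = NULL) {
  stopifnot(is(erp, "Erp"))
  if (!is.null(montage) && length(roi) == 1L && roi %in% names(montage@rois))
    roi <- roiChannels(montage, roi)
  miss <- setdiff(roi, rownames(erp@data))
  if (length(miss)) stop("ROI channel(s) absent: ",
                         paste(miss, collapse = ", "))
  times <- sampleTimes(erp)
  if (window[1] < times[1] - 1e-9 ||
      window[2] > times[length(times)] + 1000 / erp@fs + 1e-9)
    stop("window lies outside the epoch span")
  idx <- windowIndices(times, window)
  if (!length(idx)) stop("window contains no samples")
  mean(erp@data[roi, idx])
}

#' Contralateral-minus-ipsilateral (N2pc) waveform
#'
#' Given the ERPs of epochs binned by the side of a reference stimulus
#' (the to-be-chosen stimulus, or the set winner), computes for each
#' left/right homologue ROI pair the contralateral-minus-ipsilateral
#' difference and collapses over the two presentation sides and the
#' pairs:
#' \deqn{N2pc(t) = [ (R_{ch} - L_{ch})_{ref left} +
#'                   (L_{ch} - R_{ch})_{ref right} ] / 2}
#' A field mirror-symmetric across the midline gives identically zero;
#' swapping the two input ERPs flips the sign.
#'
#' @param erpLeft [Erp-class] for reference-stimulus-left epochs.
#' @param erpRight [Erp-class] for reference-stimulus-right epochs.
#' @param montage a [Montage-class]; its \code{occipital_left} /
#'   \code{occipital_right} ROIs define the homologue pairs unless
#'   \code{pairs} is given.
#' @param window measurement window in ms (default 175--225).
#' @param pairs optional two-column matrix of (left, right) channel pairs.
#' @return list with \code{wave} (numeric vector), \code{mean} (window
#'   mean, microvolts), \code{times} (ms), \code{window}.
#' @export
contraIpsi <- function(erpLeft, erpRight, montage, window = c(175, 225),
                       pairs = NULL) {
  stopifnot(is(erpLeft, "Erp"), is(erpRight, "Erp"))
  if (is.null(pairs)) {
    L <- roiChannels(montage, "occipital_left")
    R <- roiChannels(montage, "occipital_right")
    if (length(L) != length(R)) stop("unpaired occipital ROI channels")
    pairs <- cbind(L, R)
  }
  need <- as.vector(pairs)
  for (e in list(erpLeft, erpRight)) {
    miss <- setdiff(need, rownames(e@data))
    if (length(miss)) stop("unpaired/missing ROI channel(s): ",
                           paste(miss, collapse = ", "))
  }
  # reference left: contralateral = right-hemisphere channels
  dL <- erpLeft@data[pairs[, 2], , drop = FALSE] -
    erpLeft@data[pairs[, 1], , drop = FALSE]
  dR <- erpRight@data[pairs[, 1], , drop = FALSE] -
    erpRight@data[pairs[, 2], , drop = FALSE]
  wave <- (colMeans(dL) + colMeans(dR)) / 2
  times <- sampleTimes(erpLeft)
  idx <- windowIndices(times, window)
  list(wave = wave, mean = mean(wave[idx]), times = times, window = window)
}

#' Standard measurement table for one subject
#'
#' Applies the canonical bins and ROI/window means to one subject's cue-
#' and feedback-locked epochs: gain/loss frontal means and their
#' difference (reward positivity, 275--375 ms), centro-parietal means of
#' the four feedback-by-next-strategy cells (P300, 400--600 ms), and the
#' contra-minus-ipsi occipital window mean referenced to the chosen side
#' and to the set-winner side (N2pc, default 175--225 ms).
#'
#' @param cue,feedback the subject's [EpochSet-class] pair.
#' @param montage a [Montage-class].
#' @param n2pcWindow N2pc window in ms; the measurement stage also accepts
#'   the wider 175--275 ms variant.
#' @return one-row data.frame of measures (microvolts) and bin counts.
#' @export
subjectErpMeasures <- function(cue, feedback, montage,
                               n2pcWindow = c(175, 225)) {
  win <- erpWindows()
  fb <- binAverage(feedback, "feedback")
  rewpGain <- roiWindowMean(fb[["gain"]], "frontal", win$rewp, montage)
  rewpLoss <- roiWindowMean(fb[["loss"]], "frontal", win$rewp, montage)

  ok <- epochInfo(feedback)$strat_next != "none"
  cells <- suppressMessages(binAverage(feedback[which(ok), ],
                                       c("feedback", "strat_next")))
  p300 <- vapply(c("gain&stay", "gain&shift", "loss&stay", "loss&shift"),
                 function(cell) {
                   if (is.null(cells[[cell]])) return(NA_real_)
                   roiWindowMean(cells[[cell]], "centroparietal",
                                 win$p300, montage)
                 }, 0)
  cnt <- attr(cells, "counts")

  bySide <- binAverage(cue, "chosen_side")
  n2pcChosen <- contraIpsi(bySide[["left"]], bySide[["right"]], montage,
                           n2pcWindow)$mean
  byWin <- binAverage(cue, "winner_side")
  n2pcWinner <- contraIpsi(byWin[["left"]], byWin[["right"]], montage,
                           n2pcWindow)$mean

  data.frame(
    subject = epochInfo(feedback)$subject[1],
    rewp_gain = rewpGain, rewp_loss = rewpLoss,
    rewp_diff = rewpGain - rewpLoss,
    p300_gain_stay = p300[["gain&stay"]],
    p300_gain_shift = p300[["gain&shift"]],
    p300_loss_stay = p300[["loss&stay"]],
    p300_loss_shift = p300[["loss&shift"]],
    n2pc_chosen = n2pcChosen, n2pc_winner = n2pcWinner,
    n_gain = fb[["gain"]]@n, n_loss = fb[["loss"]]@n,
    stringsAsFactors = FALSE)
}
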