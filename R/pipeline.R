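# Cleaning / preprocessing stages between raw epochs and per-bin ERPs.

# ---- filtering -------------------------------------------------------------

# IIR filter applied down the rows of an S x m matrix, vectorized over
# columns, with steady-state initial conditions: the filter starts as if
# each column had sat at its own mean forever. A constant input maps to
# its steady-state output exactly, and a high-pass with a time constant
# longer than the epoch behaves as mean removal rather than tracking the
# arbitrary first sample.
iirFilterMatrix <- function(b, a, X) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  S <- nrow(X)
  m <- ncol(X)
  dc <- sum(b) / sum(a)
  Y <- matrix(0, S, m)
  x1 <- colMeans(X)
  y1 <- dc * x1
  for (t in seq_len(S)) {
    acc <- b[1] * X[t, ]
    if (nb > 1) for (k in 2:nb) {
      acc <- acc + b[k] * (if (t >= k) X[t - k + 1, ] else x1)
    }
    if (na > 1) for (k in 2:na) {
      acc <- acc - a[k] * (if (t >= k) Y[t - k + 1, ] else y1)
    }
    Y[t, ] <- acc
  }
  Y
}

# zero-phase (forward-backward) filtering with mirror (even-reflection)
# padding: pad values are actual signal values, so the padded series keeps
# the epoch's mean and the steady-state initialization stays anchored
filtfiltMatrix <- function(b, a, X, pad = 100L) {
  S <- nrow(X)
  pad <- min(S - 1L, pad)
  top <- X[(pad + 1L):2L, , drop = FALSE]
  bot <- X[(S - 1L):(S - pad), , drop = FALSE]
  E <- rbind(top, X, bot)
  Y <- iirFilterMatrix(b, a, E)
  Y <- iirFilterMatrix(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(pad + 1L):(pad + S), , drop = FALSE]
}

.epochsAsMatrix <- function(epochs) {
  # samples x (channel, epoch) with channels varying fastest
  matrix(aperm(epochs@data, c(3L, 2L, 1L)), nrow = nSamples(epochs))
}

.matrixAsEpochs <- function(X, template, fs = NULL, t0 = NULL) {
  e <- nEpochs(template)
  C <- nChannels(template)
  arr <- aperm(array(X, c(nrow(X), C, e)), c(3L, 2L, 1L))
  dimnames(arr) <- list(NULL, channelNames(template), NULL)
  new("EpochSet", data = arr,
      fs = if (is.null(fs)) template@fs else fs,
      t0 = if (is.null(t0)) template@t0 else t0,
      eventKind = template@eventKind, info = template@info)
}

#' Band-pass filter epochs (Butterworth, zero-phase)
#'
#' Applies an order-\code{order} Butterworth high-pass at \code{low} Hz and
#' an order-\code{order} Butterworth low-pass at \code{high} Hz, each
#' forward and backward (zero-phase, so component latencies are not
#' shifted; the effective magnitude order doubles). Either edge may be
#' \code{NULL} to skip it.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high band edges in Hz.
#' @param order Butterworth order per edge (default 4).
#' @return the filtered [EpochSet-class].
#' @export
bandpassEpochs <- function(epochs, low = 0.1, high = 30, order = 4) {
  stopifnot(is(epochs, "EpochSet"))
  nyq <- epochs@fs / 2
  if (!is.null(high) && high >= nyq)
    stop("high edge must lie below the Nyquist frequency")
  if (!is.null(low) && (low <= 0 || low >= nyq))
    stop("low edge must lie in (0, Nyquist)")
  X <- .epochsAsMatrix(epochs)
  # high-pass first: its long time constant would otherwise smear the
  # low-pass's edge transients across short epochs
  if (!is.null(low)) {
    hp <- signal::butter(order, low / nyq, type = "high")
    X <- filtfiltMatrix(hp$b, hp$a, X)
  }
  if (!is.null(high)) {
    lp <- signal::butter(order, high / nyq, type = "low")
    X <- filtfiltMatrix(lp$b, lp$a, X)
  }
  .matrixAsEpochs(X, epochs)
}

#' Notch filter at the line frequency
#'
#' Second-order IIR notch (narrow band-stop Butterworth), zero-phase.
#'
#' @param epochs an [EpochSet-class].
#' @param freq notch centre in Hz.
#' @param width stop-band half-width in Hz.
#' @return the filtered [EpochSet-class].
#' @export
notchEpochs <- function(epochs, freq = 60, width = 2) {
  nyq <- epochs@fs / 2
  if (freq + width >= nyq) stop("notch band must lie below Nyquist")
  bs <- signal::butter(2, c(freq - width, freq + width) / nyq, type = "stop")
  X <- filtfiltMatrix(bs$b, bs$a, .epochsAsMatrix(epochs))
  .matrixAsEpochs(X, epochs)
}

# ---- resampling ------------------------------------------------------------

# FFT-domain resampling of the columns of an S x m matrix to S2 rows
fftResampleMatrix <- function(X, S2) {
  S <- nrow(X)
  Xf <- stats::mvfft(X)
  keep <- S2 %/% 2L
  Y <- matrix(0+0i, S2, ncol(X))
  Y[seq_len(keep + 1L), ] <- Xf[seq_len(keep + 1L), , drop = FALSE]
  if (keep > 1L)
    Y[(S2 - keep + 2L):S2, ] <- Xf[(S - keep + 2L):S, , drop = FALSE]
  if (S2 %% 2L == 0L)
    Y[keep + 1L, ] <- Re(Y[keep + 1L, ])
  Re(stats::mvfft(Y, inverse = TRUE)) / S
}

#' Resample epochs to a lower rate
#'
#' Anti-aliased resampling in the frequency domain (spectrum truncation,
#' the approach standard epoched-EEG toolchains use): exact for
#' band-limited content, duration preserved. Upsampling requests are an
#' error; \code{targetFs} equal to the current rate is the identity.
#'
#' @param epochs an [EpochSet-class].
#' @param targetFs target sampling rate in Hz (default 250).
#' @return the resampled [EpochSet-class].
#' @export
resampleEpochs <- function(epochs, targetFs = 250) {
  stopifnot(is(epochs, "EpochSet"))
  if (targetFs > epochs@fs) stop("upsampling not supported")
  if (targetFs == epochs@fs) return(epochs)
  S <- nSamples(epochs)
  S2 <- S * targetFs / epochs@fs
  if (abs(S2 - round(S2)) > 1e-9)
    stop("target rate must divide the epoch length into whole samples")
  X <- fftResampleMatrix(.epochsAsMatrix(epochs), as.integer(round(S2)))
  .matrixAsEpochs(X, epochs, fs = targetFs)
}

# ---- referencing, baseline, channel set ------------------------------------

#' Re-reference to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every channel,
#' per epoch and sample. Idempotent after the first application (the
#' mastoid mean becomes identically zero).
#'
#' @param epochs an [EpochSet-class] containing both mastoids.
#' @param montage a [Montage-class] naming the mastoid pair.
#' @return the re-referenced [EpochSet-class].
#' @export
rereferenceMastoids <- function(epochs, montage) {
  m <- mastoids(montage)
  if (!all(m %in% channelNames(epochs)))
    stop("mastoid channel(s) missing: ",
         paste(setdiff(m, channelNames(epochs)), collapse = ", "))
  ref <- (epochs@data[, m[1], , drop = FALSE] +
            epochs@data[, m[2], , drop = FALSE]) / 2
  e <- nEpochs(epochs)
  S <- nSamples(epochs)
  refArr <- aperm(array(ref, c(e, S, nChannels(epochs))), c(1L, 3L, 2L))
  epochs@data <- epochs@data - refArr
  epochs
}

#' Drop the outer-ring channels
#'
#' Removes the montage's designated outer-ring channels (the ring most
#' prone to poor sensor contact in paediatric recordings) from the epochs.
#' Applying it twice equals applying it once.
#'
#' @param epochs an [EpochSet-class].
#' @param montage a [Montage-class].
#' @return the reduced [EpochSet-class].
#' @export
removeOuterRing <- function(epochs, montage) {
  drop <- intersect(outerRing(montage), channelNames(epochs))
  if (!length(drop)) return(epochs)
  keep <- setdiff(channelNames(epochs), drop)
  epochs[, keep]
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (closed-open, default -200..0 ms); the baseline-window mean of the
#' result is zero to machine precision.
#'
#' @param epochs an [EpochSet-class].
#' @param window baseline window in ms.
#' @return the corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, window = c(-200, 0)) {
  idx <- windowIndices(sampleTimes(epochs), window)
  if (!length(idx)) stop("baseline window contains no samples")
  B <- rowMeans(epochs@data[, , idx, drop = FALSE], dims = 2L)
  epochs@data <- epochs@data - as.vector(B)
  epochs
}

#' Extract epochs from a continuous record
#'
#' Cuts epochs spanning \code{span} ms around each event from a continuous
#' channels-x-samples record and baseline-corrects them. Events whose
#' epoch would run past the record edges are skipped and reported in the
#' \code{"skipped"} attribute (and a message).
#'
#' @param record numeric matrix, channels x samples, with channel row names.
#' @param fs sampling rate of the record in Hz.
#' @param events event onsets, in samples (1-based).
#' @param span epoch span in ms around each event.
#' @param baseline baseline window in ms, or \code{NULL} to skip.
#' @param eventKind stored on the result.
#' @param info optional data.frame, one row per event.
#' @return an [EpochSet-class]; skipped event indices in
#'   \code{attr(, "skipped")}.
#' @export
extractEpochs <- function(record, fs, events, span = c(-400, 800),
                          baseline = c(-200, 0), eventKind = "generic",
                          info = NULL) {
  stopifnot(is.matrix(record), !is.null(rownames(record)))
  S <- round(diff(span) * fs / 1000)
  rel <- round(span[1] * fs / 1000) + seq_len(S) - 1L
  ok <- vapply(events, function(ev)
    ev + rel[1] >= 1L && ev + rel[S] <= ncol(record), TRUE)
  if (any(!ok))
    message(sum(!ok), " event(s) too close to the record edge; skipped")
  keep <- which(ok)
  arr <- array(0, c(length(keep), nrow(record), S),
               dimnames = list(NULL, rownames(record), NULL))
  for (i in seq_along(keep))
    arr[i, , ] <- record[, events[keep[i]] + rel]
  if (is.null(info)) info <- data.frame(event = events)
  out <- new("EpochSet", data = arr, fs = fs, t0 = span[1],
             eventKind = eventKind,
             info = info[keep, , drop = FALSE])
  if (!is.null(baseline)) out <- baselineCorrect(out, baseline)
  attr(out, "skipped") <- which(!ok)
  out
}

# ---- bad-channel detection -------------------------------------------------

#' Detect bad channels
#'
#' Evaluates three independent criteria on the record (epochs are viewed
#' concatenated):
#' \enumerate{
#'   \item \strong{flat}: the channel is constant for more than
#'     \code{flatSeconds} contiguous seconds;
#'   \item \strong{line-noise}: the channel's line-frequency power
#'     relative to the rest of its spectrum is more than \code{lineZ}
#'     (robust) standard deviations above the montage-wide typical ratio;
#'   \item \strong{low-correlation}: the channel correlates at less than
#'     \code{corrThreshold} with the mean of its \code{k} nearest
#'     neighbours.
#' }
#' The union is reported with one row per (channel, criterion).
#'
#' @param epochs an [EpochSet-class].
#' @param montage a [Montage-class] (for neighbourhoods).
#' @param flatSeconds,lineZ,corrThreshold,k criterion parameters.
#' @param lineFreq line frequency in Hz.
#' @return data.frame with columns \code{channel}, \code{criterion}.
#' @export
detectBadChannels <- function(epochs, montage, flatSeconds = 5,
                              lineZ = 4, corrThreshold = 0.8, k = 8,
                              lineFreq = 60) {
  stopifnot(is(epochs, "EpochSet"))
  ch <- channelNames(epochs)
  X <- t(matrix(aperm(epochs@data, c(3L, 1L, 2L)),
                ncol = length(ch)))          # channels x (samples*epochs)
  rownames(X) <- ch
  n <- ncol(X)
  fs <- epochs@fs
  out <- list()

  runLen <- apply(X, 1L, function(x) {
    d <- abs(diff(x)) < 1e-9
    if (!any(d)) return(0L)
    r <- rle(d)
    max(r$lengths[r$values]) + 1L
  })
  flat <- ch[runLen / fs > flatSeconds]
  if (length(flat))
    out$flat <- data.frame(channel = flat, criterion = "flat")

  if (lineFreq < fs / 2) {
    P <- abs(stats::mvfft(t(X)))^2
    fr <- (seq_len(n) - 1L) * fs / n
    half <- fr <= fs / 2
    band <- half & abs(fr - lineFreq) <= 1
    rest <- half & !band & fr > 0
    ratio <- colSums(P[band, , drop = FALSE]) /
      colSums(P[rest, , drop = FALSE])
    # robust z so a single contaminated channel cannot mask itself by
    # inflating the spread estimate; silent channels give NaN ratios and
    # are left to the flat criterion
    z <- (ratio - stats::median(ratio, na.rm = TRUE)) /
      (stats::mad(ratio, na.rm = TRUE) + 1e-12)
    ln <- ch[is.finite(z) & z > lineZ]
    if (length(ln))
      out$line <- data.frame(channel = ln, criterion = "line-noise")
  }

  nb <- channelNeighbors(subsetMontage(montage, ch), k = k, channels = ch)
  lowc <- ch[vapply(ch, function(cc) {
    nbm <- colMeans(X[nb[[cc]], , drop = FALSE])
    sx <- stats::sd(X[cc, ])
    if (sx == 0 || stats::sd(nbm) == 0) return(TRUE)  # degenerate: flat
    stats::cor(X[cc, ], nbm) < corrThreshold
  }, TRUE)]
  if (length(lowc))
    out$corr <- data.frame(channel = lowc, criterion = "low-correlation")

  if (!length(out))
    return(data.frame(channel = character(0), criterion = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
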