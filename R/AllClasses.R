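#' @import methods
NULL

#' Sensor montage for a geodesic-style EEG net
#'
#' A \code{Montage} holds named channels with 3-D unit-sphere positions,
#' the set of outer-ring channels (removed early in the cleaning path),
#' a catalog of regions of interest (ROIs), the left/right homologue
#' pairing used for lateralized (contra-minus-ipsi) analyses, and the
#' mastoid reference pair.
#'
#' @slot channels character vector of channel names.
#' @slot pos numeric matrix (channels x 3) of unit-sphere positions;
#'   x = right, y = anterior, z = superior.
#' @slot outerRing channels forming the outermost ring of the net.
#' @slot rois named list of character vectors, each an ROI.
#' @slot pairs two-column character matrix of left/right homologue pairs.
#' @slot mastoids character vector of length two, the mastoid pair.
#' @slot midline channels lying on the sagittal midline.
#'
#' @seealso [hydrocelMontage()], [subsetMontage()]
#' @export
setClass("Montage",
  representation(
    channels = "character",
    pos = "matrix",
    outerRing = "character",
    rois = "list",
    pairs = "matrix",
    mastoids = "character",
    midline = "character"
  )
)

setValidity("Montage", function(object) {
  msg <- NULL
  ch <- object@channels
  if (anyDuplicated(ch)) msg <- c(msg, "duplicated channel names")
  if (nrow(object@pos) != length(ch) ||
      !identical(rownames(object@pos), ch))
    msg <- c(msg, "pos must have one named row per channel")
  if (!all(object@outerRing %in% ch))
    msg <- c(msg, "outer-ring channels absent from channel set")
  roiCh <- unlist(object@rois, use.names = FALSE)
  if (!all(roiCh %in% ch))
    msg <- c(msg, "ROI members absent from channel set")
  if (length(intersect(roiCh, object@outerRing)))
    msg <- c(msg, "ROI channels must not lie on the outer ring")
  if (ncol(object@pairs) != 2)
    msg <- c(msg, "pairs must have two columns (left, right)")
  if (!all(object@pairs %in% ch))
    msg <- c(msg, "paired channels absent from channel set")
  if (!length(object@mastoids) %in% c(0L, 2L) ||
      !all(object@mastoids %in% ch))
    msg <- c(msg, "mastoids must name two present channels (or none, for reference-free subsets)")
  if (is.null(msg)) TRUE else msg
})

#' Epoched multichannel EEG
#'
#' An \code{EpochSet} stores a numeric array of epochs x channels x samples
#' (microvolts), the sampling rate, the time of the first sample relative
#' to the alignment event, the event kind (choice-cue pair or feedback
#' screen), and one row of metadata per epoch (subject, trial link,
#' condition labels).
#'
#' @slot data numeric array, epochs x channels x samples; channel names on
#'   the second dimension.
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in ms relative to event onset
#'   (negative = pre-event).
#' @slot eventKind \code{"cue_pair"} or \code{"feedback"}.
#' @slot info data.frame with one row per epoch.
#'
#' @seealso [synthesizeEpochs()], [extractEpochs()]
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    fs = "numeric",
    t0 = "numeric",
    eventKind = "character",
    info = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "data must be epochs x channels x samples")
  if (length(object@fs) != 1 || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (length(d) == 3 && nrow(object@info) != d[1])
    msg <- c(msg, "info must have one row per epoch")
  if (length(d) == 3 && is.null(dimnames(object@data)[[2]]))
    msg <- c(msg, "channel names required on dim 2")
  if (!object@eventKind %in% c("cue_pair", "feedback", "generic"))
    msg <- c(msg, "eventKind must be cue_pair, feedback or generic")
  if (is.null(msg)) TRUE else msg
})

#' Averaged event-related potential
#'
#' An \code{Erp} is the average over the epochs of one condition bin:
#' a channels x samples matrix plus its time base and the number of
#' epochs averaged.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot t0 time of first sample in ms relative to event onset.
#' @slot n number of epochs averaged.
#' @slot label bin label.
#' @export
setClass("Erp",
  representation(
    data = "matrix",
    fs = "numeric",
    t0 = "numeric",
    n = "numeric",
    label = "character"
  )
)

setValidity("Erp", function(object) {
  msg <- NULL
  if (is.null(rownames(object@data))) msg <- c(msg, "channel names required")
  if (object@n < 0) msg <- c(msg, "n must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Report from the trial-by-trial cleaning stage
#'
#' Records, per epoch, whether it was kept, kept with per-epoch channel
#' interpolation, or rejected; which channels triggered which criterion;
#' and any record-level bad channels with the criterion that flagged them.
#'
#' @slot epochs data.frame with columns \code{epoch}, \code{outcome}
#'   (\code{kept}, \code{kept-with-interpolation}, \code{rejected}) and
#'   \code{n_flagged}.
#' @slot flagged list (one element per epoch) of data.frames with columns
#'   \code{channel} and \code{criterion}.
#' @slot badChannels data.frame with columns \code{channel} and
#'   \code{criterion} (\code{flat}, \code{line-noise}, \code{low-correlation}).
#' @export
setClass("CleaningReport",
  representation(
    epochs = "data.frame",
    flagged = "list",
    badChannels = "data.frame"
  )
)

setValidity("CleaningReport", function(object) {
  msg <- NULL
  if (nrow(object@epochs) != length(object@flagged))
    msg <- c(msg, "flagged must have one element per epoch row")
  ok <- object@epochs$outcome %in% c("kept", "kept-with-interpolation", "rejected")
  if (!all(ok)) msg <- c(msg, "invalid epoch outcome")
  if (is.null(msg)) TRUE else msg
})

#' One simulated subject's task session
#'
#' Holds the full trial log of a simulated session of the probabilistic
#' reward-learning task, together with the generating agent (ground truth
#' for recovery studies) and the task configuration.
#'
#' @slot subject subject identifier.
#' @slot trials data.frame with one row per trial: \code{block},
#'   \code{trial}, \code{set_winner}, \code{left_stimulus},
#'   \code{right_stimulus}, \code{choice}, \code{chosen_side},
#'   \code{feedback}, \code{strategy_next}, \code{rt_ms}.
#' @slot agent the agent specification (see [agentSpec()]).
#' @slot task the task configuration (see [taskConfig()]).
#' @export
setClass("SubjectSession",
  representation(
    subject = "character",
    trials = "data.frame",
    agent = "list",
    task = "list"
  )
)

setValidity("SubjectSession", function(object) {
  need <- c("block", "trial", "set_winner", "left_stimulus", "right_stimulus",
            "choice", "chosen_side", "feedback", "strategy_next")
  if (!all(need %in% names(object@trials)))
    return(paste("trials is missing columns:",
                 paste(setdiff(need, names(object@trials)), collapse = ", ")))
  TRUE
})
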