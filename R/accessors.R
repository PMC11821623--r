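#' Accessors for EpochSet objects
#'
#' @param x an \code{EpochSet} (or \code{Erp} where noted).
#' @return \code{nEpochs}, \code{nChannels}, \code{nSamples} return counts;
#'   \code{samplingRate} the sampling rate in Hz; \code{sampleTimes} the
#'   per-sample times in ms relative to event onset; \code{channelNames}
#'   the channel names; \code{epochInfo} the per-epoch metadata;
#'   \code{epochData} the raw epochs x channels x samples array.
#' @name EpochSet-accessors
NULL

#' @rdname EpochSet-accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname EpochSet-accessors
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2L])

#' @rdname EpochSet-accessors
#' @export
setMethod("nChannels", "Erp", function(x) nrow(x@data))

#' @rdname EpochSet-accessors
#' @export
setMethod("nSamples", "EpochSet", function(x) dim(x@data)[3L])

#' @rdname EpochSet-accessors
#' @export
setMethod("nSamples", "Erp", function(x) ncol(x@data))

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("samplingRate", "Erp", function(x) x@fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("sampleTimes", "EpochSet",
          function(x) x@t0 + (seq_len(nSamples(x)) - 1) * 1000 / x@fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("sampleTimes", "Erp",
          function(x) x@t0 + (seq_len(nSamples(x)) - 1) * 1000 / x@fs)

#' @rdname EpochSet-accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) dimnames(x@data)[[2L]])

#' @rdname EpochSet-accessors
#' @export
setMethod("channelNames", "Erp", function(x) rownames(x@data))

#' @rdname EpochSet-accessors
#' @export
setMethod("epochInfo", "EpochSet", function(x) x@info)

#' @rdname EpochSet-accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' Subset an EpochSet
#'
#' \code{x[i, j]} keeps epochs \code{i} and channels \code{j} (names or
#' indices); metadata rows follow the epochs.
#'
#' @param x an \code{EpochSet}.
#' @param i epoch indices.
#' @param j channel names or indices.
#' @param ... ignored.
#' @param drop ignored (dimensions are always kept).
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nEpochs(x))
  if (missing(j)) j <- seq_len(nChannels(x))
  new("EpochSet",
      data = x@data[i, j, , drop = FALSE],
      fs = x@fs, t0 = x@t0, eventKind = x@eventKind,
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples\n",
              nEpochs(object), nChannels(object), nSamples(object)))
  cat(sprintf("  fs %g Hz, span %g..%g ms, event: %s\n",
              object@fs, object@t0,
              max(sampleTimes(object)), object@eventKind))
  if (ncol(object@info))
    cat("  metadata:", paste(names(object@info), collapse = ", "), "\n")
})

setMethod("show", "Erp", function(object) {
  cat(sprintf("Erp '%s': %d channels x %d samples (mean of %d epochs)\n",
              object@label, nChannels(object), nSamples(object), object@n))
})

#' Accessors for SubjectSession objects
#'
#' @param x a \code{SubjectSession}.
#' @return \code{trialLog} returns the per-trial data.frame;
#'   \code{agentSpecOf} the generating agent specification.
#' @name SubjectSession-accessors
NULL

#' @rdname SubjectSession-accessors
#' @export
setMethod("trialLog", "SubjectSession", function(x) x@trials)

#' @rdname SubjectSession-accessors
#' @export
setMethod("agentSpecOf", "SubjectSession", function(x) x@agent)

setMethod("show", "SubjectSession", function(object) {
  tr <- object@trials
  cat(sprintf("SubjectSession '%s': %d trials in %d blocks (agent: %s)\n",
              object@subject, nrow(tr), length(unique(tr$block)),
              object@agent$kind))
  cat(sprintf("  %% set-winner choices: %.1f, %% gain feedback: %.1f\n",
              100 * mean(tr$choice == tr$set_winner),
              100 * mean(tr$feedback == "gain")))
})

#' Accessors for Montage objects
#'
#' @param x a \code{Montage}.
#' @param roi name of a catalogued ROI.
#' @name Montage-accessors
NULL

#' @rdname Montage-accessors
#' @export
setMethod("roiChannels", "Montage", function(x, roi) {
  if (!roi %in% names(x@rois)) stop("unknown ROI: ", roi)
  x@rois[[roi]]
})

#' @rdname Montage-accessors
#' @export
setMethod("outerRing", "Montage", function(x) x@outerRing)

#' @rdname Montage-accessors
#' @export
setMethod("mastoids", "Montage", function(x) x@mastoids)

#' @rdname Montage-accessors
#' @export
setMethod("channelNames", "Montage", function(x) x@channels)

#' @rdname Montage-accessors
#' @export
setMethod("channelPositions", "Montage", function(x) x@pos)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d channels (%d outer ring, %d L/R pairs)\n",
              length(object@channels), length(object@outerRing),
              nrow(object@pairs)))
  cat("  ROIs:", paste(names(object@rois), collapse = ", "), "\n")
  cat("  mastoids:", paste(object@mastoids, collapse = "/"), "\n")
})

setMethod("show", "CleaningReport", function(object) {
  tab <- table(factor(object@epochs$outcome,
                      c("kept", "kept-with-interpolation", "rejected")))
  cat("CleaningReport:",
      sprintf("%d kept, %d kept-with-interpolation, %d rejected\n",
              tab[1], tab[2], tab[3]))
  if (nrow(object@badChannels))
    cat("  record-level bad channels:",
        paste(object@badChannels$channel, collapse = ", "), "\n")
})
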