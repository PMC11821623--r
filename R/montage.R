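# Synthetic 129-channel geodesic-style montage.
#
# True HydroCel sensor coordinates are proprietary; no analysis here depends
# on exact geometry beyond laterality (left/right homologues), a designated
# outer ring, neighbourhood structure and the mastoid pair, so a
# deterministic unit-sphere layout preserving those features is used.

.sph <- function(thetaDeg, phiDeg, side = 0) {
  # theta: polar angle from vertex; phi: azimuth from anterior midline
  # towards the lateral side; side -1 = left (x < 0), +1 = right, 0 midline
  th <- thetaDeg * pi / 180
  ph <- phiDeg * pi / 180
  c(x = side * sin(th) * sin(ph), y = sin(th) * cos(ph), z = cos(th))
}

# left/right homologue pairs that the analyses name explicitly:
# centro-parietal P300 pairs, occipital N2pc pairs, mastoids, and one
# fronto-lateral pair so the frontal ROI channel E10 has a defined side.
.forcedPairs <- function() {
  rbind(
    c("E37", "E87"), c("E31", "E80"), c("E53", "E86"), c("E60", "E85"),
    c("E67", "E77"), c("E61", "E78"), c("E54", "E79"),
    c("E50", "E101"), c("E58", "E96"),
    c("E57", "E100"),
    c("E10", "E3")
  )
}

.forcedPairAngles <- function() {
  # theta, phi per forced pair (left member; right is mirrored)
  rbind(
    c(30, 115), c(38, 110), c(38, 130), c(46, 125),
    c(54, 140), c(46, 105), c(30, 135),
    c(62, 155), c(70, 148),
    c(95, 120),
    c(40, 25)
  )
}

#' Build the synthetic 129-channel geodesic montage
#'
#' Constructs a deterministic montage with channels \code{E1..E128} plus the
#' vertex channel \code{E129}: unit-sphere positions, a designated
#' 24-channel outer ring at the lowest elevation, left/right homologue
#' pairs covering every lateralized ROI channel, the mastoid pair
#' (\code{E57}/\code{E100}), and the ROI catalog used by the ERP analyses:
#' \describe{
#'   \item{frontal}{E10, E11, E16 — reward-positivity window means}
#'   \item{centroparietal}{seven left/right pairs plus the midline
#'     E129, E55, E62, E71 — P300 window means}
#'   \item{occipital_left / occipital_right}{E50, E58 / E101, E96 — the
#'     homologue pairs entering the N2pc contra-minus-ipsi subtraction}
#' }
#'
#' @return a [Montage-class] object.
#' @examples
#' m <- hydrocelMontage()
#' length(outerRing(m))  # 24
#' @export
hydrocelMontage <- function() {
  channels <- paste0("E", 1:129)
  fp <- .forcedPairs()
  fa <- .forcedPairAngles()
  midline <- c("E6", "E11", "E16", "E55", "E62", "E71")
  midAng <- rbind( # theta, anterior(+1)/posterior(-1)
    c(25, +1), c(48, +1), c(65, +1), c(25, -1), c(48, -1), c(65, -1)
  )

  pos <- matrix(NA_real_, 129, 3, dimnames = list(channels, c("x", "y", "z")))
  pos["E129", ] <- c(0, 0, 1)
  for (i in seq_along(midline))
    pos[midline[i], ] <- .sph(midAng[i, 1], ifelse(midAng[i, 2] > 0, 0, 180))
  for (i in seq_len(nrow(fp))) {
    pos[fp[i, 1], ] <- .sph(fa[i, 1], fa[i, 2], side = -1)
    pos[fp[i, 2], ] <- .sph(fa[i, 1], fa[i, 2], side = +1)
  }

  free <- setdiff(channels[1:128], c(fp, midline))
  nf <- length(free) / 2L                       # 50 free pairs
  freeL <- free[seq_len(nf)]
  freeR <- free[nf + seq_len(nf)]
  nInner <- nf - 12L                            # last 12 pairs = outer ring
  for (i in seq_len(nInner)) {
    th <- 22 + 58 * (i - 1) / (nInner - 1)
    ph <- 20 + (i * 37) %% 140
    pos[freeL[i], ] <- .sph(th, ph, side = -1)
    pos[freeR[i], ] <- .sph(th, ph, side = +1)
  }
  outerIdx <- nInner + seq_len(12L)
  phOut <- seq(15, 165, length.out = 12)
  for (k in seq_along(outerIdx)) {
    i <- outerIdx[k]
    pos[freeL[i], ] <- .sph(100, phOut[k], side = -1)
    pos[freeR[i], ] <- .sph(100, phOut[k], side = +1)
  }
  outer <- c(freeL[outerIdx], freeR[outerIdx])

  rois <- list(
    frontal = c("E10", "E11", "E16"),
    centroparietal = c("E37", "E87", "E31", "E80", "E53", "E86", "E60",
                       "E85", "E67", "E77", "E61", "E78", "E54", "E79",
                       "E129", "E55", "E62", "E71"),
    occipital_left = c("E50", "E58"),
    occipital_right = c("E101", "E96")
  )
  pairs <- rbind(fp, cbind(freeL, freeR))
  dimnames(pairs) <- list(NULL, c("left", "right"))

  new("Montage", channels = channels, pos = pos, outerRing = outer,
      rois = rois, pairs = pairs, mastoids = c("E57", "E100"),
      midline = c(midline, "E129"))
}

#' Restrict a montage to a channel subset
#'
#' Keeps only the named channels; ROIs, pairs, the outer ring and the
#' midline are intersected accordingly. The mastoid pair must survive the
#' subset. Useful for reduced-channel simulation studies where only ROI
#' channels are needed.
#'
#' @param montage a [Montage-class].
#' @param keep channel names to retain.
#' @return a [Montage-class] on the subset.
#' @export
subsetMontage <- function(montage, keep) {
  stopifnot(is(montage, "Montage"))
  miss <- setdiff(keep, montage@channels)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  keep <- montage@channels[montage@channels %in% keep]  # stable order
  pr <- montage@pairs
  pr <- pr[pr[, 1] %in% keep & pr[, 2] %in% keep, , drop = FALSE]
  rois <- lapply(montage@rois, intersect, keep)
  rois <- rois[vapply(rois, length, 1L) > 0]
  new("Montage",
      channels = keep,
      pos = montage@pos[keep, , drop = FALSE],
      outerRing = intersect(montage@outerRing, keep),
      rois = rois, pairs = pr,
      mastoids = intersect(montage@mastoids, keep),
      midline = intersect(montage@midline, keep))
}

#' k nearest neighbours of each channel
#'
#' Neighbourhoods by Euclidean distance between unit-sphere positions;
#' used by the low-correlation bad-channel criterion.
#'
#' @param montage a [Montage-class].
#' @param k neighbours per channel.
#' @param channels channels to report (default all).
#' @return named list of character vectors.
#' @export
channelNeighbors <- function(montage, k = 8, channels = NULL) {
  pos <- montage@pos
  if (is.null(channels)) channels <- montage@channels
  d <- as.matrix(stats::dist(pos))
  out <- lapply(channels, function(ch) {
    nb <- sort(d[ch, setdiff(montage@channels, ch)])
    names(nb)[seq_len(min(k, length(nb)))]
  })
  names(out) <- channels
  out
}

# channels whose montage defines them as carrying lateralized signal
.sideOf <- function(montage, channels) {
  s <- sign(montage@pos[channels, "x"])
  ifelse(s < 0, "left", ifelse(s > 0, "right", "midline"))
}
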