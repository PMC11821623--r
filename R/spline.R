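# Spherical-spline scalp interpolation (Perrin et al. style, order m = 4).
# Written in-package: no installed R package provides it.

# Legendre polynomials P_1..P_n at x (vector), by recurrence
.legendreUpTo <- function(x, n) {
  out <- matrix(0, length(x), n)
  out[, 1] <- x
  if (n >= 2) out[, 2] <- (3 * x^2 - 1) / 2
  if (n >= 3) for (k in 3:n)
    out[, k] <- ((2 * k - 1) * x * out[, k - 1] - (k - 1) * out[, k - 2]) / k
  out
}

# spline kernel g(cos angle) with stiffness m, truncated series
.splineG <- function(x, m = 4, nTerms = 20) {
  P <- .legendreUpTo(pmin(pmax(x, -1), 1), nTerms)
  n <- seq_len(nTerms)
  w <- (2 * n + 1) / (n * (n + 1))^m
  matrix(P %*% w / (4 * pi), nrow = length(x))
}

# interpolation weight matrix W (bad x good): estimate = W %*% v_good.
# KKT system with an explicit constant term, so spatially constant fields
# are reproduced exactly; `lambda` is a small ridge on the kernel block.
.splineWeights <- function(posGood, posBad, m = 4, nTerms = 20,
                           lambda = 1e-8) {
  g <- nrow(posGood)
  if (g < 4) stop("spherical-spline interpolation needs >= 4 good channels")
  cosGG <- tcrossprod(posGood)
  cosBG <- posBad %*% t(posGood)
  G <- matrix(.splineG(as.vector(cosGG), m, nTerms), g, g) + lambda * diag(g)
  Gb <- matrix(.splineG(as.vector(cosBG), m, nTerms), nrow(posBad), g)
  A <- rbind(cbind(G, 1), c(rep(1, g), 0))
  sol <- solve(A, rbind(diag(g), 0))      # maps v -> (c, d)
  cbind(Gb, 1) %*% sol
}

#' Interpolate channels by spherical splines
#'
#' Replaces the named channels, in every epoch, by spherical-spline
#' estimates (stiffness \code{m = 4}) from the remaining channels.
#' A spatially constant field is reconstructed exactly.
#'
#' @param epochs an [EpochSet-class].
#' @param channels channels to replace.
#' @param montage a [Montage-class] with positions for all channels.
#' @param m spline stiffness.
#' @param lambda small ridge term on the kernel matrix.
#' @return the [EpochSet-class] with the channels replaced.
#' @export
interpolateSpherical <- function(epochs, channels, montage, m = 4,
                                 lambda = 1e-8) {
  stopifnot(is(epochs, "EpochSet"))
  if (!length(channels)) return(epochs)
  present <- channelNames(epochs)
  if (!all(channels %in% present))
    stop("channel(s) not in the epochs: ",
         paste(setdiff(channels, present), collapse = ", "))
  good <- setdiff(present, channels)
  pos <- channelPositions(montage)
  if (!all(present %in% rownames(pos)))
    stop("montage lacks positions for some epoch channels")
  W <- .splineWeights(pos[good, , drop = FALSE],
                      pos[channels, , drop = FALSE], m = m, lambda = lambda)
  e <- nEpochs(epochs)
  S <- nSamples(epochs)
  Vg <- matrix(aperm(epochs@data[, good, , drop = FALSE], c(2L, 1L, 3L)),
               nrow = length(good))           # good x (e*S)
  est <- W %*% Vg                              # bad x (e*S)
  epochs@data[, channels, ] <-
    aperm(array(est, c(length(channels), e, S)), c(2L, 1L, 3L))
  epochs
}
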