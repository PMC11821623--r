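# small shared utilities

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards. seed = NULL evaluates in the current stream.
runWithSeed <- function(seed, expr, normalKind = NULL) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (is.null(normalKind)) set.seed(as.integer(seed))
  else set.seed(as.integer(seed), normal.kind = normalKind)
  eval.parent(substitute(expr))
}

# Counter-based fan-out of one master seed into per-unit substreams
# (subject, repetition, stage ...). Keeps results independent of the order
# in which units are simulated and below 2^31.
subSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + 104729 * as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# closed-open [t0, t1) window -> sample indices on a time grid (ms)
windowIndices <- function(times, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  which(times >= window[1] & times < window[2])
}

# raised-cosine bump confined to `window` on the grid `times`, normalized
# so its mean over the in-window samples is exactly 1
raisedCosine <- function(times, window) {
  w <- numeric(length(times))
  idx <- windowIndices(times, window)
  if (!length(idx)) stop("window contains no samples at this sampling rate")
  ph <- (times[idx] - window[1]) / (window[2] - window[1])
  w[idx] <- 1 - cos(2 * pi * ph)
  w / mean(w[idx])
}
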