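# shared fixtures, built in code at test time

fullMontage <- hydrocelMontage()
roiMontage <- compactMontage()

# toy 5-trial block from the worked strategy example:
# choices F,F,H,H,F with feedback G,L,G,L,- gives transition labels
# (win-stay, lose-shift, win-stay, lose-shift)
toyBlockTrials <- function() {
  data.frame(
    block = 1L, trial = 1:5,
    set_winner = "face",
    left_stimulus = "face", right_stimulus = "house",
    choice = c("face", "face", "house", "house", "face"),
    chosen_side = c("left", "left", "right", "right", "left"),
    feedback = c("gain", "loss", "gain", "loss", "loss"),
    strategy_next = c("win-stay", "lose-shift", "win-stay", "lose-shift",
                      "none"),
    stringsAsFactors = FALSE)
}

# small constant-valued EpochSet on the compact montage
constantEpochs <- function(e = 4, value = 0, fs = 250,
                           montage = roiMontage, span = c(-400, 800)) {
  S <- round(diff(span) * fs / 1000)
  ch <- channelNames(montage)
  arr <- array(value, c(e, length(ch), S), dimnames = list(NULL, ch, NULL))
  new("EpochSet", data = arr, fs = fs, t0 = span[1], eventKind = "generic",
      info = data.frame(epoch = seq_len(e)))
}

# quiet epochs with a little white noise (so correlations are defined)
quietEpochs <- function(e = 5, sd = 1, seed = 99, fs = 250,
                        montage = roiMontage) {
  ep <- constantEpochs(e, 0, fs, montage)
  set.seed(seed)
  ep@data[] <- rnorm(length(ep@data), sd = sd)
  ep
}

noiseFreeSpec <- function(...) {
  effectSpec(noiseSd = 0, pinkSd = 0, lineAmp = 0, blinkRate = 0, ...)
}
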