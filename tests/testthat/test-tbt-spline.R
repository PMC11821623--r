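test_that("clean epochs pass the trial-by-trial screen untouched", {
  ep <- quietEpochs(e = 5)
  res <- rejectEpochsTBT(ep, roiMontage)
  expect_equal(res$report@epochs$outcome, rep("kept", 5))
  expect_true(all(res$report@epochs$n_flagged == 0))
  expect_equal(epochData(res$epochs), epochData(ep))
})

test_that("hand-enumerated artifact plans give the predicted outcomes", {
  ep <- quietEpochs(e = 6)
  chs <- channelNames(ep)
  plan <- rbind(
    data.frame(epoch = 3, channel = chs[1:12], kind = "spike",
               amplitude = 200, onset_ms = 0),
    data.frame(epoch = 5, channel = chs[13:16], kind = "offset",
               amplitude = 160, onset_ms = 0))
  res <- rejectEpochsTBT(injectArtifacts(ep, plan), roiMontage)
  out <- res$report@epochs
  expect_equal(out$outcome[3], "rejected")            # 12 >= 10 channels
  expect_equal(out$outcome[5], "kept-with-interpolation")
  expect_equal(out$outcome[c(1, 2, 4, 6)], rep("kept", 4))
  expect_setequal(res$report@flagged[[5]]$channel, chs[13:16])
  expect_true(all(grepl("absolute-voltage",
                        res$report@flagged[[5]]$criterion)))
  expect_true(all(grepl("peak-to-peak",
                        res$report@flagged[[3]]$criterion)))
  # rejected epoch removed; interpolated epoch's channels replaced
  expect_equal(nEpochs(res$epochs), 5L)
  kept5 <- epochData(res$epochs)[4, chs[13], ]        # epoch 5 after drop
  expect_lt(max(abs(kept5)), 20)                      # 160 uV offset gone
})

test_that("the rejection rule is the flagged-channel count threshold", {
  ep <- quietEpochs(e = 4)
  chs <- channelNames(ep)
  mk <- function(k) data.frame(epoch = 2, channel = chs[seq_len(k)],
                               kind = "offset", amplitude = 200)
  nine <- rejectEpochsTBT(injectArtifacts(ep, mk(9)), roiMontage)
  expect_equal(nine$report@epochs$outcome[2], "kept-with-interpolation")
  ten <- rejectEpochsTBT(injectArtifacts(ep, mk(10)), roiMontage)
  expect_equal(ten$report@epochs$outcome[2], "rejected")
})

test_that("identical epochs produce identical cleaning reports", {
  ep <- quietEpochs(e = 5, sd = 40, seed = 3)
  a <- rejectEpochsTBT(ep, roiMontage)
  b <- rejectEpochsTBT(ep, roiMontage)
  expect_identical(a$report@epochs, b$report@epochs)
  expect_identical(epochData(a$epochs), epochData(b$epochs))
})

test_that("spherical splines reproduce constants and smooth fields", {
  ep <- constantEpochs(e = 2, value = 7)
  out <- interpolateSpherical(ep, "E11", roiMontage)
  expect_equal(max(abs(epochData(out)[, "E11", ] - 7)), 0,
               tolerance = 1e-8)
  # low-order field: reconstruction error far below typical noise
  pos <- channelPositions(roiMontage)
  field <- 3 * pos[, "z"] + 2 * pos[, "x"] - pos[, "y"]
  ep2 <- constantEpochs(e = 1)
  for (ch in channelNames(ep2)) ep2@data[, ch, ] <- field[ch]
  out2 <- interpolateSpherical(ep2, c("E62", "E87"), roiMontage)
  expect_lt(max(abs(epochData(out2)[, "E62", ] - field["E62"])), 0.01)
  expect_lt(max(abs(epochData(out2)[, "E87", ] - field["E87"])), 0.01)
  # interpolating an already-consistent channel is near identity
  out3 <- interpolateSpherical(ep2, "E55", roiMontage)
  expect_lt(max(abs(epochData(out3)[, "E55", ] - field["E55"])), 0.02)
})

test_that("interpolation demands enough good channels", {
  ep <- constantEpochs(e = 1, value = 1)
  few <- ep[, c("E11", "E16", "E10", "E55", "E62")]
  expect_error(interpolateSpherical(few, c("E55", "E62"), roiMontage),
               ">= 4 good channels")
})
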