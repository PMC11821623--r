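test_that("noise-free synthesis reproduces every injected amplitude exactly", {
  s <- simulateSession(taskConfig(nBlocks = 4L),
                       agentSpec("rescorla_wagner", group = "poor"),
                       seed = 1)
  ep <- synthesizeEpochs(s, noiseFreeSpec(), roiMontage, fs = 250, seed = 2)
  fb <- baselineCorrect(rereferenceMastoids(ep$feedback, roiMontage))
  cu <- baselineCorrect(rereferenceMastoids(ep$cue, roiMontage))
  m <- subjectErpMeasures(cu, fb, roiMontage)
  expect_equal(m$rewp_diff, 2, tolerance = 1e-9)
  expect_equal(m$rewp_loss, 0, tolerance = 1e-9)
  expect_equal(c(m$p300_gain_stay, m$p300_gain_shift,
                 m$p300_loss_stay, m$p300_loss_shift),
               c(4, 5, 5, 6), tolerance = 1e-9)
  expect_equal(m$n2pc_chosen, -1.5, tolerance = 1e-9)
})

test_that("ipsilateral channels receive no chosen-side deflection", {
  s <- simulateSession(taskConfig(nBlocks = 2L), agentSpec("random"),
                       seed = 3)
  spec <- noiseFreeSpec(rewpDiffByGroup = c(all = 0),
                        p300ByCell = c(gain_stay = 0, gain_shift = 0,
                                       loss_stay = 0, loss_shift = 0))
  cu <- synthesizeEpochs(s, spec, roiMontage, fs = 250, seed = 4,
                         which = "cue")$cue
  left <- which(epochInfo(cu)$chosen_side == "left")
  # chosen left: ipsilateral = left occipital channels -> zero
  expect_equal(max(abs(epochData(cu)[left, c("E50", "E58"), ])), 0)
  expect_lt(min(epochData(cu)[left, c("E101", "E96"), ]), -1)
})

test_that("component bumps stay inside their measurement windows", {
  s <- simulateSession(taskConfig(nBlocks = 2L),
                       agentSpec("oracle", group = "poor"), seed = 5)
  fb <- synthesizeEpochs(s, noiseFreeSpec(), roiMontage, fs = 250,
                         seed = 6, which = "feedback")$feedback
  t <- sampleTimes(fb)
  pre <- which(t < 275)
  expect_equal(max(abs(epochData(fb)[, "E11", pre])), 0)
  post <- which(t >= 600)
  expect_equal(max(abs(epochData(fb)[, "E62", post])), 0)
})

test_that("zero-effect noisy averages shrink toward zero", {
  s <- simulateSession(taskConfig(nBlocks = 20L), agentSpec("random"),
                       seed = 7)
  spec <- effectSpec(rewpDiffByGroup = c(all = 0),
                     p300ByCell = c(gain_stay = 0, gain_shift = 0,
                                    loss_stay = 0, loss_shift = 0),
                     n2pc = 0, n2pcWinner = 0, blinkRate = 0, lineAmp = 0)
  fb <- synthesizeEpochs(s, spec, roiMontage, fs = 250, seed = 8,
                         which = "feedback")$feedback
  fb <- baselineCorrect(rereferenceMastoids(fb, roiMontage))
  bins <- binAverage(fb, "feedback")
  gm <- roiWindowMean(bins[["gain"]], "frontal", c(275, 375), roiMontage)
  expect_lt(abs(gm), 0.75)   # ~180-epoch average of zero-mean noise
})

test_that("identical seeds reproduce epochs bit for bit", {
  s <- simulateSession(taskConfig(nBlocks = 2L),
                       agentSpec("random", group = "good"), seed = 9)
  a <- synthesizeEpochs(s, effectSpec(), roiMontage, fs = 250, seed = 10)
  b <- synthesizeEpochs(s, effectSpec(), roiMontage, fs = 250, seed = 10)
  expect_identical(epochData(a$feedback), epochData(b$feedback))
  expect_identical(epochData(a$cue), epochData(b$cue))
})

test_that("pink noise has unit variance and a 1/f spectrum", {
  set.seed(11)
  x <- pinkNoiseMatrix(1000, 150)
  expect_lt(abs(mean(apply(x, 2, var)) - 1), 0.05)
  P <- rowMeans(abs(stats::mvfft(x))^2)[2:400]
  slope <- coef(lm(log(P) ~ log(1:399)))[2]
  expect_lt(abs(slope + 1), 0.1)
})

test_that("faulty channels are emulated outside ROIs and mastoids", {
  s <- simulateSession(taskConfig(nBlocks = 2L),
                       agentSpec("random", group = "good"), seed = 12)
  out <- synthesizeEpochs(s, effectSpec(nBadChannels = 4), fullMontage,
                          fs = 250, seed = 13, which = "feedback")
  expect_length(out$badChannels, 4L)
  expect_length(intersect(out$badChannels,
                          c(unlist(fullMontage@rois),
                            mastoids(fullMontage))), 0L)
  flat <- out$badChannels[1]
  expect_equal(max(abs(epochData(out$feedback)[, flat, ])), 0)
})

test_that("artifact injection is exact and validates its plan", {
  ep <- quietEpochs(e = 4)
  expect_identical(epochData(injectArtifacts(ep, NULL)), epochData(ep))
  expect_identical(
    epochData(injectArtifacts(ep, data.frame())), epochData(ep))
  plan <- data.frame(epoch = 2, channel = "E11", kind = "offset",
                     amplitude = 160)
  out <- injectArtifacts(ep, plan)
  expect_equal(epochData(out)[2, "E11", ] - epochData(ep)[2, "E11", ],
               rep(160, nSamples(ep)))
  expect_error(injectArtifacts(ep, transform(plan, epoch = 99)),
               "out of range")
  expect_error(injectArtifacts(ep, transform(plan, channel = "Zz")),
               "unknown")
})
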