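test_that("transition labels match the hand-enumerated toy block", {
  lab <- labelTransitions(toyBlockTrials())
  expect_equal(lab, c(NA, "win-stay", "lose-shift", "win-stay",
                      "lose-shift"))
})

test_that("transition labels partition all within-block transitions", {
  s <- simulateSession(taskConfig(nBlocks = 5L),
                       agentSpec("rescorla_wagner"), seed = 3)
  lab <- labelTransitions(s)
  expect_equal(sum(is.na(lab)), 5L)                # one per block start
  expect_equal(sum(!is.na(lab)), 5L * 17L)
  expect_true(all(lab[!is.na(lab)] %in%
                    c("win-stay", "win-shift", "lose-stay", "lose-shift")))
})

test_that("conditional and N-1 denominators diverge as enumerated", {
  tr <- toyBlockTrials()
  cond <- strategyProportions(tr, "conditional")
  expect_equal(cond$ws_proportion, 1.0)   # 2 win-stay of 2 post-gain
  expect_equal(cond$ls_proportion, 1.0)   # 2 lose-shift of 2 post-loss
  nm1 <- strategyProportions(tr, "n_minus_1")
  expect_equal(nm1$ws_proportion, 0.5)    # 2 of 4 transitions
  expect_equal(nm1$ls_proportion, 0.5)
  expect_equal(cond$n_transitions, 4L)
})

test_that("degenerate all-gain stay sessions give WS = 1, LS undefined", {
  tr <- toyBlockTrials()
  tr$feedback <- "gain"
  tr$choice <- "face"
  sp <- strategyProportions(tr, "conditional")
  expect_equal(sp$ws_proportion, 1.0)
  expect_true(is.na(sp$ls_proportion))    # no post-loss transitions
  spN <- strategyProportions(tr, "n_minus_1")
  expect_equal(spN$ws_proportion, 1.0)
})

test_that("deterministic WSLS yields conditional WS and LS near 1", {
  s <- simulateSession(taskConfig(nBlocks = 40L),
                       agentSpec("wsls", pStayAfterWin = 1,
                                 pShiftAfterLoss = 1), seed = 5)
  sp <- strategyProportions(s)
  expect_equal(sp$ws_proportion, 1.0)
  expect_equal(sp$ls_proportion, 1.0)
})

test_that("learning curves sit at chance for unbiased agents and rise for learners", {
  rnd <- lapply(1:6, function(i)
    simulateSession(taskConfig(), agentSpec("random"), seed = 100 + i,
                    subject = paste0("R", i)))
  lc <- learningCurve(rnd)
  expect_equal(nrow(lc), 18L)
  expect_true(all(abs(lc$p_winner - 0.5) < 3 * sqrt(0.25 / lc$n)))
  # deterministic WSLS: positions 2..18 near the 0.77 stationary rate
  wsls <- lapply(1:6, function(i)
    simulateSession(taskConfig(), agentSpec("wsls", pStayAfterWin = 1,
                                            pShiftAfterLoss = 1),
                    seed = 200 + i, subject = paste0("W", i)))
  lcW <- learningCurve(wsls)
  expect_lt(abs(mean(lcW$p_winner[2:18]) - 0.77), 0.03)
})

test_that("learning-rate slopes behave across degenerate and learning profiles", {
  rnd <- simulateSession(taskConfig(), agentSpec("random"), seed = 21)
  expect_lt(abs(fitLearningRate(rnd)), 0.05)
  # perfectly increasing profile: winner chosen iff past mid-block
  tr <- trialLog(rnd)
  tr$choice <- ifelse(tr$trial > 9, tr$set_winner,
                      ifelse(tr$set_winner == "face", "house", "face"))
  fit <- fitLearningRate(tr)
  expect_gt(as.numeric(fit), 1)
  expect_equal(attr(fit, "method"), "ridge")  # separated fit, penalised
})

test_that("generative learning-ability differences are recovered", {
  mkGroup <- function(alpha, beta, tag, seeds) lapply(seeds, function(i)
    simulateSession(taskConfig(), agentSpec("rescorla_wagner",
                                            alpha = alpha, beta = beta),
                    seed = i, subject = paste0(tag, i)))
  fast <- mkGroup(0.3, 4, "F", 1:8)
  slow <- mkGroup(0.05, 1.5, "S", 11:18)
  rF <- vapply(fast, function(s) as.numeric(fitLearningRate(s)), 0)
  rS <- vapply(slow, function(s) as.numeric(fitLearningRate(s)), 0)
  expect_gt(median(rF), median(rS))
})

test_that("median split is balanced, ordered and tie-stable", {
  pr <- data.frame(subject = c("a", "b", "c", "d"),
                   learning_rate = c(1, 2, 3, 4))
  out <- medianSplit(pr)
  expect_equal(out$learner_class, c("poor", "poor", "good", "good"))
  # 30 subjects -> 15/15
  pr30 <- data.frame(subject = sprintf("s%02d", 1:30),
                     learning_rate = rnorm(30))
  out30 <- medianSplit(pr30)
  expect_equal(as.vector(table(out30$learner_class)), c(15L, 15L))
  # all-equal rates: stable split with a warning
  prEq <- data.frame(subject = sprintf("s%02d", 1:30),
                     learning_rate = rep(0.2, 30))
  expect_warning(outEq <- medianSplit(prEq), "tie")
  expect_equal(as.vector(table(outEq$learner_class)), c(15L, 15L))
  expect_equal(outEq$learner_class[1], "good")
})

test_that("block halves split 20 blocks into 10 + 10 and detect drift", {
  s <- simulateSession(taskConfig(), agentSpec("wsls"), seed = 31)
  h <- halvesContrast(list(s))
  expect_equal(h$half, c("first", "second"))
  # stationary agent: halves agree within sampling error
  many <- lapply(1:10, function(i)
    simulateSession(taskConfig(), agentSpec("wsls"), seed = 40 + i,
                    subject = paste0("S", i)))
  hm <- halvesContrast(many)
  expect_lt(abs(mean(hm$ls[hm$half == "first"]) -
                  mean(hm$ls[hm$half == "second"])), 0.05)
  # scripted decay of the shift probability across halves
  decayed <- lapply(1:10, function(i) {
    early <- simulateSession(taskConfig(nBlocks = 10L),
                             agentSpec("wsls", pShiftAfterLoss = 0.9),
                             seed = 60 + i)
    late <- simulateSession(taskConfig(nBlocks = 10L),
                            agentSpec("wsls", pShiftAfterLoss = 0.4),
                            seed = 80 + i)
    tr <- rbind(trialLog(early),
                transform(trialLog(late), block = block + 10L))
    new("SubjectSession", subject = paste0("D", i), trials = tr,
        agent = list(kind = "wsls", group = "all"), task = list())
  })
  hd <- halvesContrast(decayed)
  expect_gt(mean(hd$ls[hd$half == "first"]),
            mean(hd$ls[hd$half == "second"]) + 0.2)
})

test_that("behaviour profiles summarise accuracy and strategies per subject", {
  sess <- simulateCohort(taskConfig(nBlocks = 6L), defaultGroupAgents(),
                         nPerGroup = 2L, seed = 5)
  pr <- behaviorProfiles(sess)
  expect_equal(nrow(pr), 4L)
  expect_true(all(pr$pct_correct >= 0 & pr$pct_correct <= 100))
  expect_true(all(is.finite(pr$learning_rate)))
})
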