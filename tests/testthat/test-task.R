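test_that("session structure follows the task design", {
  s <- simulateSession(taskConfig(), agentSpec("wsls"), seed = 1)
  tr <- trialLog(s)
  expect_equal(nrow(tr), 360L)
  expect_equal(as.vector(table(tr$block)), rep(18L, 20L))
  # one set winner per block, from the two categories
  perBlock <- tapply(tr$set_winner, tr$block, function(x) length(unique(x)))
  expect_true(all(perBlock == 1L))
  expect_true(all(tr$set_winner %in% c("face", "house")))
  # stimulus placement covers both categories, choice is consistent
  expect_true(all(tr$left_stimulus != tr$right_stimulus))
  expect_true(all(ifelse(tr$chosen_side == "left",
                         tr$left_stimulus, tr$right_stimulus) == tr$choice))
  # block-final trials carry no transition label
  expect_true(all(tr$strategy_next[tr$trial == 18] == "none"))
  expect_true(all(tr$strategy_next[tr$trial < 18] != "none"))
})

test_that("practice mode shortens the session to 2 blocks of 18", {
  s <- simulateSession(taskConfig(practice = TRUE), agentSpec("random"),
                       seed = 2)
  expect_equal(nrow(trialLog(s)), 36L)
  expect_equal(length(unique(trialLog(s)$block)), 2L)
})

test_that("identical seeds reproduce a session bit for bit", {
  a <- simulateSession(taskConfig(), agentSpec("rescorla_wagner"), seed = 7)
  b <- simulateSession(taskConfig(), agentSpec("rescorla_wagner"), seed = 7)
  expect_identical(trialLog(a), trialLog(b))
})

test_that("invalid configurations are rejected", {
  expect_error(taskConfig(pRewardWinner = 1.2), "probabilities")
  expect_error(taskConfig(trialsPerBlock = 1), "trialsPerBlock")
  expect_error(taskConfig(categories = c("face", "face")), "categories")
  expect_error(agentSpec("wsls", pStayAfterWin = -0.1), "pStayAfterWin")
  expect_error(agentSpec("rescorla_wagner", beta = -1), "beta")
})

test_that("an always-winner agent under certain reward always gains", {
  s <- simulateSession(taskConfig(pRewardWinner = 1), agentSpec("oracle"),
                       seed = 3)
  expect_true(all(trialLog(s)$feedback == "gain"))
  expect_true(all(trialLog(s)$choice == trialLog(s)$set_winner))
})

test_that("WSLS policy honours its stay/shift contract", {
  stay1 <- agentSpec("wsls", pStayAfterWin = 1, pShiftAfterLoss = 1)
  expect_equal(wslsChoice("face", "gain", stay1), "face")
  expect_equal(wslsChoice("face", "loss", stay1), "house")
  # Bernoulli contract: ~0.8 repeat rate after a win
  ag <- agentSpec("wsls", pStayAfterWin = 0.8)
  set.seed(11)
  n <- 10000
  rep80 <- mean(replicate(n, wslsChoice("face", "gain", ag) == "face"))
  expect_lt(abs(rep80 - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("delta-rule update and softmax behave as computed by hand", {
  q <- c(face = 0, house = 0)
  up <- rwUpdate(q, "face", 1, alpha = 0.5, beta = 2)
  expect_equal(unname(up$q), c(0.5, 0))
  # beta = 0: indifferent choice regardless of values
  up0 <- rwUpdate(c(face = 0.9, house = 0.1), "face", 1, 0.3, beta = 0)
  expect_equal(unname(up0$prob), c(0.5, 0.5))
  expect_equal(sum(up$prob), 1)
})

test_that("a Rescorla-Wagner learner improves across the block", {
  cfg <- taskConfig(nBlocks = 300L)
  s <- simulateSession(cfg, agentSpec("rescorla_wagner", alpha = 0.3,
                                      beta = 5), seed = 13)
  tr <- trialLog(s)
  first <- mean((tr$choice == tr$set_winner)[tr$trial == 1])
  last <- mean((tr$choice == tr$set_winner)[tr$trial == 18])
  expect_gt(last, first + 0.1)
})

test_that("deterministic WSLS matches the two-state Markov chain", {
  # two-state chain over the choice (winner / non-winner): a winner choice
  # stays with P(gain) = p, a non-winner choice moves to the winner with
  # P(loss) = 1 - (1 - p) = p, so each row is (p, 1 - p) and the
  # stationary winner rate is p
  p <- 0.77
  P <- matrix(c(p, 1 - p, p, 1 - p), 2, byrow = TRUE)
  pi <- Re(eigen(t(P))$vectors[, 1])
  pi <- pi / sum(pi)
  expect_equal(pi[1], p, tolerance = 1e-12)
  s <- simulateSession(taskConfig(nBlocks = 3L, trialsPerBlock = 10000L),
                       agentSpec("wsls", pStayAfterWin = 1,
                                 pShiftAfterLoss = 1), seed = 17)
  rate <- mean(trialLog(s)$choice == trialLog(s)$set_winner)
  expect_lt(abs(rate - pi[1]), 0.01)
})
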