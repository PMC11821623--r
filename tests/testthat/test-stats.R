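test_that("t statistics and Cohen's d match closed-form computation", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 5)
  d <- a - b                              # -1, -1, -2
  tHand <- mean(d) / (sd(d) / sqrt(3))
  res <- tTestD(a, b, kind = "paired")
  expect_equal(res$statistic, tHand)
  expect_equal(res$df, 2)
  expect_equal(res$d, mean(d) / sd(d))
  # independent: pooled-SD d
  x <- c(1, 2, 3, 4)
  y <- c(3, 4, 5, 7)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  ri <- tTestD(x, y)
  expect_equal(ri$d, (mean(x) - mean(y)) / sp)
  expect_equal(ri$p, t.test(x, y, var.equal = TRUE)$p.value)
  # identical paired samples: t = 0, p = 1
  same <- tTestD(a, a, kind = "paired")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  # zero-variance independent input flagged undefined
  z <- tTestD(c(1, 1, 1), c(1, 1, 1))
  expect_true(is.na(z$p) && z$degenerate)
})

test_that("the estimated independent d is calibrated at its true value", {
  set.seed(31)
  ds <- replicate(400, tTestD(rnorm(15, 1), rnorm(15, 0))$d)
  expect_lt(abs(mean(ds) - 1.0), 0.08)
})

test_that("mixed ANOVA matches the per-effect contrast oracle exactly", {
  set.seed(7)
  d <- expand.grid(subject = paste0("s", 1:8), A = c("a1", "a2"),
                   B = c("b1", "b2"))
  d$G <- ifelse(d$subject %in% paste0("s", 1:4), "g1", "g2")
  d$y <- rnorm(nrow(d), 10, 3) + 2 * (d$G == "g2") + 1.5 * (d$A == "a2")
  an <- mixedAnova(d, "y", within = c("A", "B"), between = "G")

  # oracle: each two-level within effect is a one-sample contrast test
  # with the group factor partialled out; F = (unweighted grand contrast
  # mean)^2 / (pooled residual variance * sum(1/n_g) / G^2)
  cellM <- with(d, tapply(y, list(subject, A, B), mean))
  subj <- dimnames(cellM)[[1]]
  g <- vapply(subj, function(s) as.character(d$G[d$subject == s][1]), "")
  oracleF <- function(x) {
    m <- lm(x ~ factor(g))
    s2 <- sum(resid(m)^2) / m$df.residual
    ng <- table(g)
    gm <- mean(tapply(x, g, mean))
    gm^2 / (s2 * sum(1 / ng) / length(ng)^2)
  }
  cA <- (cellM[, 2, 1] + cellM[, 2, 2] - cellM[, 1, 1] - cellM[, 1, 2]) / 2
  cB <- (cellM[, 1, 2] + cellM[, 2, 2] - cellM[, 1, 1] - cellM[, 2, 1]) / 2
  cAB <- (cellM[, 2, 2] - cellM[, 2, 1] - cellM[, 1, 2] + cellM[, 1, 1]) / 2
  expect_equal(an$F[an$effect == "strategy"], oracleF(cA))
  expect_equal(an$F[an$effect == "feedback"], oracleF(cB))
  expect_equal(an$F[an$effect == "feedback:strategy"], oracleF(cAB))
  expect_true(all(an$df1 == 1) && all(an$df2 == 6))
  expect_true(all(an$pes >= 0 & an$pes <= 1))
})

test_that("the between-group F equals the squared independent t", {
  set.seed(9)
  d <- expand.grid(subject = sprintf("s%02d", 1:12), A = c("a1", "a2"),
                   B = c("b1", "b2"))
  d$G <- ifelse(d$subject %in% sprintf("s%02d", 1:6), "g1", "g2")
  d$y <- rnorm(nrow(d)) + 0.8 * (d$G == "g2")
  an <- mixedAnova(d, "y", within = c("A", "B"), between = "G")
  sm <- aggregate(y ~ subject + G, d, mean)
  tt <- tTestD(sm$y[sm$G == "g1"], sm$y[sm$G == "g2"])
  expect_equal(an$F[an$effect == "learner"], tt$statistic^2)
})

test_that("partial eta squared grows with the injected effect", {
  base <- expand.grid(subject = sprintf("s%02d", 1:10),
                      A = c("a1", "a2"), B = c("b1", "b2"))
  base$G <- ifelse(base$subject %in% sprintf("s%02d", 1:5), "g1", "g2")
  set.seed(13)
  noise <- rnorm(nrow(base))
  pes <- vapply(c(0.5, 1.5, 3), function(effect) {
    d <- base
    d$y <- noise + effect * (d$A == "a2")
    an <- mixedAnova(d, "y", within = c("A", "B"), between = "G")
    an$pes[an$effect == "strategy"]
  }, 0)
  expect_true(all(diff(pes) > 0))
})

test_that("subjects with incomplete cells are dropped with a message", {
  d <- expand.grid(subject = paste0("s", 1:6), A = c("a1", "a2"),
                   B = c("b1", "b2"))
  d$G <- ifelse(d$subject %in% paste0("s", 1:3), "g1", "g2")
  set.seed(3)
  d$y <- rnorm(nrow(d))
  d <- d[!(d$subject == "s1" & d$A == "a1" & d$B == "b1"), ]
  expect_message(an <- mixedAnova(d, "y", within = c("A", "B"),
                                  between = "G"), "incomplete")
  expect_equal(unique(an$df2), 3)         # 5 subjects left
})

test_that("null p-values are uniform for the whole battery", {
  set.seed(17)
  nRep <- 400
  pT <- numeric(nRep)
  pA <- matrix(0, nRep, 3)
  base <- expand.grid(subject = sprintf("s%02d", 1:10),
                      A = c("a1", "a2"), B = c("b1", "b2"))
  base$G <- ifelse(base$subject %in% sprintf("s%02d", 1:5), "g1", "g2")
  for (r in seq_len(nRep)) {
    pT[r] <- tTestD(rnorm(10), rnorm(10))$p
    d <- base
    d$y <- rnorm(nrow(d))
    an <- mixedAnova(d, "y", within = c("A", "B"), between = "G")
    pA[r, ] <- an$p[match(c("strategy", "feedback", "feedback:strategy"),
                          an$effect)]
  }
  expect_gt(ks.test(pT, "punif")$p.value, 0.001)
  for (j in 1:3) expect_gt(ks.test(pA[, j], "punif")$p.value, 0.001)
})
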