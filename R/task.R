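# Simulation of the two-alternative probabilistic reward-learning task:
# in each block one stimulus category (face or house) is the "set winner"
# and choosing it is rewarded with high probability.

#' Task configuration
#'
#' The main task runs 20 blocks of 18 trials; within a block one of the two
#' categories is the set winner and choosing it yields gain feedback with
#' probability \code{pRewardWinner} (0.77 by default), while the other
#' choice yields gain with \code{pRewardNonwinner} (the symmetric
#' complement 0.23 by default; configurable because the exact contingency
#' for non-winner choices is a design choice — see the methods vignette).
#' Practice mode shortens the session to 2 blocks of 18 trials.
#'
#' @param nBlocks number of blocks (default 20).
#' @param trialsPerBlock trials per block (default 18, minimum 2).
#' @param pRewardWinner gain probability when the set winner is chosen.
#' @param pRewardNonwinner gain probability otherwise.
#' @param categories the two stimulus categories.
#' @param practice logical; practice mode (2 blocks x 18 trials).
#' @return a validated list of class \code{"TaskConfig"}.
#' @export
taskConfig <- function(nBlocks = 20L, trialsPerBlock = 18L,
                       pRewardWinner = 0.77, pRewardNonwinner = 1 - 0.77,
                       categories = c("face", "house"), practice = FALSE) {
  if (isTRUE(practice)) nBlocks <- 2L
  nBlocks <- as.integer(nBlocks)
  trialsPerBlock <- as.integer(trialsPerBlock)
  if (trialsPerBlock < 2L) stop("trialsPerBlock must be >= 2")
  if (nBlocks < 1L) stop("nBlocks must be >= 1")
  for (p in c(pRewardWinner, pRewardNonwinner))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("reward probabilities must lie in [0, 1]")
  if (length(categories) != 2L || anyDuplicated(categories))
    stop("exactly two distinct categories required")
  structure(list(nBlocks = nBlocks, trialsPerBlock = trialsPerBlock,
                 pRewardWinner = pRewardWinner,
                 pRewardNonwinner = pRewardNonwinner,
                 categories = as.character(categories),
                 practice = isTRUE(practice)),
            class = "TaskConfig")
}

#' Agent specification
#'
#' Agents playing the task:
#' \describe{
#'   \item{wsls}{Win-Stay/Lose-Shift heuristic: after gain feedback the
#'     previous choice is repeated with probability \code{pStayAfterWin};
#'     after loss it is abandoned with probability \code{pShiftAfterLoss}.}
#'   \item{rescorla_wagner}{delta-rule value learner with learning rate
#'     \code{alpha} and softmax inverse temperature \code{beta}; values
#'     reset at block boundaries (the set winner changes and the block
#'     break is explicit to the participant).}
#'   \item{random}{ignores feedback; picks the left stimulus with
#'     probability \code{sideBias} on every trial.}
#'   \item{oracle}{always chooses the set winner — a diagnostic agent used
#'     to calibrate the feedback contingency.}
#' }
#' On the first trial of a block (no usable history) the wsls and
#' rescorla_wagner agents also fall back to a \code{sideBias} draw.
#'
#' @param kind one of \code{"wsls"}, \code{"rescorla_wagner"},
#'   \code{"random"}, \code{"oracle"}.
#' @param pStayAfterWin,pShiftAfterLoss WSLS probabilities.
#' @param alpha,beta Rescorla-Wagner learning rate (in \[0,1\]) and softmax
#'   inverse temperature (>= 0).
#' @param sideBias probability of picking the left-presented stimulus when
#'   no history is available.
#' @param group optional learner-group label carried into synthesis
#'   (e.g. \code{"good"}/\code{"poor"}).
#' @return a validated list of class \code{"AgentSpec"}.
#' @export
agentSpec <- function(kind = c("wsls", "rescorla_wagner", "random", "oracle"),
                      pStayAfterWin = 0.9, pShiftAfterLoss = 0.7,
                      alpha = 0.25, beta = 5, sideBias = 0.5,
                      group = "all") {
  kind <- match.arg(kind)
  chk01 <- function(p, nm) if (!is.finite(p) || p < 0 || p > 1)
    stop(nm, " must lie in [0, 1]")
  chk01(sideBias, "sideBias")
  if (kind == "wsls") {
    chk01(pStayAfterWin, "pStayAfterWin")
    chk01(pShiftAfterLoss, "pShiftAfterLoss")
  }
  if (kind == "rescorla_wagner") {
    chk01(alpha, "alpha")
    if (!is.finite(beta) || beta < 0) stop("beta must be >= 0")
  }
  structure(list(kind = kind, pStayAfterWin = pStayAfterWin,
                 pShiftAfterLoss = pShiftAfterLoss, alpha = alpha,
                 beta = beta, sideBias = sideBias,
                 group = as.character(group)),
            class = "AgentSpec")
}

#' Win-Stay/Lose-Shift policy
#'
#' After gain feedback the previous choice is repeated with probability
#' \code{agent$pStayAfterWin}; after loss feedback the other category is
#' taken with probability \code{agent$pShiftAfterLoss}. Draws use the
#' current R random-number stream.
#'
#' @param prevChoice category chosen on the previous trial.
#' @param prevFeedback \code{"gain"} or \code{"loss"}.
#' @param agent an [agentSpec()].
#' @param categories the two categories.
#' @return the chosen category.
#' @export
wslsChoice <- function(prevChoice, prevFeedback, agent,
                       categories = c("face", "house")) {
  other <- setdiff(categories, prevChoice)
  if (prevFeedback == "gain") {
    if (stats::runif(1) < agent$pStayAfterWin) prevChoice else other
  } else {
    if (stats::runif(1) < agent$pShiftAfterLoss) other else prevChoice
  }
}

#' Rescorla-Wagner delta-rule update with softmax choice probabilities
#'
#' Updates the value of the chosen category towards the obtained reward,
#' \code{q'[choice] = q[choice] + alpha * (reward - q[choice])}, leaving the
#' other value untouched, and returns the softmax choice probabilities
#' \code{exp(beta * q') / sum(exp(beta * q'))} for the next draw.
#'
#' @param q named numeric vector of the two current values.
#' @param choice name of the chosen category.
#' @param reward 0 or 1.
#' @param alpha learning rate in \[0,1\].
#' @param beta softmax inverse temperature (>= 0; \code{beta = 0} gives
#'   uniform choice regardless of values).
#' @return list with elements \code{q} (updated values) and \code{prob}
#'   (choice probabilities).
#' @export
rwUpdate <- function(q, choice, reward, alpha, beta) {
  stopifnot(choice %in% names(q), alpha >= 0, alpha <= 1, beta >= 0)
  q[choice] <- q[choice] + alpha * (reward - q[choice])
  z <- beta * q
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  list(q = q, prob = p)
}

# strategy label for the transition into trial n (previous feedback x
# stay/shift); used both for session post-processing and labelTransitions()
.transitionLabel <- function(prevFeedback, prevChoice, choice) {
  stay <- choice == prevChoice
  ifelse(prevFeedback == "gain",
         ifelse(stay, "win-stay", "win-shift"),
         ifelse(stay, "lose-stay", "lose-shift"))
}

#' Simulate one session of the reward-learning task
#'
#' Plays \code{cfg$nBlocks} blocks of \code{cfg$trialsPerBlock} trials.
#' The set winner is drawn uniformly per block; the two stimuli are placed
#' left/right uniformly at random each trial; feedback is Bernoulli with
#' \code{pRewardWinner} when the set winner is chosen and
#' \code{pRewardNonwinner} otherwise. Each trial carries its derived
#' next-trial strategy label (\code{strategy_next}); transitions do not
#' cross block boundaries, so the last trial of a block is labelled
#' \code{"none"}. A descriptive log-normal reaction time column is added.
#' The same \code{seed} reproduces the session bit for bit.
#'
#' @param cfg a [taskConfig()].
#' @param agent an [agentSpec()].
#' @param seed integer seed; \code{NULL} uses the current RNG stream.
#' @param subject subject identifier.
#' @return a [SubjectSession-class].
#' @examples
#' s <- simulateSession(taskConfig(), agentSpec("wsls"), seed = 1)
#' table(trialLog(s)$block)  # 18 trials in each of 20 blocks
#' @export
simulateSession <- function(cfg, agent, seed = NULL, subject = "S01") {
  stopifnot(inherits(cfg, "TaskConfig"), inherits(agent, "AgentSpec"))
  runWithSeed(seed, {
    nb <- cfg$nBlocks; tpb <- cfg$trialsPerBlock
    cats <- cfg$categories
    n <- nb * tpb
    block <- rep(seq_len(nb), each = tpb)
    trial <- rep(seq_len(tpb), nb)
    winner <- rep(sample(cats, nb, replace = TRUE), each = tpb)
    leftIsFirst <- stats::runif(n) < 0.5
    left <- ifelse(leftIsFirst, cats[1], cats[2])
    right <- ifelse(leftIsFirst, cats[2], cats[1])

    choice <- character(n)
    feedback <- character(n)
    if (agent$kind %in% c("oracle", "random")) {
      # no sequential dependence: vectorized
      if (agent$kind == "oracle") {
        choice <- winner
      } else {
        pickLeft <- stats::runif(n) < agent$sideBias
        choice <- ifelse(pickLeft, left, right)
      }
      pGain <- ifelse(choice == winner, cfg$pRewardWinner,
                      cfg$pRewardNonwinner)
      feedback <- ifelse(stats::runif(n) < pGain, "gain", "loss")
    } else {
      u <- matrix(stats::runif(2L * n), n, 2L)
      i <- 0L
      for (b in seq_len(nb)) {
        q <- stats::setNames(c(0, 0), cats)
        prob <- stats::setNames(c(0.5, 0.5), cats)
        for (t in seq_len(tpb)) {
          i <- i + 1L
          ch <- if (t == 1L) {
            if (u[i, 1L] < agent$sideBias) left[i] else right[i]
          } else if (agent$kind == "wsls") {
            prev <- choice[i - 1L]
            other <- if (prev == cats[1]) cats[2] else cats[1]
            if (feedback[i - 1L] == "gain") {
              if (u[i, 1L] < agent$pStayAfterWin) prev else other
            } else {
              if (u[i, 1L] < agent$pShiftAfterLoss) other else prev
            }
          } else { # rescorla_wagner
            if (u[i, 1L] < prob[cats[1]]) cats[1] else cats[2]
          }
          choice[i] <- ch
          pGain <- if (ch == winner[i]) cfg$pRewardWinner else
            cfg$pRewardNonwinner
          feedback[i] <- if (u[i, 2L] < pGain) "gain" else "loss"
          if (agent$kind == "rescorla_wagner") {
            upd <- rwUpdate(q, ch, as.integer(feedback[i] == "gain"),
                            agent$alpha, agent$beta)
            q <- upd$q
            prob <- upd$prob
          }
        }
      }
    }

    chosenSide <- ifelse(choice == left, "left", "right")
    stratNext <- rep("none", n)
    notLast <- trial < tpb
    idx <- which(notLast)
    stratNext[idx] <- .transitionLabel(feedback[idx], choice[idx],
                                       choice[idx + 1L])
    rt <- round(stats::rlnorm(n, log(620), 0.35) + 50)

    trials <- data.frame(
      block = block, trial = trial, set_winner = winner,
      left_stimulus = left, right_stimulus = right,
      choice = choice, chosen_side = chosenSide, feedback = feedback,
      strategy_next = stratNext, rt_ms = rt,
      stringsAsFactors = FALSE)
    new("SubjectSession", subject = subject, trials = trials,
        agent = unclass(agent), task = unclass(cfg))
  })
}

#' Simulate a cohort of subjects
#'
#' One session per subject; agents are recycled over the groups given in
#' \code{agents} (a named list of [agentSpec()]s, name = learner group),
#' \code{nPerGroup} subjects per group. Per-subject seeds are fanned out
#' deterministically from \code{seed}.
#'
#' @param cfg a [taskConfig()].
#' @param agents named list of [agentSpec()] (one per group).
#' @param nPerGroup subjects per group.
#' @param seed integer seed.
#' @return list of [SubjectSession-class], names = subject ids.
#' @export
simulateCohort <- function(cfg, agents, nPerGroup = 15L, seed = 1L) {
  stopifnot(is.list(agents), length(names(agents)) == length(agents))
  sessions <- list()
  k <- 0L
  for (g in names(agents)) {
    ag <- agents[[g]]
    ag$group <- g
    for (i in seq_len(nPerGroup)) {
      k <- k + 1L
      id <- sprintf("S%02d", k)
      sessions[[id]] <- simulateSession(cfg, ag, seed = subSeed(seed, k),
                                        subject = id)
    }
  }
  sessions
}
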