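# Behavioural quantities: strategy labels and Win-Stay / Lose-Shift
# proportions, learning curves, per-subject learning rates, the good/poor
# learner split, and the block-half strategy contrast.

.trialsOf <- function(x) {
  if (is(x, "SubjectSession")) x@trials else as.data.frame(x)
}

#' Label within-block choice transitions
#'
#' Each non-initial trial of a block is labelled by the previous trial's
#' feedback crossed with stay/shift of the current choice: \code{win-stay},
#' \code{win-shift}, \code{lose-stay}, \code{lose-shift}. The first trial
#' of each block has no usable previous trial (the set winner changes at
#' the block boundary) and is labelled \code{NA}. The four labels
#' partition all within-block transitions.
#'
#' @param x a [SubjectSession-class] or its trial data.frame.
#' @return character vector, one label per trial (\code{NA} on
#'   block-initial trials).
#' @export
labelTransitions <- function(x) {
  tr <- .trialsOf(x)
  n <- nrow(tr)
  lab <- rep(NA_character_, n)
  prev <- which(tr$trial > 1L)
  lab[prev] <- .transitionLabel(tr$feedback[prev - 1L],
                                tr$choice[prev - 1L], tr$choice[prev])
  lab
}

#' Win-Stay / Lose-Shift proportions
#'
#' In \code{conditional} mode (the default, matching standard WSLS usage)
#' the win-stay proportion divides win-stay transitions by the number of
#' transitions whose previous trial was rewarded, and lose-shift by those
#' whose previous trial was unrewarded. In \code{n_minus_1} mode both are
#' divided by the total transition count N - B (N trials, B blocks; the
#' first trial of each block has no previous trial). Zero-denominator
#' proportions are reported as \code{NA}, not 0.
#'
#' @param x a [SubjectSession-class] or trial data.frame.
#' @param mode \code{"conditional"} or \code{"n_minus_1"}.
#' @return list of class \code{"StrategySummary"}: \code{n_transitions},
#'   \code{ws_proportion}, \code{ls_proportion}, \code{denominator_mode},
#'   and the raw \code{counts} table.
#' @export
strategyProportions <- function(x, mode = c("conditional", "n_minus_1")) {
  mode <- match.arg(mode)
  lab <- labelTransitions(x)
  lab <- lab[!is.na(lab)]
  nTrans <- length(lab)
  counts <- table(factor(lab, c("win-stay", "win-shift",
                                "lose-stay", "lose-shift")))
  prop <- function(num, den) if (den > 0) num / den else NA_real_
  if (mode == "conditional") {
    ws <- prop(counts["win-stay"], counts["win-stay"] + counts["win-shift"])
    ls <- prop(counts["lose-shift"], counts["lose-stay"] + counts["lose-shift"])
  } else {
    ws <- prop(counts["win-stay"], nTrans)
    ls <- prop(counts["lose-shift"], nTrans)
  }
  structure(list(n_transitions = nTrans,
                 ws_proportion = unname(ws), ls_proportion = unname(ls),
                 denominator_mode = mode, counts = counts),
            class = "StrategySummary")
}

#' Cohort learning curve over within-block trial position
#'
#' For each trial position k (1..trials per block), the proportion of
#' set-winner choices pooled over blocks and subjects.
#'
#' @param sessions a [SubjectSession-class], or a list of them (all sharing
#'   the same trials-per-block).
#' @return data.frame with columns \code{trial}, \code{p_winner}, \code{n}.
#' @export
learningCurve <- function(sessions) {
  if (is(sessions, "SubjectSession")) sessions <- list(sessions)
  tr <- do.call(rbind, lapply(sessions, .trialsOf))
  if (length(unique(vapply(sessions,
                           function(s) max(.trialsOf(s)$trial), 1))) != 1L)
    stop("sessions must share trials_per_block")
  correct <- tr$choice == tr$set_winner
  agg <- stats::aggregate(correct, by = list(trial = tr$trial), FUN = mean)
  n <- as.vector(table(tr$trial))
  data.frame(trial = agg$trial, p_winner = agg$x, n = n)
}

# penalised logistic log-likelihood fit (2 parameters), used when the
# plain glm fit is separated or fails to converge
.ridgeLogistic <- function(yy, xx, lambda = 1e-3) {
  nll <- function(par) {
    eta <- par[1] + par[2] * xx
    sum(log1p(exp(-ifelse(yy == 1, eta, -eta)))) + lambda * par[2]^2
  }
  stats::optim(c(0, 0), nll, method = "BFGS")$par
}

#' Per-subject behavioural learning rate
#'
#' Slope of a logistic regression of the set-winner-choice indicator on
#' the within-block trial position, pooled over blocks: the per-trial
#' change in log-odds of choosing the set winner. Positive slope =
#' learning. If the plain fit is separated or does not converge, a
#' ridge-penalised fit (penalty \code{lambda} on the slope) is used and
#' flagged in the \code{"method"} attribute.
#'
#' @param x a [SubjectSession-class] or trial data.frame.
#' @param lambda ridge penalty for the fallback fit.
#' @return the slope (log-odds per trial) with attributes
#'   \code{"intercept"} and \code{"method"} (\code{"glm"} or
#'   \code{"ridge"}).
#' @export
fitLearningRate <- function(x, lambda = 1e-3) {
  tr <- .trialsOf(x)
  yy <- as.integer(tr$choice == tr$set_winner)
  xx <- tr$trial - mean(tr$trial)
  fit <- suppressWarnings(stats::glm(yy ~ xx, family = stats::binomial()))
  co <- stats::coef(fit)
  method <- "glm"
  if (!fit$converged || !all(is.finite(co)) || abs(co[2]) > 10) {
    co <- .ridgeLogistic(yy, xx, lambda)
    method <- "ridge"
  }
  structure(unname(co[2]), intercept = unname(co[1]), method = method)
}

#' Behavioural profiles for a cohort
#'
#' One row per subject: learning rate, percent set-winner choices, mean
#' reaction time on correct (set-winner) trials, and WS/LS proportions.
#'
#' @param sessions list of [SubjectSession-class].
#' @param mode denominator mode for [strategyProportions()].
#' @return data.frame, one row per subject.
#' @export
behaviorProfiles <- function(sessions, mode = "conditional") {
  rows <- lapply(sessions, function(s) {
    tr <- .trialsOf(s)
    sp <- strategyProportions(s, mode)
    corr <- tr$choice == tr$set_winner
    data.frame(subject = s@subject,
               group = if (!is.null(s@agent$group)) s@agent$group else "all",
               learning_rate = as.numeric(fitLearningRate(s)),
               pct_correct = 100 * mean(corr),
               mean_rt_correct = if ("rt_ms" %in% names(tr))
                 mean(tr$rt_ms[corr]) else NA_real_,
               ws = sp$ws_proportion, ls = sp$ls_proportion,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median split into good and poor learners
#'
#' Subjects are ordered by learning rate (descending, ties broken by their
#' stable input order) and the top half is labelled \code{good}, the rest
#' \code{poor}; split sizes differ by at most one (odd cohorts put the
#' middle subject in \code{good}). A warning is emitted when the split
#' boundary falls inside a run of tied rates.
#'
#' @param profiles data.frame with columns \code{subject} and
#'   \code{learning_rate} (e.g. from [behaviorProfiles()]).
#' @return the data.frame with a \code{learner_class} column added.
#' @export
medianSplit <- function(profiles) {
  n <- nrow(profiles)
  if (n < 2L) stop("median split needs at least two subjects")
  ord <- order(-profiles$learning_rate, seq_len(n))
  nGood <- ceiling(n / 2)
  rates <- profiles$learning_rate[ord]
  if (rates[nGood] == rates[min(nGood + 1L, n)] && n > nGood)
    warning("ties at the split boundary broken by stable subject order")
  cls <- rep("poor", n)
  cls[ord[seq_len(nGood)]] <- "good"
  profiles$learner_class <- cls
  profiles
}

#' Strategy proportions by block half
#'
#' Conditional WS/LS proportions per subject computed separately for the
#' first and second half of the blocks (blocks 1..B/2 vs B/2+1..B; for the
#' 20-block task, 1-10 vs 11-20), the within-subject cells of the
#' strategy-by-half group analysis.
#'
#' @param sessions list of [SubjectSession-class].
#' @param mode denominator mode for [strategyProportions()].
#' @return data.frame with columns \code{subject}, \code{half}
#'   (\code{"first"}/\code{"second"}), \code{ws}, \code{ls}.
#' @export
halvesContrast <- function(sessions, mode = "conditional") {
  if (is(sessions, "SubjectSession")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    tr <- .trialsOf(s)
    nb <- max(tr$block)
    cut <- nb %/% 2L
    out <- lapply(c(first = TRUE, second = FALSE), function(isFirst) {
      sel <- if (isFirst) tr$block <= cut else tr$block > cut
      sp <- strategyProportions(tr[sel, , drop = FALSE], mode)
      c(ws = sp$ws_proportion, ls = sp$ls_proportion)
    })
    data.frame(subject = rep(s@subject, 2L),
               half = c("first", "second"),
               ws = c(out$first["ws"], out$second["ws"]),
               ls = c(out$first["ls"], out$second["ls"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
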