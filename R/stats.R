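# Statistical battery: t-tests with Cohen's d and the 2 (strategy) x
# 2 (feedback) x group mixed-design repeated-measures ANOVA with partial
# eta squared.

#' t-test with Cohen's d
#'
#' Two-tailed by default. Independent tests pool the variance and use the
#' pooled SD for Cohen's d; paired (and one-sample) tests use the SD of
#' the differences. Zero-variance input yields \code{NA} statistics with
#' a \code{degenerate} flag rather than an error.
#'
#' @param a,b numeric samples; \code{b = NULL} gives a one-sample test of
#'   \code{a} against \code{mu}.
#' @param kind \code{"independent"}, \code{"paired"} or
#'   \code{"one_sample"}.
#' @param mu null value for the one-sample test.
#' @param alternative passed to [stats::t.test()].
#' @return list of class \code{"prlTTest"}: \code{statistic}, \code{df},
#'   \code{p}, \code{d}, \code{kind}, \code{alternative},
#'   \code{degenerate}.
#' @export
tTestD <- function(a, b = NULL,
                   kind = c("independent", "paired", "one_sample"),
                   mu = 0, alternative = "two.sided") {
  kind <- match.arg(kind)
  if (kind == "one_sample" || is.null(b)) {
    kind <- "one_sample"
    x <- a - mu
    if (length(x) < 2) stop("need n >= 2")
    if (stats::sd(x) == 0)
      return(structure(list(statistic = NA_real_, df = length(x) - 1,
                            p = NA_real_, d = NA_real_, kind = kind,
                            alternative = alternative, degenerate = TRUE),
                       class = "prlTTest"))
    tt <- stats::t.test(x, alternative = alternative)
    d <- mean(x) / stats::sd(x)
  } else if (kind == "paired") {
    if (length(a) != length(b)) stop("paired samples must be matched")
    x <- a - b
    if (length(x) < 2) stop("need n >= 2")
    if (stats::sd(x) == 0)
      return(structure(list(statistic = 0, df = length(x) - 1, p = 1,
                            d = 0, kind = kind, alternative = alternative,
                            degenerate = TRUE), class = "prlTTest"))
    tt <- stats::t.test(x, alternative = alternative)
    d <- mean(x) / stats::sd(x)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) *
              stats::var(b)) / (length(a) + length(b) - 2)
    if (sp2 == 0)
      return(structure(list(statistic = NA_real_,
                            df = length(a) + length(b) - 2, p = NA_real_,
                            d = NA_real_, kind = kind,
                            alternative = alternative, degenerate = TRUE),
                       class = "prlTTest"))
    tt <- stats::t.test(a, b, var.equal = TRUE, alternative = alternative)
    d <- (mean(a) - mean(b)) / sqrt(sp2)
  }
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = d, kind = kind,
                 alternative = alternative, degenerate = FALSE),
            class = "prlTTest")
}

#' @export
print.prlTTest <- function(x, ...) {
  cat(sprintf("%s t(%g) = %.3f, p = %.4g, Cohen's d = %.3f\n",
              x$kind, x$df, x$statistic, x$p, x$d))
  invisible(x)
}

#' Mixed-design 2 x 2 x group repeated-measures ANOVA
#'
#' Classical univariate mixed-model ANOVA with two two-level
#' within-subject factors (behaviour strategy, feedback) and one
#' between-subject factor (learner group), fitted with [stats::aov()]
#' error strata \code{Error(subject/(A*B))}. With two-level within
#' factors no sphericity correction is required. Partial eta squared is
#' \code{SS_effect / (SS_effect + SS_error)} with each effect's own
#' stratum error. Subjects with incomplete 2 x 2 cells are dropped with a
#' message. Degrees of freedom are those implied by the data.
#'
#' @param data long-format data.frame.
#' @param dv name of the response column.
#' @param within length-2 character: within-subject factor columns
#'   (strategy, feedback).
#' @param between name of the group column.
#' @param id name of the subject column.
#' @return data.frame of class \code{"prlAnova"}: one row per effect with
#'   \code{df1}, \code{df2}, \code{SS}, \code{F}, \code{p}, \code{pes}.
#' @export
mixedAnova <- function(data, dv, within, between, id = "subject") {
  stopifnot(length(within) == 2)
  d <- data.frame(
    y = data[[dv]],
    A = factor(data[[within[1]]]),
    B = factor(data[[within[2]]]),
    G = factor(data[[between]]),
    S = factor(data[[id]]))
  d <- d[stats::complete.cases(d), ]
  cellCount <- table(d$S)
  bad <- names(cellCount)[cellCount < nlevels(d$A) * nlevels(d$B)]
  if (length(bad)) {
    message("dropping subject(s) with incomplete cells: ",
            paste(bad, collapse = ", "))
    d <- d[!d$S %in% bad, ]
    d$S <- droplevels(d$S)
  }
  fit <- stats::aov(y ~ G * A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)

  grab <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    r <- match("Residuals", rn)
    c(df1 = tab[i, "Df"], df2 = tab[r, "Df"],
      SS = tab[i, "Sum Sq"], SSe = tab[r, "Sum Sq"],
      F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  rows <- rbind(
    strategy = grab("Error: S:A", "A"),
    learner = grab("Error: S", "G"),
    feedback = grab("Error: S:B", "B"),
    `feedback:strategy` = grab("Error: S:A:B", "A:B"),
    `strategy:learner` = grab("Error: S:A", "G:A"),
    `feedback:learner` = grab("Error: S:B", "G:B"),
    `feedback:strategy:learner` = grab("Error: S:A:B", "G:A:B"))
  out <- data.frame(effect = rownames(rows), rows, row.names = NULL)
  out$pes <- out$SS / (out$SS + out$SSe)
  out$SSe <- NULL
  class(out) <- c("prlAnova", "data.frame")
  out
}

#' @export
print.prlAnova <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$F <- round(y$F, 3)
  y$p <- signif(y$p, 3)
  y$pes <- round(y$pes, 3)
  y$SS <- round(y$SS, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Holm-adjust a vector of p-values
#'
#' The analyses report unadjusted p-values by default (matching common
#' practice for planned ERP contrasts); this helper applies the Holm
#' step-down correction when familywise control is wanted.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
holmAdjust <- function(p) stats::p.adjust(p, method = "holm")
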