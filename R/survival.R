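# Risk stratification and survival comparison. The Kaplan-Meier estimator
# and the two-group log-rank test are computed through the survival
# package (survfit / survdiff); hand-tallied product-limit and risk-set
# oracles in the test suite pin down the conventions used here (deaths
# processed before censorings at tied times, chi-square with 1 df).

#' Split samples into high/low-risk groups at the median predicted risk
#'
#' High risk means a predicted probability strictly above the median;
#' samples at or below the median (including ties at the median) go to the
#' low-risk group.
#'
#' @param pred prediction data.frame with `sample_id` and `probHighRisk`
#'   (see [predictRisk()]), or a named numeric vector of risk scores.
#' @return list with character vectors `high` and `low`.
#' @export
medianRiskSplit <- function(pred) {
  if (is.data.frame(pred)) {
    p <- pred$probHighRisk
    ids <- pred$sample_id
  } else {
    p <- as.numeric(pred)
    ids <- names(pred)
  }
  if (length(p) < 2L) stop("need at least two samples")
  if (max(p) == min(p))
    stop("degenerate risk distribution: all predicted risks identical")
  med <- stats::median(p)
  list(high = ids[p > med], low = ids[p <= med])
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)}
#' over the distinct event times; censored samples leave the risk set
#' after their recorded time.
#'
#' @param times non-negative survival times.
#' @param events 1 = death observed, 0 = censored.
#' @param group optional label stored with the curve.
#' @return list of class `survivalCurve` with `time` (distinct event
#'   times), `surv` (step values), `nRisk`, `nEvent`, `group`.
#' @export
kaplanMeier <- function(times, events, group = "all") {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 nRisk = fit$n.risk[keep], nEvent = fit$n.event[keep],
                 group = group),
            class = "survivalCurve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a `survivalCurve` from [kaplanMeier()].
#' @param t times at which to read off S(t).
#' @return numeric vector of survival probabilities (S = 1 before the
#'   first event).
#' @export
kmSurvival <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$surv[max(idx)]
  }, numeric(1L))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed group-1 events are compared
#' with the hypergeometric expectation \eqn{e = d\,n_1/n} with variance
#' \eqn{v = d\,n_1 n_2 (n-d) / (n^2 (n-1))}; the statistic
#' \eqn{\chi^2 = (\sum (o-e))^2 / \sum v} is referred to the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param times1,events1 survival data of group 1.
#' @param times2,events2 survival data of group 2.
#' @return list of class `logrankResult`: `chiSquare`, `pValue`,
#'   `groupSizes`, `observed`, `expected`.
#' @export
logrankTest <- function(times1, events1, times2, events2) {
  if (length(times1) == 0L || length(times2) == 0L)
    stop("both groups must be non-empty")
  if (sum(events1) + sum(events2) == 0)
    stop("no events in either group")
  times <- c(times1, times2)
  events <- c(events1, events2)
  grp <- rep(c(1L, 2L), c(length(times1), length(times2)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  chi <- unname(sd$chisq)
  structure(list(chiSquare = chi,
                 pValue = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 groupSizes = c(length(times1), length(times2)),
                 observed = unname(sd$obs), expected = unname(sd$exp)),
            class = "logrankResult")
}

#' Survival analysis of model-stratified risk groups
#'
#' Convenience wrapper: split samples at the median predicted risk, fit
#' Kaplan-Meier curves per group, and run the log-rank test against the
#' observed survival data.
#'
#' @param pred prediction data.frame ([predictRisk()]).
#' @param clinical clinical data.frame with `sample_id`, `survival_time`,
#'   `event` covering the predicted samples.
#' @return list with `groups`, `curves` (high/low `survivalCurve`s) and
#'   `logrank` (a `logrankResult`).
#' @export
survivalAnalysis <- function(pred, clinical) {
  clinical <- validateClinical(clinical)
  rownames(clinical) <- clinical$sample_id
  groups <- medianRiskSplit(pred)
  hi <- clinical[groups$high, ]
  lo <- clinical[groups$low, ]
  if (anyNA(hi$sample_id) || anyNA(lo$sample_id))
    stop("clinical data missing for some predicted samples")
  list(groups = groups,
       curves = list(
         high = kaplanMeier(hi$survival_time, hi$event, "high"),
         low = kaplanMeier(lo$survival_time, lo$event, "low")),
       logrank = logrankTest(hi$survival_time, hi$event,
                             lo$survival_time, lo$event))
}

#' @export
print.survivalCurve <- function(x, ...) {
  cat("Kaplan-Meier curve (", x$group, "): ", length(x$time),
      " event time(s), final S = ",
      if (length(x$surv)) signif(x$surv[length(x$surv)], 4) else 1,
      "\n", sep = "")
  invisible(x)
}

#' @export
print.logrankResult <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (1 df), p = %.4g\n",
              x$chiSquare, x$pValue))
  cat(sprintf("  group sizes %d/%d, observed events %.0f/%.0f, expected %.2f/%.2f\n",
              x$groupSizes[1], x$groupSizes[2], x$observed[1], x$observed[2],
              x$expected[1], x$expected[2]))
  invisible(x)
}

#' Plot Kaplan-Meier curves for the two risk groups
#'
#' Base-graphics step plot of the high- and low-risk survival curves.
#'
#' @param curves list with `high` and `low` `survivalCurve`s (see
#'   [survivalAnalysis()]).
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plotSurvivalCurves <- function(curves, main = "Risk-stratified survival") {
  xmax <- max(c(curves$high$time, curves$low$time, 1))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = "Time",
                 ylab = "Survival probability", main = main)
  for (i in 1:2) {
    cv <- curves[[c("high", "low")[i]]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = c(2, 4)[i],
                    do.points = FALSE, lwd = 2)
  }
  graphics::legend("bottomleft", legend = c("high risk", "low risk"),
                   col = c(2, 4), lwd = 2, bty = "n")
  invisible(NULL)
}
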