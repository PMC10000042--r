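# Clinical statistics: group comparisons and time-to-event association of
# the methylation score with watchful-waiting time and progression-free
# survival.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test: sums hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0)) stop("negative cell counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Univariate Cox proportional hazards fit
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson and reports
#' the hazard ratio with Wald 95% confidence interval and p-value.
#'
#' @param times follow-up times (>= 0).
#' @param events logical/0-1 event indicators; at least one event required.
#' @param covariate numeric or logical covariate; must vary.
#' @param name covariate label for the output.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `cox_fit`: list with `name`, `beta`, `hr`,
#'   `ci95`, `p`, `se`, `n`, `n_events`, `converged`.
#' @export
cox_univariate <- function(times, events, covariate, name = "covariate",
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  events <- as.logical(events)
  covariate <- as.numeric(covariate)
  stopifnot(length(times) == length(events),
            length(times) == length(covariate), all(times >= 0))
  if (sum(events) < 1L) stop("need at least one event")
  if (stats::sd(covariate) == 0) stop("covariate does not vary")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariate, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(stats::vcov(fit))))
  z <- beta / se
  structure(
    list(name = name, beta = beta, hr = exp(beta),
         ci95 = exp(beta + c(-1, 1) * 1.96 * se),
         p = 2 * stats::pnorm(-abs(z)), se = se,
         n = length(times), n_events = sum(events), converged = converged),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s: HR %.2f (95%% CI %.2f-%.2f), p = %.4g, %d events/%d%s\n",
              x$name, x$hr, x$ci95[1], x$ci95[2], x$p, x$n_events, x$n,
              if (x$converged) "" else " [non-convergence flagged]"))
  invisible(x)
}

#' Log-rank test for two groups
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param group two-group factor (or coercible).
#' @return list with `chi2` (1 df) and `p`.
#' @export
logrank <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2L || any(table(g) == 0L)) {
    stop("exactly two non-empty groups required")
  }
  if (sum(as.logical(events)) < 1L) stop("need at least one event")
  sd <- survival::survdiff(
    survival::Surv(times, as.logical(events)) ~ g
  )
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring; the curve starts at
#' S(0) = 1.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @return object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `surv` (includes the t = 0 anchor).
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) >= 1L)
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(times), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    surv = c(1, fit$surv))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve a `km_curve`.
#' @param t times at which to evaluate S(t).
#' @export
km_surv_at <- function(curve, t) {
  stats::approx(curve$time, curve$surv, xout = t, method = "constant",
                rule = 2L, f = 0)$y
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact for small untied samples, otherwise the normal approximation with
#' tie correction. Completely tied input returns p = 1 with a warning.
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  if (length(unique(c(x, y))) == 1L) {
    warning("all observations tied: p = 1")
    return(1)
  }
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' @param table contingency table of counts.
#' @return list with `chi2` and `p` (no continuity correction).
#' @export
chi_square <- function(table) {
  res <- suppressWarnings(stats::chisq.test(as.matrix(table), correct = FALSE))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Median follow-up time
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param method `"reverse_km"` (median of the censoring distribution via
#'   the reverse Kaplan-Meier estimator) or `"median"` (plain median of the
#'   observed times).
#' @return median follow-up in the input time unit.
#' @export
median_followup <- function(times, events, method = c("reverse_km", "median")) {
  method <- match.arg(method)
  if (method == "median") return(stats::median(times))
  fit <- survival::survfit(survival::Surv(times, !as.logical(events)) ~ 1)
  unname(summary(fit)$table["median"])
}
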