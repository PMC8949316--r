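#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function (via
#' [survival::survfit]). `S(0) = 1`; the curve is a right-continuous step
#' function dropping only at event times.
#'
#' @param time Positive follow-up times (days).
#' @param event Event indicator (1/TRUE = death observed, 0/FALSE censored).
#' @return A data.frame with columns `time`, `n_risk`, `n_event`, `surv`.
#' @seealso [survivalAt()] to evaluate the step function.
#' @export
#' @examples
#' km <- kmEstimate(c(5, 8, 12, 16, 23), c(0, 1, 1, 0, 1))
#' survivalAt(km, 12)    # 0.5
kmEstimate <- function(time, event) {
  if (length(time) < 1L) stop("at least one record is required")
  if (any(time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' @rdname kmEstimate
#' @param km A data.frame from [kmEstimate()].
#' @param t Times at which to evaluate `S(t)`.
#' @export
survivalAt <- function(km, t) {
  vapply(t, function(tt) {
    i <- which(km$time <= tt & km$n_event > 0)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test on an expression split
#'
#' Splits samples at a quantile of a continuous marker (median by default;
#' ties go to the low group) and compares survival between the two groups by
#' the standard log-rank test: at each event time the observed events in one
#' group are compared with their hypergeometric expectation, giving a 1-df
#' chi-square statistic (via [survival::survdiff]).
#'
#' @param time,event Survival records (see [kmEstimate()]).
#' @param values Continuous marker (e.g. one gene's expression), one value
#'   per sample.
#' @param splitQuantile Split point as a quantile of `values`.
#' @return A list with `chisq`, `p`, `groups` (factor low/high), `obs` and
#'   `exp` (per-group observed/expected events). With no events at all the
#'   convention `chisq = 0, p = 1` applies.
#' @export
logrankTwoGroups <- function(time, event, values, splitQuantile = 0.5) {
  cut <- stats::quantile(values, splitQuantile, names = FALSE)
  groups <- factor(ifelse(values > cut, "high", "low"),
                   levels = c("low", "high"))
  if (any(table(groups) == 0L))
    stop("degenerate split: one group is empty")
  if (sum(event) == 0L)
    return(list(chisq = 0, p = 1, groups = groups,
                obs = c(low = 0, high = 0), exp = c(low = 0, high = 0)))
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ groups)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       groups = groups,
       obs = stats::setNames(sd$obs, levels(groups)),
       exp = stats::setNames(sd$exp, levels(groups)))
}

#' One-way ANOVA with Tukey HSD across subtypes
#'
#' Ordinary one-way ANOVA (F test) followed by the Tukey honest significant
#' difference post-hoc test (studentized-range distribution on the pooled
#' variance), applied identically to expression values or methylation betas.
#'
#' @param values Numeric vector (one value per sample).
#' @param groups Group labels (e.g. molecular subtype), at least 2 groups
#'   with at least 2 values each.
#' @return A list with `groupStats` (per-group n, mean, sd), `F`, `df`, `p`,
#'   and `tukey` (symmetric matrix of pairwise adjusted p-values).
#' @export
subtypeAnovaTukey <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(table(groups) < 2L)) stop("at least 2 values per group are required")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  lev <- levels(groups)
  pm <- matrix(NA_real_, nlevels(groups), nlevels(groups),
               dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  diag(pm) <- 1
  gs <- data.frame(
    group = lev,
    n = as.integer(table(groups)[lev]),
    mean = tapply(values, groups, mean)[lev],
    sd = tapply(values, groups, stats::sd)[lev])
  rownames(gs) <- NULL
  list(groupStats = gs,
       F = an[1, "F value"],
       df = c(an[1, "Df"], an[2, "Df"]),
       p = an[1, "Pr(>F)"],
       tukey = pm)
}
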