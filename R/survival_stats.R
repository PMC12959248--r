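# Elementary statistics of the survival workflow: log transformation,
# quartile grouping, Kaplan-Meier estimation, log-rank tests, Harrell's
# concordance, Spearman correlation and Wilcoxon rank-sum subgroup tests.
# All of these are thin, contract-enforcing wrappers over the survival
# package and base R; the package's own contribution lives in the
# morphometry and synthetic modules.

#' Natural-log transform strictly positive biomarker values
#'
#' The morphological biomarkers are consistently right-skewed; all Cox and
#' logistic models in this package use them on the natural-log scale.
#' Non-positive values are an input error and are reported by case so that
#' cases cannot be dropped silently.
#'
#' @param values numeric vector, all > 0.
#' @param case_ids optional identifiers used in the error message.
#' @return `log(values)`.
#' @export
log_transform <- function(values, case_ids = NULL) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    ids <- if (is.null(case_ids)) paste("index", bad) else case_ids[bad]
    stop(sprintf("log transform requires strictly positive values; offending case(s): %s",
                 paste(utils::head(ids, 10), collapse = ", ")))
  }
  log(values)
}

#' Split a biomarker into quartile groups Q1-Q4
#'
#' Sample quartiles use the type-7 (linear interpolation) definition;
#' values tied with a boundary fall in the lower group.  With distinct
#' values the group sizes are equal up to one case.
#'
#' @param values numeric vector, length >= 4.
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return factor with levels Q1..Q4.
#' @export
quartile_groups <- function(values, type = 7) {
  if (length(values) < 4L) stop("need at least 4 cases to form quartiles")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  if (any(duplicated(qs)))
    stop("cannot form quartiles: tied quartile boundaries (values nearly constant)")
  cut(values, breaks = c(-Inf, qs, Inf), labels = paste0("Q", 1:4),
      right = TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @return a `km_curve`: list with `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (any(times < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event), class = "km_curve")
}

#' K-sample log-rank test
#'
#' @param times,events as in [km_estimate()].
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `chi2`, `df` (k - 1) and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Over usable pairs (the subject with the shorter time has an event),
#' the proportion in which the higher risk score belongs to the shorter
#' survival time; tied scores count 1/2, pairs with tied event times are
#' unusable.
#'
#' @param risk_scores higher = higher predicted risk.
#' @param times,events survival outcome.
#' @return concordance in \[0, 1\].
#' @export
harrells_c <- function(risk_scores, times, events) {
  stopifnot(length(risk_scores) == length(times),
            length(times) == length(events))
  fit <- survival::concordance(
    survival::Surv(times, events) ~ risk_scores, reverse = TRUE)
  counts <- fit$count
  usable <- counts["concordant"] + counts["discordant"] + counts["tied.x"]
  if (usable == 0) stop("no usable pairs for concordance")
  unname(fit$concordance)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; constant input is an error rather
#' than a silent `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Two-sided Wilcoxon rank-sum subgroup test
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties; otherwise the normal approximation with tie correction.
#'
#' @param values biomarker values.
#' @param group two-level grouping (logical or factor).
#' @return list with `statistic` (rank-sum W) and `p`.
#' @export
wilcoxon_subgroup <- function(values, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("subgroup test needs exactly 2 groups")
  sizes <- table(group)
  if (any(sizes == 0L)) stop("both groups must be non-empty")
  x <- values[group == levels(group)[1]]
  y <- values[group == levels(group)[2]]
  exact <- length(x) <= 10L && length(y) <= 10L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
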