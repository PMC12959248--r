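# Cox proportional-hazards evaluation of the log-transformed biomarkers:
# adjusted/unadjusted fits, bootstrap percentile intervals, Schoenfeld
# proportional-hazards diagnostics, and the five-year logistic/ROC
# comparison.  Confounder adjustment follows a fixed covariate set
# {age, sex, site}: age enters as continuous years, sex as male vs female
# and anatomical site as central (head/trunk) vs peripheral (limbs).

.param_cols <- c(area = "area_mm2", perimeter = "perimeter_mm",
                 major = "major_mm", dbt = "dbt_mm", ni = "ni",
                 breslow = "breslow_mm")

.param_col <- function(parameter, cohort) {
  col <- if (parameter %in% names(.param_cols)) .param_cols[[parameter]]
         else parameter
  if (!col %in% names(cohort))
    stop(sprintf("parameter column '%s' not found in cohort", col))
  col
}

.endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(toupper(endpoint), c("OS", "MSS"))
  if (endpoint == "OS") c(time = "time_os", event = "event_os")
  else c(time = "time_mss", event = "event_mss")
}

.cox_frame <- function(cohort, parameter, endpoint, adjusted) {
  col <- .param_col(parameter, cohort)
  ep <- .endpoint_cols(endpoint)
  d <- data.frame(time = cohort[[ep["time"]]],
                  event = cohort[[ep["event"]]],
                  value = cohort[[col]],
                  stringsAsFactors = FALSE)
  if (adjusted) {
    d$age <- cohort$age
    d$male <- as.integer(cohort$sex == "male")
    d$central <- as.integer(cohort$site == "central")
  }
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  d$log_value <- log_transform(d$value, cohort$case_id[keep])
  list(data = d, n_dropped = n_dropped)
}

#' Fit a Cox proportional-hazards model for one biomarker
#'
#' One biomarker per model, on the natural-log scale, optionally adjusted
#' for age (continuous years), sex and site; Efron handling of tied event
#' times.  Cases with a missing covariate are dropped (complete-case) and
#' counted in `n_dropped`.  Harrell's C of the model's linear predictor is
#' attached.
#'
#' @param cohort cohort data frame (see [read_cohort_table()]).
#' @param parameter one of `"area"`, `"perimeter"`, `"major"`, `"dbt"`,
#'   `"ni"`, `"breslow"`, or a raw column name.
#' @param endpoint `"OS"` or `"MSS"`.
#' @param adjusted adjust for age, sex and site?
#' @return a `cox_result`: list with `parameter`, `endpoint`, `adjusted`,
#'   `hr`, `ci_low`, `ci_high` (Wald 95%), `p` (Wald), `beta`, `se`,
#'   `c_index`, `n`, `n_events`, `n_dropped` and the `fit` object.
#' @export
fit_cox <- function(cohort, parameter, endpoint = "OS", adjusted = TRUE) {
  fr <- .cox_frame(cohort, parameter, endpoint, adjusted)
  d <- fr$data
  rhs <- if (adjusted) "log_value + age + male + central" else "log_value"
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(warn) && grepl("converge|infinite|beta may be infinite", warn))
    stop(sprintf("Cox model did not converge for %s/%s: %s",
                 parameter, endpoint, warn))
  sm <- summary(fit)
  i <- "log_value"
  beta <- unname(coef(fit)[i])
  se <- unname(sqrt(diag(fit$var))[which(names(coef(fit)) == i)])
  structure(list(
    parameter = parameter, endpoint = toupper(endpoint), adjusted = adjusted,
    hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p = unname(sm$coefficients[i, "Pr(>|z|)"]),
    beta = beta, se = se,
    c_index = unname(fit$concordance["concordance"]),
    n = nrow(d), n_events = sum(d$event), n_dropped = fr$n_dropped,
    fit = fit), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox %s model, %s, log(%s): HR %.3f (95%% CI %.3f-%.3f), p = %.2g, C = %.3f, n = %d (%d events, %d dropped)\n",
              if (x$adjusted) "adjusted" else "unadjusted", x$endpoint,
              x$parameter, x$hr, x$ci_low, x$ci_high, x$p, x$c_index, x$n,
              x$n_events, x$n_dropped))
  invisible(x)
}

#' Bootstrap percentile confidence interval for a Cox hazard ratio
#'
#' Lossless non-parametric case resampling with replacement; the model is
#' refit on each replicate and the 2.5/97.5 percentiles of the replicate
#' hazard ratios are returned.  Replicates that fail to converge are
#' dropped and counted; more than 10% failures is an error.
#'
#' @param cohort,parameter,endpoint,adjusted as in [fit_cox()].
#' @param B number of replicates (>= 1; the study default is 1000).
#' @param seed mandatory RNG seed; identical seeds give identical
#'   intervals.
#' @return list with `ci_low`, `ci_high`, `B`, `n_failed` and the
#'   replicate hazard ratios `hr`.
#' @export
bootstrap_cox <- function(cohort, parameter, endpoint = "OS", adjusted = TRUE,
                          B = 1000, seed) {
  if (missing(seed)) stop("bootstrap_cox requires an explicit seed")
  if (B < 1) stop("B must be >= 1")
  n <- nrow(cohort)
  hrs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_cox(cohort[idx, , drop = FALSE], parameter, endpoint,
                       adjusted)$hr,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(hrs))
  if (n_failed > 0.1 * B)
    stop(sprintf("bootstrap unstable: %d/%d replicates failed to converge",
                 n_failed, B))
  ok <- hrs[!is.na(hrs)]
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], B = B, n_failed = n_failed, hr = ok)
}

#' Schoenfeld-residual check of the proportional-hazards assumption
#'
#' Scaled Schoenfeld residuals are tested for a trend in (KM-transformed)
#' event time, per covariate and globally; the residual-vs-time points are
#' returned for plotting.
#'
#' @param fit a fitted `coxph` model or a `cox_result`.
#' @return list with `p` (named per-covariate p-values plus `GLOBAL`),
#'   `table` (the cox.zph table) and `residuals` (list with `time` and the
#'   residual matrix `y`).
#' @export
schoenfeld_ph_check <- function(fit) {
  if (inherits(fit, "cox_result")) fit <- fit$fit
  stopifnot(inherits(fit, "coxph"))
  n_cov <- length(coef(fit))
  if (fit$nevent <= n_cov)
    stop("too few events for a proportional-hazards check")
  z <- survival::cox.zph(fit, transform = "km")
  list(p = z$table[, "p"], table = z$table,
       residuals = list(time = z$x, y = z$y))
}

# Five-year logistic / ROC comparison ---------------------------------------

.ajcc_levels <- c("IA", "IB", "IIA", "IIB", "IIC", "IIIA", "IIIB", "IIIC",
                  "IVA", "IVB")

.logistic_predictor <- function(cohort, name) {
  if (name %in% c("ajcc", "ajcc_stage")) {
    if (!"ajcc_stage" %in% names(cohort)) stop("cohort has no ajcc_stage column")
    v <- cohort$ajcc_stage
    if (is.numeric(v)) return(v)
    # ordinal stage score; unknown stages become missing
    return(as.numeric(match(toupper(trimws(as.character(v))), .ajcc_levels)))
  }
  log(cohort[[.param_col(name, cohort)]])
}

#' Logistic-regression / ROC comparison for melanoma-specific survival at
#' five years
#'
#' The outcome is melanoma death within 5 years.  Subjects censored alive
#' before 5 years carry no 5-year status and are excluded (their count is
#' reported); subjects followed past 5 years without melanoma death are
#' controls.  Morphometric predictors enter on the log scale, AJCC stage
#' as an ordinal score.  The AUC is the area under the empirical ROC curve
#' of the fitted probabilities (trapezoidal rule).
#'
#' @param cohort cohort data frame.
#' @param predictors character vector, e.g. `c("dbt", "ni")`, `"breslow"`,
#'   `"ajcc"`.
#' @param horizon outcome horizon in years (default 5).
#' @return a `roc_result`: list with `predictors`, `auc`, `n_used`,
#'   `n_events`, `n_excluded`, `separation` flag and the ROC `curve`
#'   (sensitivities/specificities).
#' @export
logistic_5yr <- function(cohort, predictors, horizon = 5) {
  case <- cohort$event_mss == 1 & cohort$time_mss <= horizon
  control <- cohort$time_mss >= horizon & !case
  usable <- case | control
  d <- data.frame(outcome = as.integer(case[usable]))
  for (p in predictors) d[[p]] <- .logistic_predictor(cohort, p)[usable]
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  n_excluded <- sum(!usable) + sum(!keep)
  if (sum(d$outcome) < 10)
    stop(sprintf("too few events for 5-year logistic model (%d < 10)",
                 sum(d$outcome)))
  separation <- FALSE
  fml <- stats::as.formula(paste("outcome ~",
                                 paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  prob <- stats::predict(fit, type = "response")
  if (stats::sd(prob) == 0) {
    # constant predictor: chance discrimination by definition
    roc <- NULL
    auc <- 0.5
  } else {
    roc <- pROC::roc(response = d$outcome, predictor = prob, quiet = TRUE,
                     levels = c(0, 1), direction = "<")
    auc <- as.numeric(pROC::auc(roc))
  }
  structure(list(predictors = predictors, auc = auc, n_used = nrow(d),
                 n_events = sum(d$outcome), n_excluded = n_excluded,
                 separation = separation,
                 curve = if (is.null(roc)) NULL else
                   list(sensitivity = roc$sensitivities,
                        specificity = roc$specificities),
                 fit = fit), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("5-year MSS logistic model {%s}: AUC %.3f (n = %d, %d events, %d excluded)%s\n",
              paste(x$predictors, collapse = ", "), x$auc, x$n_used,
              x$n_events, x$n_excluded,
              if (x$separation) " [separation warning]" else ""))
  invisible(x)
}
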