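# The full survival workflow, in the order of the study design:
# quartile Kaplan-Meier curves with log-rank tests, then one Cox model per
# biomarker per endpoint (adjusted and unadjusted), bootstrap resampling
# of the adjusted models, concordance indices, proportional-hazards
# diagnostics, five-year logistic/ROC comparisons, a collinearity check
# of the adjustment set and Wilcoxon subgroup contrasts.  The family-wise
# significance threshold is p <= 0.001 throughout; raw p-values are
# always reported and the threshold only sets a flag.

.morph_params <- c("area", "perimeter", "major", "dbt", "ni")

# optional binary clinical subgroup columns the subgroup analysis knows
# how to interpret (value coding: present/absent or the named contrast)
.subgroup_defs <- list(
  ulceration = c("present", "absent"),
  vascular_invasion = c("present", "absent"),
  mitotic_rate_ge1 = c("1", "0"),
  subtype_ssm_vs_nm = NULL)   # derived from `subtype` below

#' Run the complete survival analysis on a cohort
#'
#' @param cohort cohort data frame (schema of [read_cohort_table()]) with
#'   at least 50 cases.
#' @param params biomarkers to analyse (default all five).
#' @param endpoints endpoints to analyse (`"OS"`, `"MSS"`).
#' @param B bootstrap replicates for the adjusted models (0 disables the
#'   bootstrap; the study default is 1000).
#' @param seed RNG seed for the bootstrap.
#' @param alpha family-wise significance threshold used for flags.
#' @param roc_horizon horizon (years) of the logistic/ROC comparison.
#' @return an `analysis_report` (nested list, JSON-serializable apart from
#'   the embedded KM curves): `quartiles`, `cox`, `roc`, `collinearity`,
#'   `subgroups`, `meta`.
#' @export
run_survival_analysis <- function(cohort,
                                  params = .morph_params,
                                  endpoints = c("OS", "MSS"),
                                  B = 1000, seed = .default_seed,
                                  alpha = 0.001, roc_horizon = 5) {
  if (nrow(cohort) < 50)
    stop("survival analysis requires at least 50 cases for stable quartiles")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  quartiles <- list()
  cox <- list()
  for (p in params) {
    col <- .param_col(p, cohort)
    grp <- stage("quartiles", quartile_groups(cohort[[col]]))
    for (ep in endpoints) {
      epc <- .endpoint_cols(ep)
      lr <- stage("logrank",
                  logrank_test(cohort[[epc["time"]]], cohort[[epc["event"]]], grp))
      curves <- lapply(levels(grp), function(g) {
        sel <- grp == g
        km <- km_estimate(cohort[[epc["time"]]][sel], cohort[[epc["event"]]][sel])
        list(group = g, n = sum(sel), time = km$time, surv = km$surv)
      })
      quartiles[[paste(p, ep, sep = "_")]] <-
        list(parameter = p, endpoint = ep, logrank = lr,
             significant = lr$p <= alpha, curves = curves)
      for (adj in c(TRUE, FALSE)) {
        f <- stage("cox", fit_cox(cohort, p, ep, adjusted = adj))
        entry <- list(parameter = p, endpoint = ep, adjusted = adj,
                      hr = f$hr, ci_low = f$ci_low, ci_high = f$ci_high,
                      p = f$p, c_index = f$c_index, n = f$n,
                      n_events = f$n_events, n_dropped = f$n_dropped,
                      significant = f$p <= alpha)
        if (adj) {
          entry$ph <- tryCatch(as.list(schoenfeld_ph_check(f)$p),
                               error = function(e) NULL)
          if (B > 0) {
            bs <- stage("bootstrap",
                        bootstrap_cox(cohort, p, ep, adjusted = TRUE, B = B,
                                      seed = seed))
            entry$bootstrap_ci <- c(bs$ci_low, bs$ci_high)
            entry$bootstrap_failed <- bs$n_failed
          }
        }
        cox[[paste(p, ep, if (adj) "adj" else "unadj", sep = "_")]] <- entry
      }
    }
  }
  # five-year logistic / ROC comparison on MSS
  roc_sets <- list(c("dbt"), c("ni"), c("dbt", "ni"))
  if ("breslow_mm" %in% names(cohort)) roc_sets <- c(list("breslow"), roc_sets)
  if ("ajcc_stage" %in% names(cohort))
    roc_sets <- c(roc_sets, list("ajcc"), list(c("ajcc", "ni")))
  roc <- lapply(roc_sets, function(ps) {
    r <- tryCatch(logistic_5yr(cohort, ps, horizon = roc_horizon),
                  error = function(e) NULL)
    if (is.null(r)) NULL
    else list(predictors = ps, auc = r$auc, n_used = r$n_used,
              n_events = r$n_events, n_excluded = r$n_excluded)
  })
  roc <- roc[!vapply(roc, is.null, logical(1))]
  # collinearity of the adjustment set (rank correlations)
  num <- data.frame(age = cohort$age,
                    male = as.numeric(cohort$sex == "male"),
                    central = as.numeric(cohort$site == "central"))
  cc <- stats::complete.cases(num)
  collinearity <- list(
    age_sex = spearman_rho(num$age[cc], num$male[cc]),
    age_site = spearman_rho(num$age[cc], num$central[cc]),
    sex_site = spearman_rho(num$male[cc], num$central[cc]))
  if ("breslow_mm" %in% names(cohort)) {
    ok <- stats::complete.cases(cohort$dbt_mm, cohort$breslow_mm)
    collinearity$dbt_breslow <- spearman_rho(cohort$dbt_mm[ok],
                                             cohort$breslow_mm[ok])
  }
  # subgroup contrasts for whichever clinical columns are present
  subgroups <- list()
  sub_cols <- list()
  for (nm in names(.subgroup_defs)) {
    if (nm == "subtype_ssm_vs_nm") {
      if (!"subtype" %in% names(cohort)) next
      v <- tolower(as.character(cohort$subtype))
      g <- ifelse(v %in% c("superficial spreading", "ssm"), "ssm",
                  ifelse(v %in% c("nodular", "nm"), "nm", NA))
    } else {
      if (!nm %in% names(cohort)) next
      v <- tolower(as.character(cohort[[nm]]))
      g <- ifelse(v == .subgroup_defs[[nm]][1], "yes",
                  ifelse(v == .subgroup_defs[[nm]][2], "no", NA))
    }
    sub_cols[[nm]] <- g
  }
  for (nm in names(sub_cols)) {
    g <- sub_cols[[nm]]
    for (p in params) {
      col <- .param_col(p, cohort)
      ok <- !is.na(g) & !is.na(cohort[[col]])
      if (length(unique(g[ok])) != 2L) next
      w <- wilcoxon_subgroup(cohort[[col]][ok], g[ok])
      subgroups[[paste(nm, p, sep = "_")]] <-
        list(subgroup = nm, parameter = p, statistic = w$statistic,
             p = w$p, significant = w$p <= alpha)
    }
  }
  structure(list(
    quartiles = quartiles, cox = cox, roc = roc,
    collinearity = collinearity, subgroups = subgroups,
    meta = list(n = nrow(cohort), params = params, endpoints = endpoints,
                B = B, seed = seed, alpha = alpha,
                n_flagged = sum(vapply(cox, function(e) isTRUE(e$significant),
                                       logical(1))))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Survival analysis report: n = %d, %d Cox fits, threshold p <= %g\n",
              x$meta$n, length(x$cox), x$meta$alpha))
  for (e in x$cox) {
    if (!e$adjusted) next
    cat(sprintf("  %-9s %-3s adj: HR %.2f (%.2f-%.2f) p=%.2g C=%.3f%s\n",
                e$parameter, e$endpoint, e$hr, e$ci_low, e$ci_high, e$p,
                e$c_index, if (e$significant) " *" else ""))
  }
  if (length(x$roc)) {
    cat("  5-year MSS ROC:\n")
    for (r in x$roc)
      cat(sprintf("    {%s}: AUC %.3f\n", paste(r$predictors, collapse = "+"),
                  r$auc))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' KM curves are retained; the output is deterministic for a fixed cohort,
#' seed and option set (no timestamps).
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
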