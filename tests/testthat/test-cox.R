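# Cox modelling, bootstrap, proportional-hazards diagnostics and the
# five-year logistic/ROC comparison.

# wrap a simple (time, event, x) frame into the cohort schema, with x as
# a positive biomarker column
as_cox_cohort <- function(d, seed = 1) {
  co <- make_toy_cohort(nrow(d), seed = seed)
  co$time_os <- co$time_mss <- d$time
  co$event_os <- co$event_mss <- d$event
  co$dbt_mm <- exp(d$x)          # log(dbt) == x
  co
}

test_that("a covariate unrelated to survival gives HR near 1", {
  d <- make_binary_cohort(3000, hr = 1, seed = 10)
  f <- fit_cox(as_cox_cohort(d), "dbt", "OS", adjusted = FALSE)
  expect_gt(f$p, 0.001)
  expect_true(f$ci_low <= 1 && 1 <= f$ci_high)
})

test_that("a true hazard ratio of 2 is recovered within the Wald CI", {
  d <- make_binary_cohort(2000, hr = 2, seed = 11)
  f <- fit_cox(as_cox_cohort(d), "dbt", "OS", adjusted = FALSE)
  expect_true(f$ci_low <= 2 && 2 <= f$ci_high)
  expect_equal(f$hr, 2, tolerance = 0.15)
  # attached concordance agrees with the standalone statistic
  expect_equal(f$c_index,
               harrells_c(d$x, d$time, d$event), tolerance = 1e-8)
})

test_that("Cox score test equals the log-rank statistic without ties", {
  withr::with_seed(12, {
    n <- 120
    x <- rbinom(n, 1, 0.5)
    t_death <- rexp(n, 0.4 * 1.8^x)       # continuous: no ties
    c_time <- runif(n, 0, 4)
    time <- pmin(t_death, c_time)
    event <- as.integer(t_death <= c_time)
  })
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  sc <- summary(fit)$sctest[["test"]]
  lr <- logrank_test(time, event, x)
  expect_equal(sc, lr$chi2, tolerance = 1e-6)
})

test_that("adjusted fits drop incomplete cases with a count", {
  co <- generate_cohort(cohort_spec(n = 300, seed = 5))$cohort
  co$site[1:3] <- NA
  f <- fit_cox(co, "dbt", "OS", adjusted = TRUE)
  expect_equal(f$n_dropped, 3)
  expect_equal(f$n, 297)
})

test_that("bootstrap CIs are seed-reproducible and degenerate at B = 1", {
  co <- generate_cohort(cohort_spec(n = 200, seed = 6))$cohort
  b1 <- bootstrap_cox(co, "dbt", "OS", B = 40, seed = 123)
  b2 <- bootstrap_cox(co, "dbt", "OS", B = 40, seed = 123)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_lte(b1$ci_low, b1$ci_high)
  d1 <- bootstrap_cox(co, "dbt", "OS", B = 1, seed = 9)
  expect_equal(d1$ci_low, d1$ci_high)
  expect_equal(d1$ci_low, d1$hr[1])
  expect_error(bootstrap_cox(co, "dbt", "OS", B = 10), "seed")
})

test_that("bootstrap percentile CI covers the true coefficient ~95%", {
  covered <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    d <- make_binary_cohort(150, hr = 2, seed = 1000 + r)
    co <- as_cox_cohort(d, seed = r)
    bs <- bootstrap_cox(co, "dbt", "OS", adjusted = FALSE, B = 120,
                        seed = 2000 + r)
    if (bs$ci_low <= 2 && 2 <= bs$ci_high) covered <- covered + 1
  }
  expect_gte(covered / n_rep, 0.85)
})

test_that("Schoenfeld diagnostics report one p per covariate plus GLOBAL", {
  co <- generate_cohort(cohort_spec(n = 400, seed = 8))$cohort
  f <- fit_cox(co, "dbt", "OS", adjusted = TRUE)
  ph <- schoenfeld_ph_check(f)
  expect_named(ph$p, c("log_value", "age", "male", "central", "GLOBAL"))
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  # too few events
  tiny <- co[1:8, ]; tiny$event_os <- c(1, rep(0, 7))
  f2 <- suppressWarnings(
    survival::coxph(survival::Surv(time_os, event_os) ~ age + dbt_mm,
                    data = tiny))
  expect_error(schoenfeld_ph_check(f2), "few events")
})

test_that("Schoenfeld p-values behave under the null and under violation", {
  # proportional hazards hold: p should not be systematically small
  ps <- vapply(1:10, function(s) {
    d <- make_binary_cohort(300, hr = 1.5, seed = 300 + s)
    f <- survival::coxph(survival::Surv(time, event) ~ x, data = d)
    schoenfeld_ph_check(f)$p[["GLOBAL"]]
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_gt(min(ps), 1e-4)
  # effect that reverses sign over time is flagged
  hits <- 0
  for (s in 1:5) {
    withr::with_seed(400 + s, {
      n <- 400
      x <- rbinom(n, 1, 0.5)
      # early hazard doubled for x = 1, late hazard halved
      t1 <- rexp(n, 0.8 * 2^x)
      t2 <- 0.8 + rexp(n, 0.8 * 2^(-x))
      time <- ifelse(t1 < 0.8, t1, t2)
      event <- rep(1L, n)
    })
    f <- survival::coxph(survival::Surv(time, event) ~ x)
    if (schoenfeld_ph_check(f)$p[["GLOBAL"]] < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("five-year logistic AUC matches the Mann-Whitney oracle", {
  # deterministic 4-point example: AUC = 3/4 by explicit pair count
  co <- make_toy_cohort(4)
  co$time_mss <- c(10, 10, 2, 3)
  co$event_mss <- c(0, 0, 1, 1)
  co$event_os <- pmax(co$event_os, co$event_mss)
  co$dbt_mm <- exp(c(0.1, 0.4, 0.35, 0.8))
  o <- oracle_auc(log(co$dbt_mm), co$event_mss)
  expect_equal(o, 0.75)
  co10 <- co[rep(1:4, 5), ]   # replicate to pass the >= 10 events guard
  r <- logistic_5yr(co10, "dbt")
  expect_equal(r$auc, o, tolerance = 1e-9)
  # random instances, n <= 50
  withr::with_seed(20, {
    for (i in 1:10) {
      n <- sample(30:50, 1)
      co2 <- make_toy_cohort(n, seed = 100 + i)
      co2$time_mss <- runif(n, 0, 12)
      co2$event_mss <- rbinom(n, 1, 0.6)
      r2 <- tryCatch(logistic_5yr(co2, "dbt"), error = function(e) NULL)
      if (is.null(r2)) next
      # the ROC is built on the fitted probabilities
      expect_equal(r2$auc, oracle_auc(stats::fitted(r2$fit), r2$fit$y),
                   tolerance = 1e-9)
    }
  })
})

test_that("five-year logistic handles separation, constancy and exclusions", {
  co <- make_toy_cohort(60, seed = 21)
  co$time_mss <- runif(60, 6, 15)
  co$event_mss <- 0L
  cases <- 1:15
  co$time_mss[cases] <- runif(15, 0.5, 4.5)
  co$event_mss[cases] <- 1L
  co$event_os <- pmax(co$event_os, co$event_mss)
  # perfectly separating predictor -> AUC 1 (flagged, not an error)
  co$dbt_mm <- ifelse(co$event_mss == 1, 10, 1) * exp(runif(60, 0, 0.1))
  r <- logistic_5yr(co, "dbt")
  expect_equal(r$auc, 1)
  # constant predictor -> chance
  co$dbt_mm <- rep(2, 60)
  expect_equal(logistic_5yr(co, "dbt")$auc, 0.5)
  # censored-before-horizon subjects are excluded and counted
  co$dbt_mm <- rlnorm(60, log(2), 0.5)
  co$event_mss[16:20] <- 0L
  co$time_mss[16:20] <- 2
  r3 <- logistic_5yr(co, "dbt")
  expect_equal(r3$n_excluded, 5)
  expect_equal(r3$n_used, 55)
  # fewer than 10 events is an error
  co$event_mss[cases[6:15]] <- 0L
  co$time_mss[cases[6:15]] <- 8
  expect_error(logistic_5yr(co, "dbt"), "too few events")
})

test_that("AJCC stage enters the ROC comparison as an ordinal score", {
  co <- make_toy_cohort(80, seed = 22)
  withr::with_seed(23, {
    co$time_mss <- runif(80, 0, 12)
    co$event_mss <- rbinom(80, 1, 0.5)
    co$event_os <- pmax(co$event_os, co$event_mss)
    co$ajcc_stage <- sample(c("IA", "IB", "IIA", "IIIB"), 80, TRUE)
  })
  r <- logistic_5yr(co, c("ajcc", "ni"))
  expect_true(r$auc >= 0 && r$auc <= 1)
  expect_equal(r$predictors, c("ajcc", "ni"))
})
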