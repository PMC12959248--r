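# Independent oracles and fixture builders shared by the test files.
# Each oracle is a deliberately naive reimplementation (brute force,
# enumeration, closed form) kept independent of the code paths it checks.

# minimum-area enclosing rectangle by a dense rotation sweep
oracle_min_rect_area <- function(pts, step_deg = 0.01) {
  th <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  best <- Inf
  for (t in th) {
    c1 <- pts[, 1] * cos(t) + pts[, 2] * sin(t)
    c2 <- -pts[, 1] * sin(t) + pts[, 2] * cos(t)
    a <- diff(range(c1)) * diff(range(c2))
    if (a < best) best <- a
  }
  best
}

# Harrell's C by explicit pair enumeration (ties in scores count 1/2;
# pairs with tied event times where both die are unusable)
oracle_cindex <- function(score, time, event) {
  num <- 0; den <- 0
  n <- length(score)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        # tied times: both events (no ordering) or both censored -> unusable;
        # a death tied with a censoring precedes it
        if (event[i] == event[j]) next
        s <- if (event[i] == 1) i else j
        l <- if (event[i] == 1) j else i
      } else {
        s <- if (time[i] < time[j]) i else j   # shorter time
        l <- if (time[i] < time[j]) j else i
        if (event[s] != 1) next                # usable iff shorter time has event
      }
      den <- den + 1
      if (score[s] > score[l]) num <- num + 1
      else if (score[s] == score[l]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# AUC by the Mann-Whitney pair count
oracle_auc <- function(score, outcome) {
  cases <- score[outcome == 1]
  ctrls <- score[outcome == 0]
  wins <- 0
  for (a in cases) for (b in ctrls)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(cases) * length(ctrls))
}

# two-group log-rank chi-square from first principles (observed minus
# expected over the risk sets, hypergeometric variance)
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# raster fixtures ------------------------------------------------------------

# centred ellipse mask with a generic sub-pixel offset (avoids lattice
# alignment artefacts); mpp in microns, axes in mm
make_ellipse_mask <- function(a, b, mpp, rot_deg = 0, offset = c(0.0123, 0.0071),
                              case_id = "ellipse") {
  s <- mpp / 1000
  half <- a + 1
  n <- ceiling(2 * half / s)
  xs <- (seq_len(n) - 0.5) * s - half
  X <- matrix(xs + offset[1], n, n, byrow = TRUE)
  Y <- matrix(xs + offset[2], n, n)
  th <- rot_deg * pi / 180
  U <- X * cos(th) + Y * sin(th)
  V <- -X * sin(th) + Y * cos(th)
  segmentation_mask((U / a)^2 + (V / b)^2 <= 1, mpp, mpp, case_id)
}

make_disc_mask <- function(r, mpp, ...) make_ellipse_mask(r, r, mpp, case_id = "disc", ...)

mask_from_matrix <- function(m, mpp = 10, case_id = "toy")
  segmentation_mask(m, mpp, mpp, case_id)

# small survival fixtures -----------------------------------------------------

# exponential survival with a binary covariate of a given hazard ratio and
# uniform censoring; used by the Cox calibration and identity tests
make_binary_cohort <- function(n, hr, seed, cens_max = 3) {
  withr::with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    t_death <- rexp(n, rate = 0.5 * hr^x)
    c_time <- runif(n, 0, cens_max)
    data.frame(time = pmin(t_death, c_time),
               event = as.integer(t_death <= c_time),
               x = x)
  })
}

# minimal valid cohort table wrapped around arbitrary survival columns
make_toy_cohort <- function(n, seed = 1) {
  withr::with_seed(seed, {
    dbt <- rlnorm(n, log(2), 0.6)
    data.frame(case_id = sprintf("c%03d", seq_len(n)),
               area_mm2 = rlnorm(n, log(50), 0.9),
               perimeter_mm = rlnorm(n, log(35), 0.6),
               major_mm = rlnorm(n, log(11), 0.5),
               dbt_mm = dbt, ni = pmin(0.99, rlnorm(n, log(0.2), 0.5)),
               breslow_mm = dbt * rlnorm(n, 0, 0.2),
               age = round(runif(n, 30, 90)),
               sex = sample(c("male", "female"), n, TRUE),
               site = sample(c("central", "peripheral"), n, TRUE),
               time_os = rexp(n, 0.15), event_os = rbinom(n, 1, 0.4),
               stringsAsFactors = FALSE) -> d
    d$time_mss <- d$time_os
    d$event_mss <- d$event_os * rbinom(n, 1, 0.75)
    d
  })
}
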