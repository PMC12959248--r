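# Synthetic data: tumour masks of known analytic geometry and survival
# cohorts with the statistical structure the analysis assumes.  The
# generator is the package's stand-in for the (restricted) clinical study
# material: its defaults encode the study conditions -- cohort marginals,
# the dBT <-> Breslow rank correlation, the published adjusted hazard
# ratios as generating effects, a 30% death fraction and a 5.7-year
# median follow-up -- so that parameter-recovery tests are meaningful.

.default_seed <- 20260304

# Shape fixtures ------------------------------------------------------------

#' Specify a synthetic tumour shape
#'
#' Families mirror the morphologies the analysis must cope with:
#' `ellipse` (exact analytic reference), `nodular_blob` (near-round, noisy
#' boundary), `superficial_strip` (wide and thin) and `fragmented`
#' (a main shape plus smaller satellite fragments, exercising the
#' largest-piece rule).
#'
#' @param family shape family.
#' @param a,b semi-major / semi-minor axes in mm (`a >= b > 0`); defaults
#'   depend on the family.
#' @param rotation rigid rotation in degrees.
#' @param boundary_noise relative amplitude (0-0.2) of a smooth periodic
#'   radial perturbation; 0 keeps the boundary exact.
#' @param n_fragments number of satellite fragments (each < 50% of the
#'   main shape's area).
#' @param mpp isotropic calibration in microns per pixel.
#' @param seed RNG seed (noise, fragment placement).
#' @param case_id case identifier.
#' @return a `shape_spec` list.
#' @export
shape_spec <- function(family = c("ellipse", "nodular_blob",
                                  "superficial_strip", "fragmented"),
                       a = NULL, b = NULL, rotation = 0,
                       boundary_noise = NULL, n_fragments = NULL,
                       mpp = 20, seed = .default_seed, case_id = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    ellipse            = list(a = 10, b = 4,   noise = 0,    frags = 0L),
    nodular_blob       = list(a = 6,  b = 5,   noise = 0.08, frags = 0L),
    superficial_strip  = list(a = 15, b = 1.5, noise = 0.04, frags = 0L),
    fragmented         = list(a = 8,  b = 3,   noise = 0.05, frags = 3L))
  a <- a %||% defaults$a
  b <- b %||% defaults$b
  boundary_noise <- boundary_noise %||% defaults$noise
  n_fragments <- n_fragments %||% defaults$frags
  if (!(a >= b && b > 0)) stop("shape axes must satisfy a >= b > 0")
  if (boundary_noise < 0 || boundary_noise > 0.2)
    stop("boundary_noise must lie in [0, 0.2]")
  check_mpp(mpp, "mpp")
  structure(list(family = family, a = a, b = b, rotation = rotation,
                 boundary_noise = boundary_noise,
                 n_fragments = as.integer(n_fragments), mpp = mpp,
                 seed = seed,
                 case_id = case_id %||% sprintf("%s_a%g_b%g", family, a, b)),
            class = "shape_spec")
}

# pixel-centre membership test for a (possibly noisy) rotated ellipse
.inside_blob <- function(X, Y, cx, cy, a, b, rot_deg, noise_fun) {
  th <- rot_deg * pi / 180
  u <- (X - cx) * cos(th) + (Y - cy) * sin(th)
  v <- -(X - cx) * sin(th) + (Y - cy) * cos(th)
  ang <- atan2(v, u)
  r_ell <- a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
  sqrt(u^2 + v^2) <= r_ell * noise_fun(ang)
}

#' Rasterize a synthetic tumour shape with known ground truth
#'
#' The boundary radius of the main shape is the ellipse radius optionally
#' modulated by a smooth periodic perturbation (harmonics 2-5, amplitude
#' `boundary_noise`).  Satellite fragments are plain ellipses placed
#' clear of the main shape.  For a noiseless shape the ground truth is
#' analytic: area `pi*a*b`, major axis `2a`, minor axis `2b`, NI `b/a`
#' (the minimum-area enclosing rectangle of an ellipse is the `2a x 2b`
#' axis-aligned box).
#'
#' @param spec a [shape_spec()].
#' @return list with `mask` (a [segmentation_mask()]) and `truth` (one-row
#'   data frame; `exact` flags an unperturbed boundary).
#' @export
generate_shape <- function(spec) {
  stopifnot(inherits(spec, "shape_spec"))
  sx <- spec$mpp / 1000
  if (spec$b < 2.5 * sx)
    stop("resolution too coarse for shape: minor semi-axis under 2.5 pixels")
  withr::with_seed(spec$seed, {
    amp <- spec$boundary_noise
    if (amp > 0) {
      h <- 2:5
      ch <- stats::rnorm(length(h)) / h
      sh <- stats::rnorm(length(h)) / h
      grid <- seq(0, 2 * pi, length.out = 720)
      gmax <- max(abs(colSums(ch * sin(outer(h, grid)) +
                              sh * cos(outer(h, grid)))))
      noise_fun <- function(ang)
        1 + amp * colSums(ch * sin(outer(h, ang)) + sh * cos(outer(h, ang))) / gmax
    } else {
      noise_fun <- function(ang) rep(1, length(ang))
    }
    rmax <- spec$a * (1 + amp)
    frags <- NULL
    if (spec$n_fragments > 0L) {
      k <- spec$n_fragments
      frags <- data.frame(
        af = spec$a * stats::runif(k, 0.15, 0.35),
        bf = spec$b * stats::runif(k, 0.30, 0.70),
        ang = stats::runif(k, 0, 2 * pi),
        rot = stats::runif(k, 0, 180))
      frags$dist <- rmax + frags$af + stats::runif(k, 1, 3)
      frags$cx <- frags$dist * cos(frags$ang)
      frags$cy <- frags$dist * sin(frags$ang)
    }
    half <- rmax + 1
    if (!is.null(frags)) half <- max(half, max(frags$dist + frags$af) + 1)
    n_side <- ceiling(2 * half / sx) + 2L
    if (n_side^2 > 3e8) stop("shape exceeds grid budget at this resolution")
    xs <- (seq_len(n_side) - 0.5) * sx - half
    X <- matrix(xs, n_side, n_side, byrow = TRUE)   # columns vary along x
    Y <- matrix(xs, n_side, n_side)                 # rows vary along y
    fg <- .inside_blob(X, Y, 0, 0, spec$a, spec$b, spec$rotation, noise_fun)
    if (!is.null(frags)) {
      for (i in seq_len(nrow(frags))) {
        fg <- fg | .inside_blob(X, Y, frags$cx[i], frags$cy[i],
                                frags$af[i], frags$bf[i], frags$rot[i],
                                function(ang) rep(1, length(ang)))
      }
    }
  })
  mask <- segmentation_mask(fg, spec$mpp, spec$mpp, spec$case_id)
  truth <- data.frame(case_id = spec$case_id, family = spec$family,
                      area_mm2 = pi * spec$a * spec$b,
                      major_mm = 2 * spec$a, minor_mm = 2 * spec$b,
                      ni = spec$b / spec$a,
                      exact = spec$boundary_noise == 0,
                      n_fragments = spec$n_fragments,
                      stringsAsFactors = FALSE)
  list(mask = mask, truth = truth)
}

# Cohort generator -----------------------------------------------------------

# Log-normal marginals for the biomarkers and gold-standard Breslow
# thickness (mm / mm2).  The Breslow parameters reproduce the study's
# quartile structure (~11% <= 1 mm, ~15% > 4 mm); the remainder are
# realistic whole-lesion values for conventional invasive melanoma and are
# config-overridable.
default_marginals <- function() {
  list(area      = c(meanlog = log(50),  sdlog = 0.95),
       perimeter = c(meanlog = log(35),  sdlog = 0.60),
       major     = c(meanlog = log(11),  sdlog = 0.55),
       dbt       = c(meanlog = log(2.2), sdlog = 0.65),
       breslow   = c(meanlog = log(2.0), sdlog = 0.60))
}

# Spearman rank-correlation targets of the Gaussian copula
# (area, perimeter, major, dbt, breslow).  dbt <-> breslow is the
# study-anchored 0.89; the rest express that the size metrics share a
# common scale factor while depth is only loosely tied to width.
default_copula <- function(rho_dbt_breslow = 0.89) {
  nm <- c("area", "perimeter", "major", "dbt", "breslow")
  m <- diag(5)
  dimnames(m) <- list(nm, nm)
  set <- function(i, j, v) { m[i, j] <<- v; m[j, i] <<- v }
  set("area", "perimeter", 0.92); set("area", "major", 0.85)
  set("area", "dbt", 0.70);       set("area", "breslow", 0.65)
  set("perimeter", "major", 0.90); set("perimeter", "dbt", 0.60)
  set("perimeter", "breslow", 0.55)
  set("major", "dbt", 0.50);      set("major", "breslow", 0.45)
  set("dbt", "breslow", rho_dbt_breslow)
  m   # NI is derived as dbt / major, not drawn
}

# Adjusted hazard-ratio generating defaults per endpoint, one designated
# biomarker per cohort.  MSS values for area/perimeter/major are not
# anchored and reuse the OS values (approximate, overridable).
.default_hr <- list(
  OS  = c(area = 1.48, perimeter = 1.86, major = 1.88, ni = 1.77, dbt = 2.04),
  MSS = c(area = 1.48, perimeter = 1.86, major = 1.88, ni = 2.34, dbt = 2.59))

#' Specify a synthetic survival cohort
#'
#' Each generated cohort has one designated hazard-driving biomarker
#' (matching the one-biomarker-per-model analysis); its generating hazard
#' ratio defaults to the study's adjusted estimate for the chosen
#' endpoint.  Covariate effects (age per year, male sex, central site) are
#' plausible nuisance values, not study-anchored.
#'
#' @param n number of cases (>= 4).
#' @param designated_param biomarker driving the hazard: `"area"`,
#'   `"perimeter"`, `"major"`, `"dbt"` or `"ni"`.
#' @param endpoint endpoint whose generating effect is used (`"OS"` or
#'   `"MSS"`).
#' @param hr_param generating hazard ratio per unit log-biomarker;
#'   `NULL` takes the endpoint default.
#' @param hr_age,hr_sex_male,hr_site_central nuisance hazard ratios.
#' @param melanoma_death_frac probability a death is melanoma-caused.
#' @param target_death_frac,target_median_followup,max_followup censoring
#'   calibration targets: overall observed-death fraction, median observed
#'   follow-up (years) and the administrative cap.
#' @param weibull_shape baseline Weibull shape.
#' @param p_age_ge50,p_male,p_central covariate marginals.
#' @param age_mean_sd location/scale of the (truncated-normal) age draw;
#'   the location is re-solved so that P(age >= 50) matches `p_age_ge50`.
#' @param marginals list of log-normal `c(meanlog, sdlog)` per biomarker,
#'   see [default_marginals()].
#' @param copula_spearman 5 x 5 Spearman target matrix, see
#'   [default_copula()].
#' @param seed RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n = 2000,
                        designated_param = "dbt",
                        endpoint = "OS",
                        hr_param = NULL,
                        hr_age = 1.03, hr_sex_male = 1.30,
                        hr_site_central = 1.20,
                        melanoma_death_frac = 0.75,
                        target_death_frac = 0.30,
                        target_median_followup = 5.7,
                        max_followup = 33.7,
                        weibull_shape = 3.5,
                        p_age_ge50 = 0.76, p_male = 0.5, p_central = 0.5,
                        age_mean_sd = c(60, 15),
                        marginals = default_marginals(),
                        copula_spearman = default_copula(),
                        seed = .default_seed) {
  endpoint <- match.arg(toupper(endpoint), c("OS", "MSS"))
  designated_param <- match.arg(designated_param,
                                c("area", "perimeter", "major", "dbt", "ni"))
  if (n < 4) stop("cohort size must be at least 4")
  probs <- c(p_age_ge50, p_male, p_central, melanoma_death_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  ev <- eigen(copula_spearman, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("copula correlation matrix is not positive semi-definite")
  hr_param <- hr_param %||% unname(.default_hr[[endpoint]][designated_param])
  structure(list(n = as.integer(n), designated_param = designated_param,
                 endpoint = endpoint, hr_param = hr_param, hr_age = hr_age,
                 hr_sex_male = hr_sex_male, hr_site_central = hr_site_central,
                 melanoma_death_frac = melanoma_death_frac,
                 target_death_frac = target_death_frac,
                 target_median_followup = target_median_followup,
                 max_followup = max_followup, weibull_shape = weibull_shape,
                 p_age_ge50 = p_age_ge50, p_male = p_male,
                 p_central = p_central, age_mean_sd = age_mean_sd,
                 marginals = marginals, copula_spearman = copula_spearman,
                 seed = seed),
            class = "cohort_spec")
}

# Solve the truncated-normal location so that P(age >= 50) hits the target
# within the [18, 95] support.
.age_location <- function(p_ge50, s) {
  f <- function(m) {
    hi <- stats::pnorm(95, m, s); lo <- stats::pnorm(18, m, s)
    (hi - stats::pnorm(50, m, s)) / (hi - lo) - p_ge50
  }
  stats::uniroot(f, c(20, 93))$root
}

# Nested bisection of the baseline Weibull scale (lambda) and the uniform
# censoring window (W) against the realized standardized death times T0
# and censoring uniforms U.  Observed time is min(lambda*T0, min(cap, W*U)).
# For fixed W the death fraction is monotone decreasing in lambda, which
# defines lambda(W); the median follow-up along that constraint is then
# monotone increasing in W (both a wider window and the compensating
# longer death times lengthen follow-up), so a single outer bisection on
# W converges -- a naive alternating scheme can cycle.
.calibrate_censoring <- function(T0, U, cap, target_death, target_median) {
  cens <- function(W) pmin(cap, W * U)
  f_death <- function(lam, W) mean(lam * T0 <= cens(W))
  f_med <- function(lam, W) stats::median(pmin(lam * T0, cens(W)))
  bisect <- function(f, lo, hi, increasing, iters = 50) {
    flo <- f(lo); fhi <- f(hi)
    if (increasing) {
      if (flo > 0) return(lo)
      if (fhi < 0) return(hi)
    } else {
      if (flo < 0) return(lo)
      if (fhi > 0) return(hi)
    }
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      v <- f(mid)
      if (if (increasing) v < 0 else v > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lam_given_W <- function(W)
    bisect(function(l) f_death(l, W) - target_death, 1e-4, 1e4,
           increasing = FALSE, iters = 45)
  W <- bisect(function(w) f_med(lam_given_W(w), w) - target_median,
              1e-3, 1e4, increasing = TRUE, iters = 45)
  lam <- lam_given_W(W)
  achieved_death <- f_death(lam, W)
  achieved_median <- f_med(lam, W)
  if (abs(achieved_death - target_death) > 0.02)
    stop(sprintf("censoring calibration failed: achieved death fraction %.3f (target %.3f)",
                 achieved_death, target_death))
  if (abs(achieved_median - target_median) > 0.3)
    stop(sprintf("censoring calibration failed: achieved median follow-up %.2f (target %.2f)",
                 achieved_median, target_median))
  list(lambda = lam, W = W, achieved_death = achieved_death,
       achieved_median = achieved_median)
}

#' Generate a synthetic survival cohort
#'
#' Biomarkers and gold-standard Breslow thickness are drawn from a
#' Gaussian copula with log-normal marginals (NI is derived as
#' dBT / major axis, with the rare draw exceeding the major axis capped at
#' 0.99 so NI stays in (0, 1]); age, sex and site are drawn independently
#' to their marginals.  A single latent death time follows a Weibull
#' proportional-hazards model whose linear predictor contains the
#' designated log-biomarker and the nuisance covariates; deaths are
#' melanoma-caused with fixed probability, and MSS treats other-cause
#' deaths as censored at the death time.  Censoring is uniform over a
#' window (plus an administrative cap) whose width, together with the
#' baseline Weibull scale, is calibrated by bisection against the realized
#' draws so the observed death fraction and median follow-up hit their
#' targets.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with `cohort` (observable data
#'   frame in the cohort schema) and `truth` (sealed generating record:
#'   true coefficients, calibration constants, event causes; for testing
#'   only -- never read by analysis code).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  beta <- log(c(param = spec$hr_param, age = spec$hr_age,
                male = spec$hr_sex_male, central = spec$hr_site_central))
  out <- withr::with_seed(spec$seed, {
    sigma <- 2 * sin(pi * spec$copula_spearman / 6)   # Spearman -> Pearson
    diag(sigma) <- 1
    z <- MASS::mvrnorm(n, rep(0, 5), sigma)
    u <- stats::pnorm(z)
    mg <- spec$marginals
    vals <- lapply(seq_along(mg), function(k)
      stats::qlnorm(u[, k], mg[[k]]["meanlog"], mg[[k]]["sdlog"]))
    names(vals) <- names(mg)
    capped <- vals$dbt > 0.99 * vals$major
    vals$dbt[capped] <- 0.99 * vals$major[capped]
    ni <- vals$dbt / vals$major
    m_age <- .age_location(spec$p_age_ge50, spec$age_mean_sd[2])
    ua <- stats::runif(n, stats::pnorm(18, m_age, spec$age_mean_sd[2]),
                       stats::pnorm(95, m_age, spec$age_mean_sd[2]))
    age <- stats::qnorm(ua, m_age, spec$age_mean_sd[2])
    male <- stats::runif(n) < spec$p_male
    central <- stats::runif(n) < spec$p_central
    x <- switch(spec$designated_param,
                area = log(vals$area), perimeter = log(vals$perimeter),
                major = log(vals$major), dbt = log(vals$dbt), ni = log(ni))
    lp <- beta["param"] * (x - mean(x)) + beta["age"] * (age - 60) +
      beta["male"] * male + beta["central"] * central
    k <- spec$weibull_shape
    T0 <- (-log(stats::runif(n)))^(1 / k) * exp(-lp / k)
    U_c <- stats::runif(n)
    cal <- .calibrate_censoring(T0, U_c, spec$max_followup,
                                spec$target_death_frac,
                                spec$target_median_followup)
    T_death <- cal$lambda * T0
    C <- pmin(spec$max_followup, cal$W * U_c)
    time <- pmin(T_death, C)
    event_os <- as.integer(T_death <= C)
    melanoma <- stats::runif(n) < spec$melanoma_death_frac
    list(vals = vals, ni = ni, age = age, male = male, central = central,
         time = time, event_os = event_os, melanoma = melanoma, cal = cal,
         n_capped = sum(capped))
  })
  cohort <- data.frame(
    case_id = sprintf("case_%04d", seq_len(n)),
    area_mm2 = out$vals$area, perimeter_mm = out$vals$perimeter,
    major_mm = out$vals$major, dbt_mm = out$vals$dbt, ni = out$ni,
    breslow_mm = out$vals$breslow,
    age = out$age,
    sex = ifelse(out$male, "male", "female"),
    site = ifelse(out$central, "central", "peripheral"),
    time_os = out$time, event_os = out$event_os,
    time_mss = out$time,
    event_mss = out$event_os * as.integer(out$melanoma),
    stringsAsFactors = FALSE)
  truth <- list(designated_param = spec$designated_param,
                endpoint = spec$endpoint,
                hr_param = spec$hr_param, beta = unname(beta),
                hr_age = spec$hr_age, hr_sex_male = spec$hr_sex_male,
                hr_site_central = spec$hr_site_central,
                weibull_shape = spec$weibull_shape,
                lambda = out$cal$lambda, censor_window = out$cal$W,
                achieved_death_frac = out$cal$achieved_death,
                achieved_median_followup = out$cal$achieved_median,
                melanoma_death = out$melanoma, n_capped_ni = out$n_capped,
                seed = spec$seed)
  structure(list(cohort = cohort, truth = truth), class = "synthetic_cohort")
}

#' Write a deterministic fixture suite to disk
#'
#' Produces ~20 mask PNGs spanning all four shape families, a sidecar
#' calibration JSON, the analytic ground-truth CSV, a default synthetic
#' cohort CSV and its sealed truth JSON.  Identical seeds reproduce the
#' files byte-for-byte.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed RNG seed.
#' @param n_cohort cohort size for the bundled cohort CSV.
#' @return invisibly, the vector of files written.
#' @export
make_fixture_suite <- function(out_dir, seed = .default_seed,
                               n_cohort = 500) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create fixture directory '%s'", out_dir))
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop(sprintf("fixture directory '%s' is not writable", out_dir))
  unlink(probe)
  families <- rep(c("ellipse", "nodular_blob", "superficial_strip",
                    "fragmented"), each = 5)
  scale_f <- rep(c(0.6, 0.8, 1.0, 1.25, 1.5), times = 4)
  files <- character(0)
  truth <- NULL
  calib <- list()
  for (i in seq_along(families)) {
    sp <- shape_spec(families[i], seed = seed + i, mpp = 40)
    sp$a <- sp$a * scale_f[i]; sp$b <- sp$b * scale_f[i]
    sp$case_id <- sprintf("fix_%02d_%s", i, families[i])
    g <- generate_shape(sp)
    f <- file.path(out_dir, paste0(sp$case_id, ".png"))
    png::writePNG(g$mask$pixels * 1, f)
    files <- c(files, f)
    calib[[sp$case_id]] <- list(mpp_x = sp$mpp, mpp_y = sp$mpp)
    truth <- rbind(truth, g$truth)
  }
  f_cal <- file.path(out_dir, "calibration.json")
  jsonlite::write_json(calib, f_cal, auto_unbox = TRUE, pretty = TRUE)
  f_truth <- file.path(out_dir, "shape_truth.csv")
  write.csv(truth, f_truth, row.names = FALSE)
  cs <- cohort_spec(n = n_cohort, seed = seed + 999L)
  g <- generate_cohort(cs)
  f_cohort <- file.path(out_dir, "cohort.csv")
  write_cohort_table(g$cohort, f_cohort)
  f_tj <- file.path(out_dir, "cohort_truth.json")
  tr <- g$truth
  tr$melanoma_death <- NULL   # keep the sealed record compact
  jsonlite::write_json(tr, f_tj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, f_cal, f_truth, f_cohort, f_tj))
}
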