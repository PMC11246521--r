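# Synthetic cohort generator: an HRS-like mechanism with fully known
# structural coefficients, so every estimator in the package can be tested
# against ground truth without restricted data.

#' Synthetic cohort generator configuration
#'
#' Builds the full parameterization of the synthetic cohort mechanism. The
#' defaults are calibrated to the study population the package targets:
#' three racialized groups at observed prevalences, age 67.1 (SD 9.9), 61%
#' female, group-graded education and APOE-e4 carrier prevalence (both act as
#' exposure-affected mediator-outcome confounders L), lognormal CRP with
#' group/sex-specific means (non-Hispanic Black women highest, non-Hispanic
#' white men lowest; 75th percentile near 4.73 ug/mL), and an
#' interval-censored 6-year dementia process with piecewise-constant hazard
#' over 2-year waves producing roughly 12% overall cumulative incidence
#' (about 21% / 16% / 9.5% by group).
#'
#' CRP is lognormal on the log scale: `log CRP = location(group, sex) +
#' loadings(apoe4, education) + scale * N(0,1)`; locations are derived from
#' the target group/sex means so the configured means are reproduced after
#' integrating over the loading distribution.
#'
#' The yearly dementia log-rate is
#' `intercept + beta_A[group] * A + beta_M * M + beta_AM[group] * A * M +`
#' covariate and L loadings; each 2-year interval converts with probability
#' `1 - exp(-2 * rate)`.
#'
#' @param n Cohort size.
#' @param ... Named overrides for any configuration element (see the
#'   function body for the full list, e.g. `outcome_coefs`, `p_apoe4_by_group`,
#'   `crp_mean_by_group_sex`, `threshold`).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = 6908, ...) {
  cfg <- list(
    n = n,
    p_group = c(nh_white = 5462, nh_black = 813, hispanic = 633) / 6908,
    age_mean = 67.11, age_sd = 9.91,
    p_female = 0.61,
    p_education_by_group = rbind(  # rows: groups; cols: hs_or_less, college_some, gt_college
      nh_white = c(0.68, 0.21, 0.11),
      nh_black = c(0.82, 0.13, 0.05),
      hispanic = c(0.89, 0.08, 0.03)
    ),
    p_smoking = c(never = 0.45, former = 0.43, current = 0.12),
    alcohol_p_zero = 0.55, alcohol_mean_pos = 1.58,
    bmi_mean = 28.5, bmi_sd = 5.79,
    chronic_size = 8L, chronic_p = 0.235,
    p_apoe4_by_group = c(nh_white = 0.255, nh_black = 0.38, hispanic = 0.26),
    p_wave_2008 = 0.5,
    crp_mean_by_group_sex = rbind(  # cols: female, male (ug/mL)
      nh_white = c(4.55, 3.40),
      nh_black = c(6.80, 6.03),
      hispanic = c(4.81, 4.01)
    ),
    crp_scale = 1.20,
    crp_loadings = c(apoe4 = -0.10, education_college_some = -0.05,
                     education_gt_college = -0.10),
    threshold = 4.73,
    outcome_coefs = list(
      intercept = -5.50,
      beta_A = c(nh_black = 0.60, hispanic = 0.36),
      beta_M = 0.175,
      beta_AM = c(nh_black = 0.25, hispanic = 0.25),
      age = 0.085, age_center = 67,
      sex_male = 0,
      education = c(hs_or_less = 0.9, college_some = 0.3, gt_college = 0),
      apoe4 = 0.35,
      smoking = c(never = 0, former = 0, current = 0.1),
      alcohol = -0.10,
      bmi = -0.02, bmi_center = 28.5,
      chronic = 0.12,
      wave_2008 = 0.10
    ),
    ref_time = 6, interval_years = 2, n_intervals = 3L,
    p_baseline_cind = 0.20, p_cind_onset = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg$p_group <- cfg$p_group[GROUPS]
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk1 <- function(p, nm) {
    if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
      stop(nm, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  chk1(cfg$p_group, "p_group")
  chk1(cfg$p_smoking, "p_smoking")
  for (g in rownames(cfg$p_education_by_group)) {
    chk1(cfg$p_education_by_group[g, ], paste0("p_education_by_group[", g, ",]"))
  }
  if (cfg$crp_scale <= 0) stop("crp_scale must be > 0", call. = FALSE)
  if (cfg$n < 1) stop("n must be >= 1", call. = FALSE)
  invisible(cfg)
}

# Mean multiplicative CRP loading factor E[exp(loadings)] within a group,
# integrating over the group's apoe4 and education laws.
crp_loading_factor <- function(cfg, g) {
  ld <- cfg$crp_loadings
  pe <- cfg$p_education_by_group[g, ]
  pa <- cfg$p_apoe4_by_group[[g]]
  f_apoe <- (1 - pa) + pa * exp(ld[["apoe4"]])
  f_edu <- pe[1L] + pe[2L] * exp(ld[["education_college_some"]]) +
    pe[3L] * exp(ld[["education_gt_college"]])
  unname(f_apoe * f_edu)
}

# Lognormal location for (group, sex) chosen so the configured target mean is
# reproduced after integrating over loadings and noise.
crp_location <- function(cfg, g, sex_idx) {
  log(cfg$crp_mean_by_group_sex[g, sex_idx]) - cfg$crp_scale^2 / 2 -
    log(crp_loading_factor(cfg, g))
}

# Full group x sex location matrix (rows in GROUPS order).
crp_location_matrix <- function(cfg) {
  t(vapply(GROUPS, function(g) c(crp_location(cfg, g, 1L),
                                 crp_location(cfg, g, 2L)), c(0, 0)))
}

# Group-conditional education draw, vectorized by group.
draw_education <- function(cfg, group) {
  education <- character(length(group))
  for (g in unique(group)) {
    i <- group == g
    education[i] <- sample(EDU_LEVELS, sum(i), replace = TRUE,
                           prob = cfg$p_education_by_group[g, ])
  }
  education
}

# CRP loading on the log scale for given apoe4 / education values.
crp_loading_lp <- function(cfg, apoe4, education) {
  ld <- cfg$crp_loadings
  ld[["apoe4"]] * apoe4 +
    ld[["education_college_some"]] * (education == "college_some") +
    ld[["education_gt_college"]] * (education == "gt_college")
}

# Yearly log-rate linear predictor without the A/M terms.
outcome_base_lp <- function(cfg, d) {
  oc <- cfg$outcome_coefs
  oc$intercept +
    oc$age * (d$age - oc$age_center) +
    oc$sex_male * (d$sex == "male") +
    unname(oc$education[d$education]) +
    oc$apoe4 * d$apoe4 +
    unname(oc$smoking[d$smoking]) +
    oc$alcohol * d$alcohol +
    oc$bmi * (d$bmi - oc$bmi_center) +
    oc$chronic * d$chronic_count +
    oc$wave_2008 * (d$wave == "2008")
}

# A-side multiplier exp(beta_A[g] + beta_AM[g] * m) for a minoritized group.
exposure_factor <- function(cfg, g, m) {
  oc <- cfg$outcome_coefs
  exp(oc$beta_A[[g]] + oc$beta_AM[[g]] * m)
}

#' Generate a synthetic cohort
#'
#' Draws a full person-level cohort from the configured mechanism:
#' covariates, exposure-affected confounders (APOE-e4, education) conditional
#' on racialized group, lognormal CRP, an interval-censored dementia process
#' over three 2-year waves, and per-wave cognitive scores consistent with the
#' event process (baseline free of dementia; scores 0-6 at the event wave;
#' waves after a dementia classification are unobserved). Identical
#' `(config, seed)` yield byte-identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return List with `records` (a participant-record data frame accepted by
#'   [build_analytic_sample()]) and `truth` (per-person latent yearly rates
#'   `lam00, lam01, lam10, lam11` under the four exposure/mediator settings,
#'   true mediator probabilities `pi0, pi1`, and the factual rate). For
#'   non-Hispanic white rows the exposed-side quantities average over the
#'   minoritized groups at their configured prevalences.
#' @export
generate_cohort <- function(config, seed = 1L) {
  cfg <- validate_sim_config(config)
  n <- cfg$n
  set.seed(seed)

  group <- sample(GROUPS, n, replace = TRUE, prob = cfg$p_group)
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
  wave <- ifelse(stats::runif(n) < cfg$p_wave_2008, "2008", "2006")
  education <- draw_education(cfg, group)
  smoking <- sample(SMOKE_LEVELS, n, replace = TRUE, prob = cfg$p_smoking)
  alcohol <- ifelse(stats::runif(n) < cfg$alcohol_p_zero, 0,
                    stats::rexp(n, rate = 1 / cfg$alcohol_mean_pos))
  bmi <- stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd)
  chronic_count <- stats::rbinom(n, cfg$chronic_size, cfg$chronic_p)
  apoe4 <- stats::rbinom(n, 1L, cfg$p_apoe4_by_group[group])

  sex_idx <- ifelse(sex == "female", 1L, 2L)
  locm <- crp_location_matrix(cfg)
  loc <- locm[cbind(match(group, GROUPS), sex_idx)]
  d0 <- data.frame(age = age, sex = sex, education = education,
                   smoking = smoking, alcohol = alcohol, bmi = bmi,
                   chronic_count = chronic_count, apoe4 = apoe4, wave = wave)
  logcrp <- loc + crp_loading_lp(cfg, apoe4, education) +
    cfg$crp_scale * stats::rnorm(n)
  crp <- exp(logcrp)
  M <- as.integer(crp >= cfg$threshold)

  # Latent truth: yearly rates under the four (a, m) settings and true
  # mediator probabilities under both exposures, given each person's own
  # covariates and L. Exposed-side group quantities use the person's own
  # group when minoritized, otherwise the minoritized-prevalence mixture.
  base_lp <- outcome_base_lp(cfg, d0)
  p_min <- cfg$p_group[c("nh_black", "hispanic")]
  p_min <- p_min / sum(p_min)
  fac1 <- function(m) {
    mix <- p_min[["nh_black"]] * exposure_factor(cfg, "nh_black", m) +
      p_min[["hispanic"]] * exposure_factor(cfg, "hispanic", m)
    ifelse(group == "nh_white", mix,
           ifelse(group == "nh_black", exposure_factor(cfg, "nh_black", m),
                  exposure_factor(cfg, "hispanic", m)))
  }
  oc <- cfg$outcome_coefs
  lam00 <- exp(base_lp)
  lam01 <- exp(base_lp + oc$beta_M)
  lam10 <- lam00 * fac1(0)
  lam11 <- exp(base_lp + oc$beta_M) * fac1(1)
  zthr <- (log(cfg$threshold) - loc - crp_loading_lp(cfg, apoe4, education)) /
    cfg$crp_scale
  pi_own <- 1 - stats::pnorm(zthr)
  loc_nhw <- locm[1L, sex_idx]
  pi0 <- 1 - stats::pnorm((log(cfg$threshold) - loc_nhw -
                             crp_loading_lp(cfg, apoe4, education)) / cfg$crp_scale)
  pi1 <- pi_mixture_minority(cfg, sex_idx, apoe4, education, p_min)

  lam_fact <- ifelse(group == "nh_white",
                     ifelse(M == 1, lam01, lam00),
                     exp(base_lp + oc$beta_M * M) *
                       ifelse(group == "nh_black",
                              exposure_factor(cfg, "nh_black", M),
                              exposure_factor(cfg, "hispanic", M)))

  # Interval-censored event process: 3 waves of 2 years each.
  p_int <- 1 - exp(-cfg$interval_years * lam_fact)
  u <- matrix(stats::runif(n * cfg$n_intervals), n, cfg$n_intervals)
  ev <- u < p_int  # recycled by column
  first <- apply(ev, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  Y <- as.integer(!is.na(first))
  t <- ifelse(is.na(first), cfg$ref_time, cfg$interval_years * first)

  # Cognitive trajectories consistent with the event process.
  base_cind <- stats::runif(n) < cfg$p_baseline_cind
  status <- matrix(NA_character_, n, 4L)
  status[, 1L] <- ifelse(base_cind, "cind", "normal")
  onset <- matrix(stats::runif(n * 3L) < cfg$p_cind_onset, n, 3L)
  for (j in 1:3) {
    prev <- status[, j]
    sj <- ifelse(prev == "normal" & onset[, j], "cind", prev)
    sj[!is.na(first) & first == j] <- "dementia"
    sj[!is.na(first) & first < j] <- NA_character_  # not followed past event
    status[, j + 1L] <- sj
  }
  score_for <- function(st) {
    out <- rep(NA_integer_, length(st))
    k <- !is.na(st)
    lo <- c(dementia = 0L, cind = 7L, normal = 12L)[st[k]]
    hi <- c(dementia = 6L, cind = 11L, normal = 27L)[st[k]]
    out[k] <- lo + as.integer(floor(stats::runif(sum(k)) * (hi - lo + 1L)))
    out
  }
  scores <- apply(status, 2L, score_for)

  records <- data.frame(
    id = seq_len(n), wave = wave, group = group, age = age, sex = sex,
    education = education, smoking = smoking, alcohol = alcohol, bmi = bmi,
    chronic_count = chronic_count, apoe4 = apoe4, crp = crp,
    cog0 = scores[, 1L], cog2 = scores[, 2L], cog4 = scores[, 3L],
    cog6 = scores[, 4L], stringsAsFactors = FALSE
  )
  truth <- data.frame(id = seq_len(n), lam00 = lam00, lam01 = lam01,
                      lam10 = lam10, lam11 = lam11, pi0 = pi0, pi1 = pi1,
                      lam_factual = lam_fact, M = M, Y = Y, t = t)
  list(records = records, truth = truth)
}

# True P(M = 1 | A = 1, sex, l) mixed over minoritized groups with weights
# proportional to prevalence times P(l | group).
pi_mixture_minority <- function(cfg, sex_idx, apoe4, education, p_min) {
  ltau <- log(cfg$threshold)
  load <- crp_loading_lp(cfg, apoe4, education)
  locm <- crp_location_matrix(cfg)
  num <- 0
  den <- 0
  edu_idx <- match(education, EDU_LEVELS)
  for (g in names(p_min)) {
    pa <- cfg$p_apoe4_by_group[[g]]
    w <- p_min[[g]] * ifelse(apoe4 == 1, pa, 1 - pa) *
      cfg$p_education_by_group[g, ][edu_idx]
    locg <- locm[match(g, GROUPS), sex_idx]
    pig <- 1 - stats::pnorm((ltau - locg - load) / cfg$crp_scale)
    num <- num + w * pig
    den <- den + w
  }
  num / den
}
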