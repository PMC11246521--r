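# Fixtures built in code: constructed model fits with known counterfactual
# cells, hand-built participant records, and small reference configurations.

# fwglm objects encoding exact counterfactual risks p_am = T * exp(lp) and
# mediator probabilities (pi0, pi1), with no covariates.
toy_fits <- function(p00 = 0.10, p01 = 0.20, p10 = 0.15, p11 = 0.40,
                     pi0 = 0.25, pi1 = 0.50, T = 6) {
  ofit <- structure(list(
    family = "poisson_log", converged = TRUE,
    coefficients = c(`(Intercept)` = log(p00 / T), A = log(p10 / p00),
                     M = log(p01 / p00),
                     `A:M` = log(p11 * p00 / (p10 * p01)))), class = "fwglm")
  mfit <- structure(list(
    family = "binomial_logit", converged = TRUE,
    coefficients = c(`(Intercept)` = stats::qlogis(pi0),
                     A = stats::qlogis(pi1) - stats::qlogis(pi0))),
    class = "fwglm")
  dat <- data.frame(A = rep(0:1, 5), M = 0L, Y = 0L, t = T)
  attr(dat, "covariates") <- character(0)
  attr(dat, "lvars") <- character(0)
  class(dat) <- c("analytic_dataset", "data.frame")
  list(outcome = ofit, mediator = mfit, data = dat, T = T)
}

# Minimal complete participant records with fixed group sizes; everyone is
# cognitively normal throughout except the first `events` rows per group,
# who convert to dementia at the wave given by `event_wave`.
make_records <- function(sizes = c(nh_white = 40, nh_black = 25, hispanic = 15),
                         events = c(nh_white = 4, nh_black = 5, hispanic = 3),
                         event_wave = 3L) {
  n <- sum(sizes)
  group <- rep(names(sizes), sizes)
  rec <- data.frame(
    id = seq_len(n), wave = rep(c("2006", "2008"), length.out = n),
    group = group, age = 67, sex = rep(c("female", "male"), length.out = n),
    education = "hs_or_less", smoking = "never", alcohol = 0.5, bmi = 28,
    chronic_count = 2L, apoe4 = rep(0:1, length.out = n),
    crp = rep(c(1, 2, 3, 6), length.out = n),
    cog0 = 20L, cog2 = 20L, cog4 = 20L, cog6 = 20L,
    stringsAsFactors = FALSE
  )
  for (g in names(sizes)) {
    i <- which(group == g)[seq_len(events[[g]])]
    rec[[paste0("cog", 2L * event_wave)]][i] <- 3L
  }
  rec
}

# Two-group, covariate-free mechanism whose oracle decomposition is the
# closed-form worked instance: risks (0.10, 0.20, 0.15, 0.40) over T = 6
# years and mediator prevalences (0.25, 0.50).
worked_instance_config <- function(n = 500) {
  Tt <- 6
  sig <- 1
  mean_nhw <- exp(sig^2 / 2 - sig * stats::qnorm(0.75))  # pi0 = 0.25 at tau = 1
  mean_min <- exp(sig^2 / 2)                             # pi1 = 0.50
  sim_config(
    n = n,
    p_group = c(nh_white = 0.5, nh_black = 0.5, hispanic = 0),
    p_female = 1,
    p_education_by_group = rbind(nh_white = c(1, 0, 0), nh_black = c(1, 0, 0),
                                 hispanic = c(1, 0, 0)),
    p_apoe4_by_group = c(nh_white = 0.3, nh_black = 0.3, hispanic = 0.3),
    crp_mean_by_group_sex = rbind(nh_white = c(mean_nhw, mean_nhw),
                                  nh_black = c(mean_min, mean_min),
                                  hispanic = c(mean_min, mean_min)),
    crp_scale = sig,
    crp_loadings = c(apoe4 = 0, education_college_some = 0,
                     education_gt_college = 0),
    threshold = 1,
    outcome_coefs = list(
      intercept = log(0.10 / Tt),
      beta_A = c(nh_black = log(1.5), hispanic = log(1.5)),
      beta_M = log(2),
      beta_AM = c(nh_black = log(4 / 3), hispanic = log(4 / 3)),
      age = 0, age_center = 67, sex_male = 0,
      education = c(hs_or_less = 0, college_some = 0, gt_college = 0),
      apoe4 = 0, smoking = c(never = 0, former = 0, current = 0),
      alcohol = 0, bmi = 0, bmi_center = 28.5, chronic = 0, wave_2008 = 0)
  )
}

# Covariate-free mechanism (all loadings zero, group-invariant L) used for
# the bootstrap coverage study: the unadjusted estimator is correctly
# specified and the oracle is exact.
flat_config <- function(n = 5000, beta_A = 0.5, beta_M = log(1.3),
                        beta_AM = 0.2) {
  cfg <- worked_instance_config(n)
  cfg$outcome_coefs$intercept <- log(0.008)
  cfg$outcome_coefs$beta_A <- c(nh_black = beta_A, hispanic = beta_A)
  cfg$outcome_coefs$beta_M <- beta_M
  cfg$outcome_coefs$beta_AM <- c(nh_black = beta_AM, hispanic = beta_AM)
  cfg
}
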