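# Monte-Carlo ground truth for the four-way decomposition under a known
# synthetic mechanism. The oracle evaluates exact per-profile counterfactual
# rates and mediator probabilities from the configuration coefficients and
# averages them over simulated covariate/L profiles, so it is independent of
# every model-fitting code path it is used to test.

#' Ground-truth four-way decomposition under a synthetic mechanism
#'
#' Computes the true excess-relative-risk components (CDE, reference
#' interaction, mediated interaction, pure indirect effect), their total, and
#' the derived proportions for one exposure contrast, directly from the
#' generator's structural coefficients. Covariate and L profiles are drawn
#' from the mechanism by Monte Carlo; per-profile counterfactual yearly rates
#' and mediator probabilities are then exact, so for configurations without
#' person-level covariate variation the result is exact (closed form).
#'
#' Two estimands are available. `"regression"` conditions on the
#' exposure-affected confounders L (APOE-e4, education) as if they were
#' ordinary confounders and standardizes over their factual joint
#' distribution - the estimand targeted by the regression-based estimator.
#' `"analog"` integrates L out of both the outcome and mediator laws under
#' the index exposure (interventional / randomized-analog estimand, the
#' g-formula target).
#'
#' @param config A [sim_config()] object.
#' @param contrast Exposure contrast (see [build_analytic_sample()]).
#' @param estimand `"regression"` or `"analog"`.
#' @param n_mc Number of Monte-Carlo profiles (>= 1e5 recommended).
#' @param seed Integer seed for the profile draw.
#' @return List of class `"fwdecomp_oracle"` with `components` (named vector
#'   `exc_cde, exc_intref, exc_intmed, exc_pie`), `te_excess`, `proportions`,
#'   `pm`, `pai`, `pe`, `theta`, `estimand`, `n_mc`.
#' @export
true_decomposition_oracle <- function(config,
                                      contrast = CONTRASTS,
                                      estimand = c("regression", "analog"),
                                      n_mc = 1e5, seed = 1L) {
  cfg <- validate_sim_config(config)
  contrast <- match.arg(contrast)
  estimand <- match.arg(estimand)
  oc <- cfg$outcome_coefs
  Tt <- cfg$ref_time

  mg <- switch(contrast,
    minoritized_vs_nhw = c("nh_black", "hispanic"),
    nhb_vs_nhw = "nh_black",
    hisp_vs_nhw = "hispanic"
  )
  p_mg <- cfg$p_group[mg] / sum(cfg$p_group[mg])
  keep <- c("nh_white", mg)
  p_keep <- cfg$p_group[keep] / sum(cfg$p_group[keep])

  set.seed(seed)
  group <- sample(keep, n_mc, replace = TRUE, prob = p_keep)
  age <- stats::rnorm(n_mc, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n_mc) < cfg$p_female, "female", "male")
  wave <- ifelse(stats::runif(n_mc) < cfg$p_wave_2008, "2008", "2006")
  education <- draw_education(cfg, group)
  smoking <- sample(SMOKE_LEVELS, n_mc, replace = TRUE, prob = cfg$p_smoking)
  alcohol <- ifelse(stats::runif(n_mc) < cfg$alcohol_p_zero, 0,
                    stats::rexp(n_mc, rate = 1 / cfg$alcohol_mean_pos))
  bmi <- stats::rnorm(n_mc, cfg$bmi_mean, cfg$bmi_sd)
  chronic_count <- stats::rbinom(n_mc, cfg$chronic_size, cfg$chronic_p)
  apoe4 <- stats::rbinom(n_mc, 1L, cfg$p_apoe4_by_group[group])
  sex_idx <- ifelse(sex == "female", 1L, 2L)
  d <- data.frame(age = age, sex = sex, education = education,
                  smoking = smoking, alcohol = alcohol, bmi = bmi,
                  chronic_count = chronic_count, apoe4 = apoe4, wave = wave)

  ltau <- log(cfg$threshold)
  locm <- crp_location_matrix(cfg)
  loc_by <- function(g) locm[match(g, GROUPS), sex_idx]
  pi_gl <- function(g, ap, ed) {  # P(M=1 | group g, sex, apoe4=ap, education=ed)
    1 - stats::pnorm((ltau - loc_by(g) - crp_loading_lp(cfg, ap, ed)) /
                       cfg$crp_scale)
  }

  if (estimand == "regression") {
    # Conditional on the factual (C, L) profile; exposed-side group mixture
    # weighted by prevalence times P(l | group).
    edu_idx <- match(education, EDU_LEVELS)
    w <- sapply(mg, function(g) {
      pa <- cfg$p_apoe4_by_group[[g]]
      p_mg[[g]] * ifelse(apoe4 == 1, pa, 1 - pa) *
        cfg$p_education_by_group[g, ][edu_idx]
    })
    w <- w / rowSums(as.matrix(w))
    w <- as.matrix(w)

    pi0 <- pi_gl("nh_white", apoe4, education)
    pi1 <- numeric(n_mc)
    f1 <- list(`0` = numeric(n_mc), `1` = numeric(n_mc))
    for (k in seq_along(mg)) {
      g <- mg[k]
      pi1 <- pi1 + w[, k] * pi_gl(g, apoe4, education)
      f1$`0` <- f1$`0` + w[, k] * exposure_factor(cfg, g, 0)
      f1$`1` <- f1$`1` + w[, k] * exposure_factor(cfg, g, 1)
    }
    base <- Tt * exp(outcome_base_lp(cfg, d))
    mu00 <- base
    mu01 <- base * exp(oc$beta_M)
    mu10 <- base * f1$`0`
    mu11 <- base * exp(oc$beta_M) * f1$`1`
  } else {
    # Interventional estimand: integrate L out under the index exposure.
    # Enumerate the 6 L cells; covariate terms excluding L factor out.
    base_noL <- Tt * exp(outcome_base_lp(cfg, d) -
                           oc$apoe4 * d$apoe4 - unname(oc$education[d$education]))
    cells <- expand.grid(ap = 0:1, ed = EDU_LEVELS, stringsAsFactors = FALSE)
    p_cell <- function(g) {
      pa <- cfg$p_apoe4_by_group[[g]]
      pe <- cfg$p_education_by_group[g, ]
      ifelse(cells$ap == 1, pa, 1 - pa) * pe[match(cells$ed, EDU_LEVELS)]
    }
    outL <- function(ap, ed) {  # exp(L terms in the outcome model)
      exp(oc$apoe4 * ap + unname(oc$education[ed]))
    }
    # Reference arm: sums over L cells under nh_white.
    pw <- p_cell("nh_white")
    K0 <- sum(pw * mapply(outL, cells$ap, cells$ed))
    pi0 <- numeric(n_mc)
    for (r in seq_len(nrow(cells))) {
      pi0 <- pi0 + pw[r] * pi_gl("nh_white", cells$ap[r], cells$ed[r])
    }
    # Index arm: group mixture; within a cell the outcome A-multiplier is
    # weighted by P(group | A = 1, l).
    K1 <- c(`0` = 0, `1` = 0)
    pi1 <- numeric(n_mc)
    pmix <- as.matrix(sapply(mg, p_cell))  # cells x groups: P(l | g)
    for (k in seq_along(mg)) pmix[, k] <- pmix[, k] * p_mg[[k]]
    p_l1 <- rowSums(pmix)  # P(l | A = 1)
    wgl <- pmix / ifelse(p_l1 > 0, p_l1, 1)  # P(group | A=1, l); 0-mass cells inert
    for (r in seq_len(nrow(cells))) {
      fac0 <- sum(wgl[r, ] * vapply(mg, exposure_factor, 0, cfg = cfg, m = 0))
      fac1 <- sum(wgl[r, ] * vapply(mg, exposure_factor, 0, cfg = cfg, m = 1))
      K1["0"] <- K1["0"] + p_l1[r] * outL(cells$ap[r], cells$ed[r]) * fac0
      K1["1"] <- K1["1"] + p_l1[r] * outL(cells$ap[r], cells$ed[r]) * fac1
      pig <- numeric(n_mc)
      for (k in seq_along(mg)) {
        pig <- pig + wgl[r, k] * pi_gl(mg[k], cells$ap[r], cells$ed[r])
      }
      pi1 <- pi1 + p_l1[r] * pig
    }
    mu00 <- base_noL * K0
    mu01 <- base_noL * K0 * exp(oc$beta_M)
    mu10 <- base_noL * K1[["0"]]
    mu11 <- base_noL * K1[["1"]] * exp(oc$beta_M)
  }

  comp <- fourway_from_cells(mu00, mu01, mu10, mu11, pi0, pi1)
  pr <- derived_proportions(comp$components, comp$te_excess)
  structure(c(comp, pr, list(estimand = estimand, contrast = contrast,
                             n_mc = n_mc)),
            class = "fwdecomp_oracle")
}

#' @export
print.fwdecomp_oracle <- function(x, digits = 4, ...) {
  cat(sprintf("True four-way decomposition (%s estimand, %s, n_mc = %g)\n",
              x$estimand, x$contrast, x$n_mc))
  print(round(c(x$components, te_excess = x$te_excess), digits))
  print(round(c(x$proportions, pm = x$pm, pai = x$pai, pe = x$pe), digits))
  invisible(x)
}
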