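# The main model-fitting entry point: four-way decomposition of a racialized
# disparity in incident dementia with CRP as mediator, with percentile
# bootstrap inference and mediational E-value sensitivity analysis.

#' Four-way decomposition of a disparity in incident dementia
#'
#' Fits the outcome model (Poisson, log link, log person-time offset, with
#' exposure, mediator, exposure-by-mediator interaction and covariates) and
#' the mediator model, and decomposes the total excess relative risk of the
#' chosen exposure contrast into four components: the controlled direct
#' effect (`exc_cde`), reference interaction (`exc_intref`), mediated
#' interaction (`exc_intmed`) and pure indirect effect (`exc_pie`), which
#' sum exactly to the total. Derived proportion measures (percent of the
#' disparity attributable to each component, percent mediated, percent due
#' to interaction, percent eliminated) are reported alongside.
#'
#' Two estimators are available. `"regression"` (default) treats every
#' covariate - including APOE-e4 carrier status and education - as an
#' ordinary confounder and standardizes model predictions over the empirical
#' covariate distribution (direct counterfactual imputation). `"analog"`
#' treats APOE-e4 and/or education as mediator-outcome confounders affected
#' by the exposure (L): models for L given exposure and covariates are
#' fitted, and the g-formula marginalizes the outcome and mediator laws over
#' L within each exposure level, giving the interventional (randomized
#' analog) decomposition.
#'
#' Inference is by nonparametric percentile bootstrap: all models are
#' refitted in each of `B` resamples of rows.
#'
#' @param data Participant records (see [read_cohort()] /
#'   [generate_cohort()]) or a prebuilt [build_analytic_sample()] dataset.
#' @param contrast Exposure contrast: `"minoritized_vs_nhw"` (non-Hispanic
#'   Black and Hispanic together vs non-Hispanic white), `"nhb_vs_nhw"`, or
#'   `"hisp_vs_nhw"`. Ignored when `data` is already an analytic dataset.
#' @param estimator `"regression"` or `"analog"`.
#' @param outcome_mode,mediator,threshold_mode,threshold,adjust,lset Passed
#'   to [build_analytic_sample()] when `data` are raw records. For the
#'   analog estimator `lset` defaults to `c("apoe4", "education")`.
#' @param m_ref Reference mediator level (0 = low CRP).
#' @param m_cde Mediator level at which the controlled direct effect is
#'   evaluated for a continuous mediator (default 1 SD above the mean).
#' @param ref_time Common prediction offset in years (default 6).
#' @param B Bootstrap resamples (default 1000); `B = 0` skips inference.
#' @param seed Integer seed for the bootstrap (and Monte-Carlo L draws).
#' @param level Confidence level for percentile intervals.
#' @param analog_mode `"enumerate"` (exact sum over the 6 L cells, default)
#'   or `"monte_carlo"`.
#' @param n_draws Monte-Carlo draws per person when
#'   `analog_mode = "monte_carlo"`.
#' @param evalue Compute the mediational E-value for the indirect effect.
#' @return An object of class `"fwdecomp"`; see [print.fwdecomp()],
#'   [summary.fwdecomp()], [coef.fwdecomp()], [confint.fwdecomp()],
#'   [plot.fwdecomp()].
#' @examples
#' cohort <- generate_cohort(sim_config(n = 1500), seed = 7)
#' fit <- fwdecomp(cohort$records, contrast = "minoritized_vs_nhw", B = 25,
#'                 seed = 1)
#' fit
#' @export
fwdecomp <- function(data, contrast = CONTRASTS,
                     estimator = c("regression", "analog"),
                     outcome_mode = "dementia",
                     mediator = c("binary", "continuous"),
                     threshold_mode = "fixed_threshold", threshold = 4.73,
                     adjust = "chronic", lset = NULL,
                     m_ref = 0, m_cde = 1, ref_time = 6,
                     B = 1000L, seed = 1L, level = 0.95,
                     analog_mode = c("enumerate", "monte_carlo"),
                     n_draws = 1e4, evalue = TRUE) {
  estimator <- match.arg(estimator)
  mediator <- match.arg(mediator)
  analog_mode <- match.arg(analog_mode)
  cl <- match.call()

  if (!inherits(data, "analytic_dataset")) {
    contrast <- match.arg(contrast)
    if (estimator == "analog" && is.null(lset)) {
      lset <- c("apoe4", "education")
    }
    data <- build_analytic_sample(data, contrast = contrast,
                                  outcome_mode = outcome_mode,
                                  mediator = mediator,
                                  threshold_mode = threshold_mode,
                                  threshold = threshold,
                                  adjust = adjust, lset = lset)
  } else {
    contrast <- attr(data, "contrast")
    mediator <- attr(data, "mediator_kind")
  }
  if (estimator == "analog" && !length(attr(data, "lvars"))) {
    stop("analog estimator requires a dataset built with an active lset ",
         "(e.g. lset = c('apoe4', 'education'))", call. = FALSE)
  }
  n <- nrow(data)

  if (estimator == "regression") {
    covs <- unique(c(attr(data, "covariates"), attr(data, "lvars")))
    Xc <- covariate_matrix(data, covs)
    A <- data$A; M <- data$M; Y <- data$Y; offs <- log(data$t)
    X_out <- cbind(`(Intercept)` = 1, A = A, M = M, `A:M` = A * M, Xc)
    X_med <- cbind(`(Intercept)` = 1, A = A, Xc)
    outcome_fit <- fit_glm(X_out, Y, "poisson_log", offset = offs)
    mediator_fit <- if (mediator == "binary") {
      fit_glm(X_med, M, "binomial_logit")
    } else {
      fit_glm(X_med, M, "gaussian_identity")
    }
    res <- point_decomposition(outcome_fit, mediator_fit, data,
                               m_ref = m_ref, m_cde = m_cde,
                               ref_time = ref_time)
    fits <- list(outcome = outcome_fit, mediator = mediator_fit)

    fam_med <- if (mediator == "binary") stats::binomial() else NULL
    warm_out <- outcome_fit$coefficients
    warm_med <- if (mediator == "binary") mediator_fit$coefficients else NULL
    boot_fn <- function(idx) {
      Ai <- A[idx]; Mi <- M[idx]
      Xci <- Xc[idx, , drop = FALSE]
      Xo <- cbind(`(Intercept)` = 1, A = Ai, M = Mi, `A:M` = Ai * Mi, Xci)
      bo <- fast_glm_coef(Xo, Y[idx], stats::poisson(), offset = offs[idx],
                          start = warm_out)
      Xm <- cbind(`(Intercept)` = 1, A = Ai, Xci)
      if (mediator == "binary") {
        bm <- fast_glm_coef(Xm, Mi, fam_med, start = warm_med)
        sig2 <- NA_real_
      } else {
        lf <- stats::lm.fit(Xm, Mi)
        bm <- lf$coefficients
        sig2 <- sum(lf$residuals^2) / (length(idx) - ncol(Xm))
      }
      q <- regression_point_fast(bo, bm, sig2, Xci, mediator, m_ref, m_cde,
                                 ref_time)
      q
    }
  } else {
    eng <- analog_engine(data)
    l_fits <- fit_confounder_models(data)
    Xc <- eng$Xc
    X_med <- cbind(`(Intercept)` = 1, A = eng$A, Xc, eng$Xl)
    X_out <- cbind(`(Intercept)` = 1, A = eng$A, M = eng$M,
                   `A:M` = eng$A * eng$M, Xc, eng$Xl)
    outcome_fit <- fit_glm(X_out, eng$Y, "poisson_log", offset = log(eng$t))
    mediator_fit <- if (mediator == "binary") {
      fit_glm(X_med, eng$M, "binomial_logit")
    } else {
      fit_glm(X_med, eng$M, "gaussian_identity")
    }
    pt <- analog_decompose(data, l_fits, mediator_fit, outcome_fit,
                           m_ref = m_ref, mode = analog_mode,
                           n_draws = n_draws, seed = seed,
                           ref_time = ref_time)
    res <- pt[c("components", "te_excess", "theta", "ey", "ey_nat", "nie_rr")]
    fits <- c(list(outcome = outcome_fit, mediator = mediator_fit), l_fits)

    warm0 <- analog_fit(eng, seq_len(n))
    boot_fn <- function(idx) {
      co <- analog_fit(eng, idx, warm = warm0)
      r <- analog_point(eng, co, idx, m_ref = m_ref, ref_time = ref_time,
                        mode = analog_mode, n_draws = n_draws, seed = seed,
                        continuous = co$continuous)
      quantity_vector(r)
    }
  }

  pr <- derived_proportions(res$components, res$te_excess)
  boot <- NULL
  if (B > 0) {
    boot <- boot_percentile(n, boot_fn, B = B, seed = seed, level = level)
  }

  sens <- NULL
  if (evalue) {
    cm <- structure(list(ey = res$ey, ey_nat = res$ey_nat, theta = res$theta,
                         nie_rr = res$nie_rr, ref_time = ref_time),
                    class = "counterfactual_means")
    sens <- mediational_evalue(cm, ci = if (!is.null(boot))
      boot$ci["nie_rr", ] else NULL)
  }

  structure(list(
    components = res$components, te_excess = res$te_excess,
    proportions = pr$proportions, pm = pr$pm, pai = pr$pai, pe = pr$pe,
    theta = res$theta, ey = res$ey, ey_nat = res$ey_nat, nie_rr = res$nie_rr,
    ci = if (!is.null(boot)) boot$ci else NULL,
    pvals = if (!is.null(boot)) boot$pvals else NULL,
    n_failed = if (!is.null(boot)) boot$n_failed else NA_integer_,
    unreliable = if (!is.null(boot)) boot$unreliable else FALSE,
    sensitivity = sens, fits = fits,
    estimator = if (estimator == "regression") "regression_based" else
      "randomized_analog",
    mediator_kind = mediator, contrast = contrast, n = n,
    B = if (is.null(boot)) 0L else B, seed = seed, level = level,
    m_ref = m_ref, m_cde = m_cde, ref_time = ref_time, call = cl
  ), class = "fwdecomp")
}

# Regression-based point estimate from bare coefficients (bootstrap hot
# path; mirrors point_decomposition without object overhead).
regression_point_fast <- function(bo_vec, bm_vec, sig2, Xc, mediator,
                                  m_ref, m_cde, ref_time) {
  bo <- split_outcome_coef(bo_vec)
  covlp_out <- if (ncol(Xc)) drop(Xc %*% bo$gamma) else rep(0, nrow(Xc))
  gam_med <- bm_vec[-(1:2)]
  covlp_med <- if (ncol(Xc)) drop(Xc %*% gam_med) else rep(0, nrow(Xc))
  if (mediator == "binary") {
    mu <- function(a, m) {
      ref_time * exp(bo$b0 + bo$bA * a + bo$bM * m + bo$bAM * a * m + covlp_out)
    }
    pi0 <- stats::plogis(bm_vec[[1L]] + covlp_med)
    pi1 <- stats::plogis(bm_vec[[1L]] + bm_vec[[2L]] + covlp_med)
    res <- if (m_ref == 1) {
      fourway_from_cells(mu(0, 1), mu(0, 0), mu(1, 1), mu(1, 0),
                         1 - pi0, 1 - pi1)
    } else {
      fourway_from_cells(mu(0, 0), mu(0, 1), mu(1, 0), mu(1, 1), pi0, pi1)
    }
  } else {
    k <- function(a) bo$bM + a * bo$bAM
    base <- function(a) ref_time * exp(bo$b0 + bo$bA * a + covlp_out)
    mbar <- function(astar) bm_vec[[1L]] + bm_vec[[2L]] * astar + covlp_med
    eyn <- function(a, astar) {
      mean(base(a) * exp(k(a) * mbar(astar) + k(a)^2 * sig2 / 2))
    }
    mu_fix <- function(a, m) mean(base(a) * exp(k(a) * m))
    theta <- eyn(0, 0)
    if (theta <= 0) stop("theta <= 0", call. = FALSE)
    cde <- (mu_fix(1, m_cde) - mu_fix(0, m_cde)) / theta
    pie <- (eyn(0, 1) - theta) / theta
    intmed <- (eyn(1, 1) - eyn(0, 1) - eyn(1, 0) + theta) / theta
    te <- (eyn(1, 1) - theta) / theta
    res <- list(components = c(exc_cde = cde,
                               exc_intref = te - cde - pie - intmed,
                               exc_intmed = intmed, exc_pie = pie),
                te_excess = te, theta = theta,
                nie_rr = eyn(1, 1) / eyn(1, 0))
  }
  quantity_vector(res)
}
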