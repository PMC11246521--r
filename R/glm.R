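# Regression engine: thin, fast wrappers around base IRLS (stats::glm.fit)
# and nnet::multinom for the model families the pipeline needs, plus the
# sequential incidence-rate-ratio and odds-ratio tables.

FW_FAMILIES <- c("poisson_log", "binomial_logit", "categorical_logit",
                 "gaussian_identity")

#' Fit a generalized linear model from a design matrix
#'
#' Maximum-likelihood fitting by iteratively reweighted least squares for the
#' families used throughout the pipeline: Poisson with log link and an
#' optional log person-time offset (incidence models), binomial with logit
#' link (binary mediator and confounder models), multinomial logit
#' (`categorical_logit`, for the 3-level education model, reference =
#' first response level), and Gaussian with identity link (continuous
#' standardized log-CRP mediator).
#'
#' @param x Design matrix including an intercept column (for
#'   `categorical_logit` the intercept is added internally).
#' @param y Response: 0/1 events (poisson/binomial), a factor
#'   (categorical_logit), or numeric (gaussian).
#' @param family One of `"poisson_log"`, `"binomial_logit"`,
#'   `"categorical_logit"`, `"gaussian_identity"`.
#' @param offset Optional offset vector (log person-time for Poisson).
#' @param tol Convergence tolerance on the relative deviance change.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `"fwglm"`: `coefficients` (named vector, or a
#'   class-by-term matrix for the categorical family), `vcov`, `converged`,
#'   `n`, `offset_used`, `family`, and `dispersion` (residual variance,
#'   Gaussian only).
#' @export
fit_glm <- function(x, y, family = FW_FAMILIES, offset = NULL,
                    tol = 1e-8, max_iter = 100L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (family != "categorical_logit" && qr(x)$rank < ncol(x)) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  n <- nrow(x)

  if (family == "categorical_logit") {
    yf <- factor(y)
    df <- data.frame(.y = yf, x, check.names = TRUE)
    fit <- nnet::multinom(.y ~ . - 1, data = df, trace = FALSE,
                          maxit = max_iter)
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                       dimnames = list(levels(yf)[2L], names(co)))
    colnames(co) <- colnames(x)
    return(structure(list(family = family, coefficients = co,
                          vcov = stats::vcov(fit), converged = fit$convergence == 0,
                          n = n, offset_used = FALSE, dispersion = NA_real_,
                          levels = levels(yf)),
                     class = "fwglm"))
  }

  fam <- switch(family,
    poisson_log = stats::poisson(link = "log"),
    binomial_logit = stats::binomial(link = "logit"),
    gaussian_identity = stats::gaussian()
  )
  fit <- suppressWarnings(stats::glm.fit(
    x, y, family = fam, offset = offset,
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  if (!fit$converged) {
    stop("GLM did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  separated <- FALSE
  if (family == "binomial_logit") {
    separated <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10) &&
      max(abs(fit$coefficients)) > 15
    if (separated) warning("possible separation in binomial fit", call. = FALSE)
  }
  p <- ncol(x)
  disp <- if (family == "gaussian_identity") {
    sum(fit$residuals^2 * fit$weights) / (n - p)
  } else 1
  vc <- tryCatch({
    v0 <- chol2inv(qr.R(fit$qr)) * disp
    piv <- fit$qr$pivot
    v <- matrix(NA_real_, p, p)
    v[piv, piv] <- v0
    v
  }, error = function(e) matrix(NA_real_, p, p))
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(family = family, coefficients = fit$coefficients,
                 vcov = vc, converged = fit$converged && !separated,
                 separated = separated, n = n,
                 offset_used = !is.null(offset),
                 dispersion = if (family == "gaussian_identity") disp else NA_real_,
                 deviance = fit$deviance),
            class = "fwglm")
}

#' @export
print.fwglm <- function(x, ...) {
  cat(sprintf("<fwglm> family = %s, n = %d, converged = %s\n",
              x$family, x$n, x$converged))
  print(x$coefficients)
  invisible(x)
}

# Covariate model matrix (no intercept column) for the named covariates.
covariate_matrix <- function(dat, covs) {
  if (!length(covs)) {
    return(matrix(0, nrow(dat), 0))
  }
  stats::model.matrix(stats::reformulate(covs), dat)[, -1L, drop = FALSE]
}

wald_row <- function(fit, term) {
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- b / se
  c(estimate = exp(b), lcl = exp(b - stats::qnorm(0.975) * se),
    ucl = exp(b + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(z)))
}

#' Sequential incidence-rate-ratio table for high CRP
#'
#' Fits Poisson log-link models with a log person-time offset for the
#' association between high CRP and incident dementia, under the four
#' sequential adjustment sets, in five strata: the overall sample, the
#' minoritized group (non-Hispanic Black and Hispanic), and each racialized
#' group separately. In the overall stratum the adjusted models additionally
#' condition on racialized group; within single-group strata group terms are
#' dropped. Wald 95% confidence intervals.
#'
#' @param records Participant records, or a prebuilt `analytic_dataset`
#'   covering all three groups.
#' @param outcome_mode,threshold_mode,threshold Passed to
#'   [build_analytic_sample()] when `records` are raw.
#' @return Data frame with columns `stratum`, `model`, `estimate`, `lcl`,
#'   `ucl`, `p`, `n`, `events`.
#' @export
sequential_irr_suite <- function(records, outcome_mode = "dementia",
                                 threshold_mode = "fixed_threshold",
                                 threshold = 4.73) {
  dat <- if (inherits(records, "analytic_dataset")) records else {
    build_analytic_sample(records, contrast = "minoritized_vs_nhw",
                          outcome_mode = outcome_mode,
                          threshold_mode = threshold_mode,
                          threshold = threshold, adjust = "chronic")
  }
  strata <- list(
    overall = rep(TRUE, nrow(dat)),
    minoritized = dat$group != "nh_white",
    nhb = dat$group == "nh_black",
    hispanic = dat$group == "hispanic",
    nhw = dat$group == "nh_white"
  )
  models <- c("unadjusted", "demographic", "risk_factors", "chronic")
  out <- list()
  for (s in names(strata)) {
    sub <- dat[strata[[s]], , drop = FALSE]
    for (m in models) {
      covs <- adjustment_set(m)
      if (s == "overall" && m != "unadjusted") covs <- c(covs, "group")
      row <- tryCatch({
        if (!nrow(sub) || sum(sub$Y) == 0L) stop("empty stratum")
        Xc <- covariate_matrix(sub, covs)
        X <- cbind(`(Intercept)` = 1, M = sub$M, Xc)
        fit <- fit_glm(X, sub$Y, "poisson_log", offset = log(sub$t))
        wald_row(fit, "M")
      }, error = function(e) c(estimate = NA_real_, lcl = NA_real_,
                               ucl = NA_real_, p = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        stratum = s, model = m, t(row), n = nrow(sub), events = sum(sub$Y))
    }
  }
  do.call(rbind, out)
}

#' Odds-ratio table for high CRP by racialized group membership
#'
#' Logistic models for the odds of high CRP comparing the minoritized group
#' and each racialized group separately to the non-Hispanic white reference,
#' under the four sequential adjustment sets (education and APOE-e4 retained
#' as covariates; group membership is the exposure here).
#'
#' @inheritParams sequential_irr_suite
#' @return Data frame with columns `contrast`, `model`, `estimate`, `lcl`,
#'   `ucl`, `p`, `n`.
#' @export
mediator_or_suite <- function(records, threshold_mode = "fixed_threshold",
                              threshold = 4.73) {
  models <- c("unadjusted", "demographic", "risk_factors", "chronic")
  out <- list()
  for (ctr in CONTRASTS) {
    dat <- if (inherits(records, "analytic_dataset")) {
      sub <- switch(ctr,
        minoritized_vs_nhw = records,
        nhb_vs_nhw = records[records$group != "hispanic", , drop = FALSE],
        hisp_vs_nhw = records[records$group != "nh_black", , drop = FALSE])
      sub$A <- as.integer(sub$group != "nh_white")
      sub
    } else {
      build_analytic_sample(records, contrast = ctr,
                            threshold_mode = threshold_mode,
                            threshold = threshold, adjust = "chronic")
    }
    for (m in models) {
      covs <- adjustment_set(m)
      row <- tryCatch({
        Xc <- covariate_matrix(dat, covs)
        X <- cbind(`(Intercept)` = 1, A = dat$A, Xc)
        fit <- fit_glm(X, dat$M, "binomial_logit")
        wald_row(fit, "A")
      }, error = function(e) c(estimate = NA_real_, lcl = NA_real_,
                               ucl = NA_real_, p = NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        contrast = ctr, model = m, t(row), n = nrow(dat))
    }
  }
  do.call(rbind, out)
}
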