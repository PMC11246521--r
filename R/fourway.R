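# Four-way mediation-interaction decomposition on the excess relative risk
# scale, by direct counterfactual imputation from an outcome model with
# exposure-mediator interaction and a mediator model, standardized over the
# empirical covariate distribution of the analytic sample.

FW_QUANTITIES <- c("exc_cde", "exc_intref", "exc_intmed", "exc_pie",
                   "te_excess", "p_cde", "p_intref", "p_intmed", "p_pie",
                   "pm", "pai", "pe", "nie_rr")

# Core algebra: per-person counterfactual means mu_am and mediator
# probabilities pi_a -> the four excess relative risk components. Works for
# any vectors of equal length (length-1 = closed form, no covariates).
fourway_from_cells <- function(mu00, mu01, mu10, mu11, pi0, pi1) {
  theta <- mean(mu00 * (1 - pi0) + mu01 * pi0)
  if (!is.finite(theta) || theta <= 0) {
    stop("reference counterfactual mean theta must be positive", call. = FALSE)
  }
  inter <- mu11 - mu10 - mu01 + mu00
  components <- c(
    exc_cde = mean(mu10 - mu00) / theta,
    exc_intref = mean(inter * pi0) / theta,
    exc_intmed = mean(inter * (pi1 - pi0)) / theta,
    exc_pie = mean((mu01 - mu00) * (pi1 - pi0)) / theta
  )
  ey_nat <- matrix(c(
    theta,                                     # a = 0, M_0
    mean(mu00 * (1 - pi1) + mu01 * pi1),       # a = 0, M_1
    mean(mu10 * (1 - pi0) + mu11 * pi0),       # a = 1, M_0
    mean(mu10 * (1 - pi1) + mu11 * pi1)        # a = 1, M_1
  ), 2, 2, byrow = TRUE,
  dimnames = list(a = c("0", "1"), astar = c("0", "1")))
  ey <- matrix(c(mean(mu00), mean(mu01), mean(mu10), mean(mu11)), 2, 2,
               byrow = TRUE, dimnames = list(a = c("0", "1"), m = c("0", "1")))
  list(components = components,
       te_excess = (ey_nat["1", "1"] - theta) / theta,
       theta = theta, ey = ey, ey_nat = ey_nat,
       nie_rr = ey_nat["1", "1"] / ey_nat["1", "0"])
}

#' Derived proportion measures of a four-way decomposition
#'
#' Converts the four excess relative risk components into their proportional
#' shares of the total excess relative risk, the percent mediated
#' (mediated interaction plus pure indirect effect), the percent due to
#' interaction (reference plus mediated interaction), and the percent
#' eliminated (everything except the controlled direct effect). The four
#' shares sum to one exactly.
#'
#' @param components Named (or ordered) numeric vector
#'   `(exc_cde, exc_intref, exc_intmed, exc_pie)`.
#' @param te_excess Total excess relative risk; defaults to the component
#'   sum (their algebraic identity).
#' @param tol Proportions are undefined when `|te_excess| < tol`.
#' @return List with `proportions` (`p_cde, p_intref, p_intmed, p_pie`),
#'   `pm`, `pai`, `pe`.
#' @examples
#' derived_proportions(c(1.26, 0.16, 0.04, 0.01))
#' @export
derived_proportions <- function(components, te_excess = NULL, tol = 1e-10) {
  components <- unname(components)
  stopifnot(length(components) == 4L)
  if (is.null(te_excess)) te_excess <- sum(components)
  if (!is.finite(te_excess) || abs(te_excess) < tol) {
    warning("total excess relative risk is ~0; proportions undefined",
            call. = FALSE)
    p <- rep(NA_real_, 4L)
  } else {
    p <- components / te_excess
  }
  names(p) <- c("p_cde", "p_intref", "p_intmed", "p_pie")
  list(proportions = p,
       pm = p[["p_intmed"]] + p[["p_pie"]],
       pai = p[["p_intref"]] + p[["p_intmed"]],
       pe = p[["p_intref"]] + p[["p_intmed"]] + p[["p_pie"]])
}

# Split a fitted coefficient vector into the structural terms and the
# covariate loadings, by position: (Intercept), A, M, A:M, covariates...
split_outcome_coef <- function(b) {
  list(b0 = b[[1L]], bA = b[[2L]], bM = b[[3L]], bAM = b[[4L]],
       gamma = b[-(1:4)])
}

#' Standardized counterfactual outcome means
#'
#' Computes `E[Y(a, m)]` for the four exposure/mediator settings and
#' `E[Y(a, M_a*)]` for the natural-mediator pairs, by predicting the
#' cumulative incidence `T * exp(outcome linear predictor)` for every person
#' at each counterfactual setting and averaging over the empirical covariate
#' distribution of the analytic sample (direct counterfactual imputation).
#' The reference mean is `theta = E[Y(0, M_0)]`.
#'
#' @param outcome_fit A converged `"fwglm"` Poisson fit with terms
#'   `(Intercept), A, M, A:M`, then covariates.
#' @param mediator_fit A converged `"fwglm"` logistic fit with terms
#'   `(Intercept), A`, then covariates (binary mediator), or a Gaussian fit
#'   for the standardized continuous mediator.
#' @param data The analytic dataset both models were fitted on.
#' @param m_ref Reference mediator level (default 0, low CRP).
#' @param ref_time Common prediction offset `T` in years (default 6). All
#'   ratio-scale decomposition quantities are invariant to it.
#' @return List of class `"counterfactual_means"`: `ey` (2x2, exposure by
#'   mediator), `ey_nat` (2x2, exposure by mediator-law exposure), `theta`,
#'   `nie_rr`, `ref_time`.
#' @export
counterfactual_means <- function(outcome_fit, mediator_fit, data,
                                 m_ref = 0, ref_time = 6) {
  cm <- point_decomposition(outcome_fit, mediator_fit, data,
                            m_ref = m_ref, ref_time = ref_time)
  structure(list(ey = cm$ey, ey_nat = cm$ey_nat, theta = cm$theta,
                 nie_rr = cm$nie_rr, ref_time = ref_time),
            class = "counterfactual_means")
}

# Covariate matrix aligned to the covariate coefficients of a fit.
aligned_covariates <- function(data, covnames) {
  if (!length(covnames)) return(matrix(0, nrow(data), 0))
  covs <- unique(c(attr(data, "covariates"), attr(data, "lvars")))
  if (!length(covs)) covs <- setdiff(names(data), c("A", "M", "Y", "t", "group"))
  X <- covariate_matrix(data, covs)
  miss <- setdiff(covnames, colnames(X))
  if (length(miss)) stop("cannot align covariates: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X[, covnames, drop = FALSE]
}

# Shared point-estimation path for the regression-based estimator; handles
# both mediator kinds. Returns components, proportions, and the means.
point_decomposition <- function(outcome_fit, mediator_fit, data,
                                m_ref = 0, m_cde = 1, ref_time = 6) {
  if (ref_time <= 0) stop("ref_time must be positive", call. = FALSE)
  if (!isTRUE(outcome_fit$converged) || !isTRUE(mediator_fit$converged)) {
    stop("model fits must have converged", call. = FALSE)
  }
  bo <- split_outcome_coef(outcome_fit$coefficients)
  bm <- mediator_fit$coefficients
  Xc_out <- aligned_covariates(data, names(bo$gamma))
  covlp_out <- if (ncol(Xc_out)) drop(Xc_out %*% bo$gamma) else
    rep(0, nrow(data))
  gam_med <- bm[-(1:2)]
  Xc_med <- aligned_covariates(data, names(gam_med))
  covlp_med <- if (ncol(Xc_med)) drop(Xc_med %*% gam_med) else
    rep(0, nrow(data))

  if (mediator_fit$family == "binomial_logit") {
    mu <- function(a, m) {
      ref_time * exp(bo$b0 + bo$bA * a + bo$bM * m + bo$bAM * a * m + covlp_out)
    }
    pi0 <- stats::plogis(bm[[1L]] + covlp_med)
    pi1 <- stats::plogis(bm[[1L]] + bm[[2L]] + covlp_med)
    if (m_ref == 1) {  # high CRP as reference: relabel the mediator
      res <- fourway_from_cells(mu(0, 1), mu(0, 0), mu(1, 1), mu(1, 0),
                                1 - pi0, 1 - pi1)
    } else {
      res <- fourway_from_cells(mu(0, 0), mu(0, 1), mu(1, 0), mu(1, 1),
                                pi0, pi1)
    }
  } else if (mediator_fit$family == "gaussian_identity") {
    sig2 <- mediator_fit$dispersion
    if (!is.finite(sig2) || sig2 < 0) stop("invalid mediator residual variance",
                                           call. = FALSE)
    k <- function(a) bo$bM + a * bo$bAM
    base <- function(a) ref_time * exp(bo$b0 + bo$bA * a + covlp_out)
    mbar <- function(astar) bm[[1L]] + bm[[2L]] * astar + covlp_med
    eyn <- function(a, astar) {  # closed-form Gaussian integral
      mean(base(a) * exp(k(a) * mbar(astar) + k(a)^2 * sig2 / 2))
    }
    mu_fix <- function(a, m) mean(base(a) * exp(k(a) * m))
    theta <- eyn(0, 0)
    if (theta <= 0) stop("reference counterfactual mean theta must be positive",
                         call. = FALSE)
    ey_nat <- matrix(c(theta, eyn(0, 1), eyn(1, 0), eyn(1, 1)), 2, 2,
                     byrow = TRUE,
                     dimnames = list(a = c("0", "1"), astar = c("0", "1")))
    cde <- (mu_fix(1, m_cde) - mu_fix(0, m_cde)) / theta
    pie <- (ey_nat["0", "1"] - theta) / theta
    intmed <- (ey_nat["1", "1"] - ey_nat["0", "1"] -
                 ey_nat["1", "0"] + theta) / theta
    te <- (ey_nat["1", "1"] - theta) / theta
    intref <- te - cde - pie - intmed
    res <- list(
      components = c(exc_cde = cde, exc_intref = intref,
                     exc_intmed = intmed, exc_pie = pie),
      te_excess = te, theta = theta,
      ey = matrix(c(mu_fix(0, m_ref), mu_fix(0, m_cde),
                    mu_fix(1, m_ref), mu_fix(1, m_cde)), 2, 2, byrow = TRUE,
                  dimnames = list(a = c("0", "1"),
                                  m = c("m_ref", "m_cde"))),
      ey_nat = ey_nat,
      nie_rr = ey_nat["1", "1"] / ey_nat["1", "0"]
    )
  } else {
    stop("mediator fit must be binomial_logit or gaussian_identity",
         call. = FALSE)
  }
  res
}

#' Four-way decomposition point estimates from fitted models
#'
#' Applies the excess relative risk decomposition to a converged outcome
#' model (Poisson, with exposure, mediator, exposure-by-mediator interaction
#' and covariates) and mediator model, standardizing over the empirical
#' covariate distribution of `data`. With a binary mediator the four
#' components are computed from the per-person counterfactual rates and
#' mediator probabilities; with a Gaussian (standardized log-CRP) mediator
#' the mediator is integrated out in closed form and the controlled direct
#' effect contrasts exposure with the mediator fixed at `m_cde`.
#'
#' @inheritParams counterfactual_means
#' @param m_cde Mediator level at which the controlled direct effect is
#'   evaluated for a continuous mediator (default 1, one SD above the mean).
#' @return List of class `"fwdecomp_points"`: `components`, `te_excess`,
#'   `proportions`, `pm`, `pai`, `pe`, `theta`, `ey`, `ey_nat`, `nie_rr`.
#' @export
fourway_components <- function(outcome_fit, mediator_fit, data,
                               m_ref = 0, m_cde = 1, ref_time = 6) {
  res <- point_decomposition(outcome_fit, mediator_fit, data,
                             m_ref = m_ref, m_cde = m_cde,
                             ref_time = ref_time)
  pr <- derived_proportions(res$components, res$te_excess)
  structure(c(res, pr), class = "fwdecomp_points")
}

# Flatten a decomposition result into the bootstrap quantity vector.
quantity_vector <- function(res, pr = derived_proportions(res$components,
                                                          res$te_excess)) {
  stats::setNames(
    c(res$components, res$te_excess, pr$proportions, pr$pm, pr$pai, pr$pe,
      res$nie_rr),
    FW_QUANTITIES)
}

# Percentile bootstrap over row indices. fn(idx) must return a named
# numeric vector; failures yield NA rows and are dropped with a count.
boot_percentile <- function(n, fn, B = 1000L, seed = 1L, level = 0.95) {
  set.seed(seed)
  draws <- matrix(NA_real_, B, 0)
  first <- TRUE
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    q <- tryCatch(fn(idx), error = function(e) NULL)
    if (first) {
      nm <- if (is.null(q)) FW_QUANTITIES else names(q)
      draws <- matrix(NA_real_, B, length(nm), dimnames = list(NULL, nm))
      first <- FALSE
    }
    if (!is.null(q)) draws[b, ] <- q
  }
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  unreliable <- n_failed > 0.1 * B
  if (unreliable) {
    warning(sprintf("%d of %d bootstrap resamples failed; inference unreliable",
                    n_failed, B), call. = FALSE)
  }
  good <- draws[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- t(apply(good, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                type = 7, names = FALSE))
  colnames(ci) <- c("lcl", "ucl")
  nulls <- ifelse(colnames(good) == "nie_rr", 1, 0)
  pvals <- vapply(seq_len(ncol(good)), function(j) {
    x <- good[, j]
    min(1, 2 * min(mean(x <= nulls[j]), mean(x >= nulls[j])))
  }, 0)
  names(pvals) <- colnames(good)
  list(ci = ci, pvals = pvals, n_failed = n_failed, unreliable = unreliable,
       draws = good)
}

#' Percentile-bootstrap inference for a decomposition estimator
#'
#' Nonparametric bootstrap: rows of the dataset are resampled with
#' replacement `B` times, the estimator (which must refit all of its models)
#' is applied to each resample, and percentile confidence intervals are
#' taken as the empirical `(alpha/2, 1 - alpha/2)` quantiles. Two-sided
#' bootstrap p-values are `2 * min(share of draws <= null, share >= null)`
#' with null 0 for excess components and proportions (1 for the indirect
#' effect risk ratio). Failed resamples are dropped and counted; more than
#' 10% failures marks the inference unreliable.
#'
#' @param data Data frame (rows are resampled).
#' @param estimator Function taking a resampled data frame and returning a
#'   named numeric vector of quantities.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed (identical seed, data and `B` give identical
#'   intervals).
#' @param level Confidence level.
#' @return List with `ci` (matrix with `lcl`, `ucl`), `pvals`, `n_failed`,
#'   `unreliable`, `draws`.
#' @export
bootstrap_decomposition <- function(data, estimator, B = 1000L, seed = 1L,
                                    level = 0.95) {
  est0 <- estimator(data)  # the estimator must succeed on the full data
  stopifnot(is.numeric(est0), !is.null(names(est0)))
  boot_percentile(nrow(data), function(idx) estimator(data[idx, , drop = FALSE]),
                  B = B, seed = seed, level = level)
}
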