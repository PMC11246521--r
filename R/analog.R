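# Interventional ("randomized analog") decomposition via the g-formula, for
# settings where mediator-outcome confounders L (APOE-e4 carrier status,
# education) are themselves affected by the exposure. The mediator value is
# drawn from its marginal-over-L law under the index exposure, independently
# of the L entering the outcome model, so the four components remain
# identifiable despite the exposure-affected confounding.

#' Fit the exposure-affected confounder models
#'
#' Fits one model per L component in the declared factorization order:
#' APOE-e4 carrier status first (binomial logit on exposure and covariates),
#' then education (multinomial logit on exposure, covariates and APOE-e4,
#' reference level high-school-or-less).
#'
#' @param data An `analytic_dataset` built with an active `lset`.
#' @return Named list of `"fwglm"` fits, in factorization order.
#' @export
fit_confounder_models <- function(data) {
  lvars <- attr(data, "lvars")
  if (!length(lvars)) stop("dataset has no exposure-affected confounders (L)",
                           call. = FALSE)
  Xc <- covariate_matrix(data, attr(data, "covariates"))
  fits <- list()
  if ("apoe4" %in% lvars) {
    X <- cbind(`(Intercept)` = 1, A = data$A, Xc)
    fits$apoe4 <- fit_glm(X, data$apoe4, "binomial_logit")
  }
  if ("education" %in% lvars) {
    X <- cbind(`(Intercept)` = 1, A = data$A, Xc)
    if ("apoe4" %in% lvars) X <- cbind(X, apoe4 = data$apoe4)
    fits$education <- fit_glm(X, factor(data$education, levels = EDU_LEVELS),
                              "categorical_logit")
  }
  fits
}

# L-cell bookkeeping: enumerate the finite L state space and the
# corresponding columns of the outcome/mediator design.
l_cells <- function(lvars) {
  grid <- list()
  if ("apoe4" %in% lvars) grid$apoe4 <- 0:1
  if ("education" %in% lvars) grid$education <- EDU_LEVELS
  cells <- expand.grid(grid, stringsAsFactors = FALSE)
  # model-matrix columns contributed by each cell
  cells$cols <- lapply(seq_len(nrow(cells)), function(r) {
    v <- c()
    if ("apoe4" %in% names(cells)) v["apoe4"] <- cells$apoe4[r]
    if ("education" %in% names(cells)) {
      v["educationcollege_some"] <- as.numeric(cells$education[r] == "college_some")
      v["educationgt_college"] <- as.numeric(cells$education[r] == "gt_college")
    }
    v
  })
  cells
}

# Per-person cell probabilities P(l | a, C) for every cell, as an n x ncell
# matrix, from coefficient-only fits (ap: apoe4 logit; ed: multinom coefs).
cell_probs <- function(a, covlp_ap, ed_coef, Xed_base, cells, has_ap, has_ed) {
  n <- if (has_ap) length(covlp_ap$lp) else nrow(Xed_base)
  P <- matrix(1, n, nrow(cells))
  if (has_ap) {
    p1 <- stats::plogis(covlp_ap$intercept + covlp_ap$A * a + covlp_ap$lp)
    for (r in seq_len(nrow(cells))) {
      P[, r] <- if (cells$apoe4[r] == 1) p1 else 1 - p1
    }
  }
  if (has_ed) {
    # ed_coef: (K-1) x p matrix, columns aligned with cbind(Xed_base, apoe4?)
    for (r in seq_len(nrow(cells))) {
      ap <- if (has_ap) cells$apoe4[r] else NULL
      Xr <- Xed_base
      Xr[, "A"] <- a
      if (!is.null(ap)) Xr[, "apoe4"] <- ap
      eta <- Xr %*% t(ed_coef)                 # n x (K-1)
      den <- 1 + rowSums(exp(eta))
      pk <- switch(cells$education[r],
        hs_or_less = 1 / den,
        college_some = exp(eta[, 1L]) / den,
        gt_college = exp(eta[, 2L]) / den)
      P[, r] <- P[, r] * pk
    }
  }
  P
}

#' Randomized-analog four-way decomposition from fitted models
#'
#' Given fitted exposure-affected confounder models, a mediator model
#' conditional on (A, C, L) and an outcome model conditional on
#' (A, M, A x M, C, L), forms for each person and exposure level the
#' marginalized quantities
#' `mu~(a, m, C) = sum_l mu(a, m, C, l) P(l | a, C)` and
#' `pi~_a(C) = sum_l pi(a, C, l) P(l | a, C)`, and plugs them into the same
#' four-way excess relative risk formulas as the regression-based estimator.
#' In `enumerate` mode the (finite, at most 6-cell) L space is summed
#' exactly; `monte_carlo` mode replaces the sums with `n_draws` sampled L
#' values per person.
#'
#' @param data An `analytic_dataset` with an active `lset`.
#' @param l_fits Output of [fit_confounder_models()].
#' @param mediator_fit,outcome_fit Converged `"fwglm"` fits including the L
#'   columns.
#' @param m_ref Reference mediator level.
#' @param mode `"enumerate"` (default) or `"monte_carlo"`.
#' @param n_draws Draws per person in Monte-Carlo mode.
#' @param seed Seed for Monte-Carlo mode.
#' @param ref_time Common prediction offset in years.
#' @return List of class `"fwdecomp_points"` (as [fourway_components()]).
#' @export
analog_decompose <- function(data, l_fits, mediator_fit, outcome_fit,
                             m_ref = 0, mode = c("enumerate", "monte_carlo"),
                             n_draws = 1e4, seed = 1L, ref_time = 6) {
  mode <- match.arg(mode)
  eng <- analog_engine(data)
  co <- list(
    out = outcome_fit$coefficients,
    med = mediator_fit$coefficients,
    med_sig2 = mediator_fit$dispersion,
    ap = if (!is.null(l_fits$apoe4)) l_fits$apoe4$coefficients,
    ed = if (!is.null(l_fits$education)) l_fits$education$coefficients
  )
  res <- analog_point(eng, co, idx = seq_len(nrow(data)), m_ref = m_ref,
                      ref_time = ref_time, mode = mode, n_draws = n_draws,
                      seed = seed,
                      continuous = mediator_fit$family == "gaussian_identity")
  pr <- derived_proportions(res$components, res$te_excess)
  structure(c(res, pr), class = "fwdecomp_points")
}

# Precompute the design pieces the analog estimator reuses across bootstrap
# resamples.
analog_engine <- function(data) {
  covs <- attr(data, "covariates")
  lvars <- attr(data, "lvars")
  if (!length(lvars)) stop("analog estimator needs an active lset", call. = FALSE)
  Xc <- covariate_matrix(data, covs)
  cells <- l_cells(lvars)
  lcolnames <- names(cells$cols[[1L]])
  Xl <- sapply(lcolnames, function(cn) {
    switch(cn,
      apoe4 = data$apoe4,
      educationcollege_some = as.numeric(data$education == "college_some"),
      educationgt_college = as.numeric(data$education == "gt_college"))
  })
  Xl <- matrix(Xl, nrow = nrow(data), dimnames = list(NULL, lcolnames))
  list(A = data$A, M = data$M, Y = data$Y, t = data$t, Xc = Xc, Xl = Xl,
       cells = cells, lvars = lvars,
       has_ap = "apoe4" %in% lvars, has_ed = "education" %in% lvars)
}

# Fit all analog models on rows idx (coefficients only; fast path). `warm`
# optionally carries full-data coefficients to start the resample fits from.
analog_fit <- function(eng, idx, warm = NULL) {
  A <- eng$A[idx]; M <- eng$M[idx]; Y <- eng$Y[idx]; t <- eng$t[idx]
  Xc <- eng$Xc[idx, , drop = FALSE]
  Xl <- eng$Xl[idx, , drop = FALSE]
  X_out <- cbind(`(Intercept)` = 1, A = A, M = M, `A:M` = A * M, Xc, Xl)
  out <- fast_glm_coef(X_out, Y, stats::poisson(), offset = log(t),
                       start = warm$out)
  X_med <- cbind(`(Intercept)` = 1, A = A, Xc, Xl)
  if (is.integer(eng$M) || all(eng$M %in% 0:1)) {
    med <- fast_glm_coef(X_med, M, stats::binomial(), start = warm$med)
    med_sig2 <- NA_real_
    continuous <- FALSE
  } else {
    fit <- stats::lm.fit(X_med, M)
    med <- fit$coefficients
    med_sig2 <- sum(fit$residuals^2) / (length(M) - ncol(X_med))
    continuous <- TRUE
  }
  ap <- ed <- NULL
  if (eng$has_ap) {
    ap <- fast_glm_coef(cbind(`(Intercept)` = 1, A = A, Xc),
                        Xl[, "apoe4"], stats::binomial(), start = warm$ap)
  }
  if (eng$has_ed) {
    ed_lab <- factor(ifelse(Xl[, "educationgt_college"] == 1, "gt_college",
                            ifelse(Xl[, "educationcollege_some"] == 1,
                                   "college_some", "hs_or_less")),
                     levels = EDU_LEVELS)
    Xed <- cbind(`(Intercept)` = 1, A = A, Xc)
    if (eng$has_ap) Xed <- cbind(Xed, apoe4 = Xl[, "apoe4"])
    ed <- if (is.null(warm$ed)) {
      fast_multinom_coef(Xed, ed_lab)
    } else {
      tryCatch(fast_multinom_newton(Xed, ed_lab, start = warm$ed),
               error = function(e) fast_multinom_coef(Xed, ed_lab))
    }
  }
  list(out = out, med = med, med_sig2 = med_sig2, ap = ap, ed = ed,
       ed_wts = if (!is.null(ed)) attr(ed, "wts"), continuous = continuous)
}

# Marginalized point decomposition on rows idx given coefficient set co.
analog_point <- function(eng, co, idx, m_ref = 0, ref_time = 6,
                         mode = "enumerate", n_draws = 1e4, seed = 1L,
                         continuous = FALSE) {
  Xc <- eng$Xc[idx, , drop = FALSE]
  n <- length(idx)
  cells <- eng$cells
  ncell <- nrow(cells)
  lcoln <- colnames(eng$Xl)

  bo <- co$out
  p_struct <- 4L
  gam_out <- bo[setdiff(names(bo), c("(Intercept)", "A", "M", "A:M", lcoln))]
  covlp_out <- if (length(gam_out)) drop(Xc[, names(gam_out), drop = FALSE] %*%
                                           gam_out) else rep(0, n)
  bm <- co$med
  gam_med <- bm[setdiff(names(bm), c("(Intercept)", "A", lcoln))]
  covlp_med <- if (length(gam_med)) drop(Xc[, names(gam_med), drop = FALSE] %*%
                                           gam_med) else rep(0, n)

  covlp_ap <- NULL
  if (eng$has_ap) {
    gap <- co$ap[setdiff(names(co$ap), c("(Intercept)", "A"))]
    covlp_ap <- list(intercept = co$ap[["(Intercept)"]], A = co$ap[["A"]],
                     lp = if (length(gap)) drop(Xc[, names(gap), drop = FALSE] %*%
                                                  gap) else rep(0, n))
  }
  Xed_base <- NULL
  if (eng$has_ed) {
    Xed_base <- cbind(`(Intercept)` = 1, A = 0, Xc)
    if (eng$has_ap) Xed_base <- cbind(Xed_base, apoe4 = 0)
    Xed_base <- Xed_base[, colnames(co$ed), drop = FALSE]
  }
  cellP <- lapply(0:1, function(a) {
    cell_probs(a, covlp_ap, co$ed, Xed_base, cells, eng$has_ap, eng$has_ed)
  })

  out_l <- vapply(cells$cols, function(v) {
    sum(bo[names(v)] * v)
  }, 0)
  med_l <- vapply(cells$cols, function(v) {
    sum(bm[names(v)] * v)
  }, 0)

  if (mode == "monte_carlo") {
    # use a private RNG stream so callers (e.g. the bootstrap) are unaffected
    has_rs <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_rs) old_rs <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_rs) assign(".Random.seed", old_rs, envir = globalenv()),
            add = TRUE)
    set.seed(seed)
    cellP <- lapply(cellP, function(P) {
      cp <- t(apply(P, 1L, cumsum))
      cnt <- matrix(0, n, ncell)
      for (d in seq_len(n_draws)) {
        u <- stats::runif(n)
        k <- rowSums(u > cp) + 1L
        cnt[cbind(seq_len(n), k)] <- cnt[cbind(seq_len(n), k)] + 1
      }
      cnt / n_draws
    })
  }

  if (!continuous) {
    mu_t <- function(a, m) {
      base <- ref_time * exp(bo[["(Intercept)"]] + bo[["A"]] * a +
                               bo[["M"]] * m + bo[["A:M"]] * a * m + covlp_out)
      acc <- 0
      for (r in seq_len(ncell)) {
        acc <- acc + cellP[[a + 1L]][, r] * exp(out_l[r])
      }
      base * acc
    }
    pi_t <- function(a) {
      base <- bm[["(Intercept)"]] + bm[["A"]] * a + covlp_med
      acc <- 0
      for (r in seq_len(ncell)) {
        acc <- acc + cellP[[a + 1L]][, r] * stats::plogis(base + med_l[r])
      }
      acc
    }
    if (m_ref == 1) {
      fourway_from_cells(mu_t(0, 1), mu_t(0, 0), mu_t(1, 1), mu_t(1, 0),
                         1 - pi_t(0), 1 - pi_t(1))
    } else {
      fourway_from_cells(mu_t(0, 0), mu_t(0, 1), mu_t(1, 0), mu_t(1, 1),
                         pi_t(0), pi_t(1))
    }
  } else {
    sig2 <- co$med_sig2
    kf <- function(a) bo[["M"]] + a * bo[["A:M"]]
    base_t <- function(a) {  # sum_l P(l|a) exp(outcome L terms), times base
      base <- ref_time * exp(bo[["(Intercept)"]] + bo[["A"]] * a + covlp_out)
      acc <- 0
      for (r in seq_len(ncell)) {
        acc <- acc + cellP[[a + 1L]][, r] * exp(out_l[r])
      }
      base * acc
    }
    emg <- function(a, astar) {  # E[exp(k_a M~)] over the mixture under astar
      k <- kf(a)
      mb <- bm[["(Intercept)"]] + bm[["A"]] * astar + covlp_med
      acc <- 0
      for (r in seq_len(ncell)) {
        acc <- acc + cellP[[astar + 1L]][, r] * exp(k * (mb + med_l[r]) +
                                                      k^2 * sig2 / 2)
      }
      acc
    }
    eyn <- function(a, astar) mean(base_t(a) * emg(a, astar))
    theta <- eyn(0, 0)
    if (theta <= 0) stop("reference counterfactual mean theta must be positive",
                         call. = FALSE)
    m_cde <- 1
    mu_fix <- function(a, m) mean(base_t(a) * exp(kf(a) * m))
    cde <- (mu_fix(1, m_cde) - mu_fix(0, m_cde)) / theta
    pie <- (eyn(0, 1) - theta) / theta
    intmed <- (eyn(1, 1) - eyn(0, 1) - eyn(1, 0) + theta) / theta
    te <- (eyn(1, 1) - theta) / theta
    intref <- te - cde - pie - intmed
    ey_nat <- matrix(c(theta, eyn(0, 1), eyn(1, 0), eyn(1, 1)), 2, 2,
                     byrow = TRUE,
                     dimnames = list(a = c("0", "1"), astar = c("0", "1")))
    list(components = c(exc_cde = cde, exc_intref = intref,
                        exc_intmed = intmed, exc_pie = pie),
         te_excess = te, theta = theta, ey = NULL, ey_nat = ey_nat,
         nie_rr = ey_nat["1", "1"] / ey_nat["1", "0"])
  }
}

# Coefficient-only IRLS fit (hot path for the bootstrap). An optional warm
# start from the full-data fit cuts the iteration count; on any failure the
# fit is retried cold.
fast_glm_coef <- function(X, y, fam, offset = NULL, start = NULL) {
  run <- function(st) {
    fit <- suppressWarnings(stats::glm.fit(
      X, y, family = fam, offset = offset, start = st,
      control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
    if (!fit$converged) stop("GLM did not converge", call. = FALSE)
    fit$coefficients
  }
  if (is.null(start)) return(run(NULL))
  tryCatch(run(start), error = function(e) run(NULL))
}

# Newton-Raphson for the 3-class multinomial logit MLE (reference = first
# level). Used in the bootstrap hot path, warm-started from the full-data
# nnet::multinom solution; maximizes the same likelihood, so the two
# routes agree at the optimum. Falls back to nnet::multinom if it fails.
fast_multinom_newton <- function(X, yf, start, tol = 1e-8, max_iter = 25L) {
  lev <- levels(yf)
  K <- length(lev)
  p <- ncol(X)
  Yk <- sapply(lev[-1L], function(l) as.numeric(yf == l))  # n x (K-1)
  b <- as.vector(t(start))  # (K-1)*p, class-major rows of start
  loglik <- function(P) sum(log(P[cbind(seq_along(yf), as.integer(yf))]))
  probs <- function(b) {
    eta <- X %*% t(matrix(b, nrow = K - 1L, byrow = TRUE))
    eeta <- exp(eta)
    den <- 1 + rowSums(eeta)
    cbind(1 / den, eeta / den)
  }
  P <- probs(b)
  ll <- loglik(P)
  for (it in seq_len(max_iter)) {
    grad <- as.vector(vapply(seq_len(K - 1L), function(k) {
      crossprod(X, Yk[, k] - P[, k + 1L])[, 1L]
    }, numeric(p)))
    if (max(abs(grad)) < tol * nrow(X)) break
    H <- matrix(0, (K - 1L) * p, (K - 1L) * p)
    for (k in seq_len(K - 1L)) {
      for (l in seq_len(k)) {
        w <- if (k == l) P[, k + 1L] * (1 - P[, k + 1L]) else
          -P[, k + 1L] * P[, l + 1L]
        blk <- crossprod(X * w, X)
        rk <- (k - 1L) * p + seq_len(p)
        rl <- (l - 1L) * p + seq_len(p)
        H[rk, rl] <- blk
        if (k != l) H[rl, rk] <- blk
      }
    }
    step <- solve(H, grad)
    for (half in 0:10) {
      bn <- b + step / 2^half
      Pn <- probs(bn)
      lln <- loglik(Pn)
      if (is.finite(lln) && lln >= ll - 1e-10) break
    }
    if (!is.finite(lln)) stop("multinomial Newton diverged", call. = FALSE)
    conv <- abs(lln - ll) < tol * (abs(ll) + tol)
    b <- bn; P <- Pn; ll <- lln
    if (conv) break
  }
  co <- matrix(b, nrow = K - 1L, byrow = TRUE,
               dimnames = list(lev[-1L], colnames(X)))
  co
}

fast_multinom_coef <- function(X, yf, wts = NULL) {
  df <- data.frame(.y = yf, X, check.names = TRUE)
  fit <- if (is.null(wts)) {
    nnet::multinom(.y ~ . - 1, data = df, trace = FALSE, maxit = 200L)
  } else {
    tryCatch(
      nnet::multinom(.y ~ . - 1, data = df, trace = FALSE, maxit = 200L,
                     Wts = wts),
      error = function(e) nnet::multinom(.y ~ . - 1, data = df, trace = FALSE,
                                         maxit = 200L))
  }
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1)
  colnames(co) <- colnames(X)
  attr(co, "wts") <- fit$wts
  co
}
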