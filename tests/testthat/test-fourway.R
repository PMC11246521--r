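test_that("counterfactual means and components match the hand-worked instance", {
  tf <- toy_fits()  # risks (0.10, 0.20, 0.15, 0.40), pi0 = 0.25, pi1 = 0.50
  cm <- counterfactual_means(tf$outcome, tf$mediator, tf$data)
  expect_equal(cm$theta, 0.125, tolerance = 1e-12)
  expect_equal(cm$ey_nat["1", "1"], 0.275, tolerance = 1e-12)
  expect_equal(unname(cm$ey), matrix(c(0.10, 0.20, 0.15, 0.40), 2, 2,
                                     byrow = TRUE), tolerance = 1e-12)
  fc <- fourway_components(tf$outcome, tf$mediator, tf$data)
  expect_equal(unname(fc$components), c(0.4, 0.3, 0.3, 0.2), tolerance = 1e-12)
  expect_equal(fc$te_excess, 1.2, tolerance = 1e-12)
  # additivity is an algebraic identity
  expect_equal(sum(fc$components), fc$te_excess, tolerance = 1e-13)
})

test_that("null exposure effects and null mediator shifts zero the right components", {
  # outcome model with zero A and A:M coefficients: ey[1, m] = ey[0, m]
  tf <- toy_fits(p00 = 0.1, p01 = 0.2, p10 = 0.1, p11 = 0.2)
  cm <- counterfactual_means(tf$outcome, tf$mediator, tf$data)
  expect_equal(cm$ey["1", ], cm$ey["0", ], tolerance = 1e-12)
  # additive no-interaction cells: both interaction components vanish exactly
  tf2 <- toy_fits(p00 = 0.10, p01 = 0.20, p10 = 0.15, p11 = 0.25)
  fc2 <- fourway_components(tf2$outcome, tf2$mediator, tf2$data)
  expect_equal(unname(fc2$components[c("exc_intref", "exc_intmed")]), c(0, 0),
               tolerance = 1e-12)
  # pi1 = pi0: mediated components vanish exactly
  tf3 <- toy_fits(pi0 = 0.3, pi1 = 0.3)
  fc3 <- fourway_components(tf3$outcome, tf3$mediator, tf3$data)
  expect_equal(unname(fc3$components[c("exc_intmed", "exc_pie")]), c(0, 0),
               tolerance = 1e-12)
})

test_that("ratio-scale quantities are invariant to the common prediction offset", {
  tf <- toy_fits()
  base <- fourway_components(tf$outcome, tf$mediator, tf$data, ref_time = 6)
  for (T in c(1, 100)) {
    alt <- fourway_components(tf$outcome, tf$mediator, tf$data, ref_time = T)
    expect_equal(alt$components, base$components, tolerance = 1e-12)
    expect_equal(alt$te_excess, base$te_excess, tolerance = 1e-12)
    expect_equal(alt$nie_rr, base$nie_rr, tolerance = 1e-12)
    # the means themselves scale linearly in T
    expect_equal(alt$theta, base$theta * T / 6, tolerance = 1e-12)
  }
})

test_that("derived proportions follow their identities", {
  pr <- derived_proportions(c(1, 0.4, 0.4, 0.2))
  expect_equal(sum(pr$proportions), 1, tolerance = 1e-12)
  expect_equal(pr$pm, pr$proportions[["p_intmed"]] + pr$proportions[["p_pie"]])
  # a pure direct effect of any size
  pr2 <- derived_proportions(c(2.7, 0, 0, 0))
  expect_equal(unname(pr2$proportions), c(1, 0, 0, 0))
  expect_equal(c(pr2$pm, pr2$pai, pr2$pe), c(0, 0, 0))
  expect_warning(derived_proportions(c(0.5, -0.5, 0.3, -0.3)), "undefined")
})

test_that("estimated decompositions on fitted synthetic data stay additive per run", {
  g <- generate_cohort(sim_config(n = 3000), seed = 13)
  f <- fwdecomp(g$records, "minoritized_vs_nhw", B = 0, evalue = FALSE)
  expect_equal(sum(f$components), f$te_excess, tolerance = 1e-12)
  expect_equal(sum(f$proportions), 1, tolerance = 1e-12)
})

test_that("continuous-mediator closed form agrees with Monte-Carlo integration", {
  set.seed(31)
  n <- 800
  A <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  Mc <- 0.4 * A + 0.2 * x + rnorm(n, sd = 0.9)
  lam <- exp(-3 + 0.5 * A + 0.3 * Mc + 0.2 * A * Mc + 0.1 * x)
  Y <- rbinom(n, 1, pmin(1 - exp(-6 * lam), 1))
  t <- ifelse(Y == 1, sample(c(2, 4, 6), n, TRUE), 6)
  dat <- data.frame(A = A, M = Mc, Y = Y, t = t, x = x)
  attr(dat, "covariates") <- "x"
  attr(dat, "lvars") <- character(0)
  attr(dat, "mediator_kind") <- "continuous"
  attr(dat, "contrast") <- "nhb_vs_nhw"
  class(dat) <- c("analytic_dataset", "data.frame")
  f <- fwdecomp(dat, estimator = "regression", B = 0, evalue = FALSE)
  # test-side Monte-Carlo oracle for E[Y(a, M_astar)] under the fitted models
  bo <- f$fits$outcome$coefficients
  bm <- f$fits$mediator$coefficients
  s2 <- f$fits$mediator$dispersion
  mc_eyn <- function(a, astar, ndr = 4e5) {
    set.seed(99)
    out <- 0
    for (r in 1:20) {  # 20 blocks of draws, averaged over persons jointly
      Md <- rnorm(n, bm[["(Intercept)"]] + bm[["A"]] * astar + bm[["x"]] * x,
                  sqrt(s2))
      out <- out + mean(6 * exp(bo[["(Intercept)"]] + bo[["A"]] * a +
                                  bo[["M"]] * Md + bo[["A:M"]] * a * Md +
                                  bo[["x"]] * x))
    }
    out / 20
  }
  expect_equal(f$ey_nat["1", "1"], mc_eyn(1, 1), tolerance = 0.02)
  expect_equal(f$ey_nat["0", "1"], mc_eyn(0, 1), tolerance = 0.02)
  expect_equal(sum(f$components), f$te_excess, tolerance = 1e-12)
})

test_that("continuous mediator collapses to the degenerate and no-interaction limits", {
  tf <- toy_fits()
  dat <- tf$data
  attr(dat, "mediator_kind") <- "continuous"
  # gaussian mediator with means 0.3 / 0.8 by arm and vanishing noise
  gfit <- structure(list(family = "gaussian_identity", converged = TRUE,
                         dispersion = 1e-24,
                         coefficients = c(`(Intercept)` = 0.3, A = 0.5)),
                    class = "fwglm")
  f0 <- fourway_components(tf$outcome, gfit, dat, m_cde = 0)
  bo <- tf$outcome$coefficients
  mu <- function(a, m) 6 * exp(bo[["(Intercept)"]] + bo[["A"]] * a +
                                 bo[["M"]] * m + bo[["A:M"]] * a * m)
  theta <- mu(0, 0.3)  # M degenerate at its conditional mean
  expect_equal(f0$theta, theta, tolerance = 1e-8)
  expect_equal(f0$te_excess, (mu(1, 0.8) - theta) / theta, tolerance = 1e-8)
  expect_equal(f0$components[["exc_pie"]], (mu(0, 0.8) - theta) / theta,
               tolerance = 1e-8)
  # no exposure coefficients in the outcome model: PAI and CDE exactly zero
  ofit2 <- tf$outcome
  ofit2$coefficients[["A:M"]] <- 0
  ofit2$coefficients[["A"]] <- 0
  gfit2 <- gfit
  gfit2$dispersion <- 0.5
  f2 <- fourway_components(ofit2, gfit2, dat)
  expect_equal(f2$pai, 0, tolerance = 1e-12)
  expect_equal(f2$components[["exc_cde"]], 0, tolerance = 1e-12)
  # no exposure effect on the mediator law: mediated components exactly zero
  gfit3 <- gfit2
  gfit3$coefficients[["A"]] <- 0
  f3 <- fourway_components(tf$outcome, gfit3, dat)
  expect_equal(unname(f3$components[c("exc_intmed", "exc_pie")]), c(0, 0),
               tolerance = 1e-12)
})

test_that("percentile bootstrap is seed-deterministic and handles degenerate estimators", {
  g <- generate_cohort(sim_config(n = 1200), seed = 17)
  f1 <- fwdecomp(g$records, "minoritized_vs_nhw", B = 40, seed = 5)
  f2 <- fwdecomp(g$records, "minoritized_vs_nhw", B = 40, seed = 5)
  expect_identical(f1$ci, f2$ci)
  expect_identical(f1$pvals, f2$pvals)
  f3 <- fwdecomp(g$records, "minoritized_vs_nhw", B = 40, seed = 6)
  expect_false(identical(f1$ci, f3$ci))
  # an estimator that is invariant under resampling yields zero-width CIs
  dat <- data.frame(v = rnorm(30))
  bs <- bootstrap_decomposition(dat, function(d) c(q = 1.5), B = 50, seed = 2)
  expect_equal(unname(bs$ci["q", ]), c(1.5, 1.5))
  expect_equal(bs$n_failed, 0L)
})
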