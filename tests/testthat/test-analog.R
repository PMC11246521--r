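test_that("confounder models come in declared order and recover the exposure effect", {
  cfg <- sim_config(n = 50000,
                    p_apoe4_by_group = c(nh_white = 0.25, nh_black = 0.35,
                                         hispanic = 0.35))
  g <- generate_cohort(cfg, seed = 23)
  d <- build_analytic_sample(g$records, "nhb_vs_nhw",
                             lset = c("apoe4", "education"))
  fits <- fit_confounder_models(d)
  expect_equal(names(fits), c("apoe4", "education"))
  expect_equal(fits$apoe4$family, "binomial_logit")
  expect_equal(fits$education$family, "categorical_logit")
  truth <- qlogis(0.35) - qlogis(0.25)
  expect_lt(abs(fits$apoe4$coefficients[["A"]] - truth), 0.05)
})

test_that("confounder exposure coefficients vanish when L is independent of A", {
  cfg <- sim_config(n = 20000,
                    p_apoe4_by_group = c(nh_white = 0.3, nh_black = 0.3,
                                         hispanic = 0.3),
                    p_education_by_group = rbind(nh_white = c(0.7, 0.2, 0.1),
                                                 nh_black = c(0.7, 0.2, 0.1),
                                                 hispanic = c(0.7, 0.2, 0.1)))
  g <- generate_cohort(cfg, seed = 24)
  d <- build_analytic_sample(g$records, "nhb_vs_nhw",
                             lset = c("apoe4", "education"))
  fits <- fit_confounder_models(d)
  expect_lt(abs(fits$apoe4$coefficients[["A"]]), 0.12)
  expect_lt(max(abs(fits$education$coefficients[, "A"])), 0.15)
  expect_error(fit_confounder_models(build_analytic_sample(g$records,
                                                           "nhb_vs_nhw")),
               "no exposure-affected")
})

test_that("analog decomposition collapses to the regression-based one when L is inert", {
  g <- generate_cohort(sim_config(n = 2500), seed = 25)
  d <- build_analytic_sample(g$records, "minoritized_vs_nhw",
                             lset = c("apoe4", "education"))
  l_fits <- fit_confounder_models(d)
  eng <- analog_engine(d)
  X_med <- cbind(`(Intercept)` = 1, A = eng$A, eng$Xc, eng$Xl)
  X_out <- cbind(`(Intercept)` = 1, A = eng$A, M = eng$M,
                 `A:M` = eng$A * eng$M, eng$Xc, eng$Xl)
  ofit <- fit_glm(X_out, eng$Y, "poisson_log", offset = log(eng$t))
  mfit <- fit_glm(X_med, eng$M, "binomial_logit")
  # force the L coefficients in mediator and outcome models to exactly zero
  lcols <- colnames(eng$Xl)
  ofit$coefficients[lcols] <- 0
  mfit$coefficients[lcols] <- 0
  an <- analog_decompose(d, l_fits, mfit, ofit)
  rb <- fourway_components(ofit, mfit, d)
  expect_equal(an$components, rb$components, tolerance = 1e-10)
  expect_equal(an$te_excess, rb$te_excess, tolerance = 1e-10)
})

test_that("enumerate and Monte-Carlo L-marginalization agree", {
  g <- generate_cohort(sim_config(n = 2000), seed = 26)
  d <- build_analytic_sample(g$records, "minoritized_vs_nhw",
                             lset = c("apoe4", "education"))
  fe <- fwdecomp(d, estimator = "analog", B = 0, evalue = FALSE)
  f1 <- fwdecomp(d, estimator = "analog", B = 0, evalue = FALSE,
                 analog_mode = "monte_carlo", n_draws = 4000, seed = 1)
  f2 <- fwdecomp(d, estimator = "analog", B = 0, evalue = FALSE,
                 analog_mode = "monte_carlo", n_draws = 4000, seed = 2)
  # two independent MC runs bracket the sampling noise; the enumerate result
  # must sit within a few of their spreads
  mc_spread <- pmax(abs(f1$components - f2$components), 1e-4)
  expect_true(all(abs(fe$components - f1$components) < 5 * mc_spread + 0.003))
  expect_equal(sum(f1$components), f1$te_excess, tolerance = 1e-12)
})

test_that("analog and regression estimators coincide when L is group-invariant", {
  cfg <- sim_config(n = 40000,
                    p_apoe4_by_group = c(nh_white = 0.27, nh_black = 0.27,
                                         hispanic = 0.27),
                    p_education_by_group = rbind(nh_white = c(0.7, 0.2, 0.1),
                                                 nh_black = c(0.7, 0.2, 0.1),
                                                 hispanic = c(0.7, 0.2, 0.1)))
  g <- generate_cohort(cfg, seed = 27)
  fa <- fwdecomp(g$records, "minoritized_vs_nhw", estimator = "analog",
                 B = 0, evalue = FALSE)
  fr <- fwdecomp(g$records, "minoritized_vs_nhw", estimator = "regression",
                 B = 0, evalue = FALSE)
  expect_equal(fa$proportions, fr$proportions, tolerance = 0.01)
})
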