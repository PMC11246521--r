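test_that("Poisson fits with offsets recover closed-form rate estimates", {
  # intercept-only: MLE is log(total events / total person-time)
  y <- c(3, 0, 1, 2, 0, 1)
  t <- c(6, 6, 2, 4, 6, 6)
  fit <- fit_glm(matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)")), y,
                 "poisson_log", offset = log(t))
  expect_equal(unname(fit$coefficients), log(sum(y) / sum(t)),
               tolerance = 1e-10)
  expect_true(fit$offset_used)
  # two-arm: 20 events / 100 py vs 10 events / 100 py -> IRR 2.0
  X <- cbind(`(Intercept)` = 1, A = c(0, 1))
  fit2 <- fit_glm(X, c(10, 20), "poisson_log", offset = log(c(100, 100)))
  expect_equal(exp(fit2$coefficients[["A"]]), 2.0, tolerance = 1e-10)
})

test_that("logistic fit on a 2x2 table matches the odds-ratio closed form", {
  # (a, b, c, d) = (30, 70, 15, 85)
  y <- rep(c(1, 0, 1, 0), c(30, 70, 15, 85))
  A <- rep(c(1, 1, 0, 0), c(30, 70, 15, 85))
  fit <- fit_glm(cbind(`(Intercept)` = 1, A = A), y, "binomial_logit")
  expect_equal(exp(fit$coefficients[["A"]]), (30 * 85) / (70 * 15),
               tolerance = 1e-8)
  # vcov is symmetric PSD with matching dimension
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > 0))
})

test_that("IRLS fixed point satisfies the score equations for canonical links", {
  set.seed(8)
  n <- 400
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rpois(n, exp(-1 + 0.5 * X[, 2] - 0.3 * X[, 3]))
  fit <- fit_glm(X, y, "poisson_log")
  mu <- exp(drop(X %*% fit$coefficients))
  expect_lt(max(abs(crossprod(X, y - mu))), 1e-8 * n)
  # a balanced covariate orthogonal to the exposure (and to the response
  # pattern) leaves the exposure coefficient unchanged
  A <- rep(0:1, n / 2)
  z <- rep(c(-1, 1), each = n / 2)  # balanced within exposure arms
  yy <- ifelse(A == 1, 5, 2)
  f1 <- fit_glm(cbind(1, A = A), yy, "poisson_log")
  f2 <- fit_glm(cbind(1, A = A, z = z), yy, "poisson_log")
  expect_lt(abs(f1$coefficients[["A"]] - f2$coefficients[["A"]]), 1e-6)
})

test_that("gaussian and categorical families report their extras; errors surface", {
  set.seed(3)
  n <- 300
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n, sd = 0.7)
  fit <- fit_glm(X, y, "gaussian_identity")
  res <- y - drop(X %*% fit$coefficients)
  expect_equal(fit$dispersion, sum(res^2) / (n - 2), tolerance = 1e-10)
  ed <- factor(sample(c("hs_or_less", "college_some", "gt_college"), n, TRUE),
               levels = c("hs_or_less", "college_some", "gt_college"))
  fitc <- fit_glm(X, ed, "categorical_logit")
  expect_equal(rownames(fitc$coefficients), c("college_some", "gt_college"))
  expect_error(fit_glm(cbind(1, x = X[, 2], x2 = 2 * X[, 2]), y,
                       "gaussian_identity"), "rank-deficient")
})

test_that("sequential IRR suite has the 4 x 5 layout and recovers a common IRR", {
  cfg <- sim_config(n = 50000,
                    outcome_coefs = utils::modifyList(
                      sim_config()$outcome_coefs,
                      list(beta_M = log(1.25),
                           beta_AM = c(nh_black = 0, hispanic = 0))))
  g <- generate_cohort(cfg, seed = 21)
  tab <- sequential_irr_suite(g$records)
  expect_equal(nrow(tab), 20L)
  expect_equal(unique(tab$model),
               c("unadjusted", "demographic", "risk_factors", "chronic"))
  expect_equal(unique(tab$stratum),
               c("overall", "minoritized", "nhb", "hispanic", "nhw"))
  full <- tab[tab$stratum == "overall" & tab$model == "chronic", ]
  expect_lt(abs(full$estimate - 1.25), 0.05)
  expect_true(full$lcl < full$estimate & full$estimate < full$ucl)
})

test_that("mediator OR suite covers the three contrasts and is null under no shift", {
  cfg <- sim_config(n = 60000)
  cfg$crp_mean_by_group_sex <- rbind(nh_white = c(4.5, 3.5),
                                     nh_black = c(4.5, 3.5),
                                     hispanic = c(4.5, 3.5))
  g <- generate_cohort(cfg, seed = 22)
  tab <- mediator_or_suite(g$records)
  expect_equal(nrow(tab), 12L)
  expect_setequal(unique(tab$contrast),
                  c("minoritized_vs_nhw", "nhb_vs_nhw", "hisp_vs_nhw"))
  chronic <- tab[tab$model == "chronic", ]
  expect_true(all(abs(chronic$estimate - 1) < 0.1))
})
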