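test_that("oracle reproduces the closed-form worked instance exactly", {
  cfg <- worked_instance_config()
  # covariate-free: every profile is identical, so any n_mc is exact
  for (est in c("regression", "analog")) {
    orc <- true_decomposition_oracle(cfg, "nhb_vs_nhw", est, n_mc = 200,
                                     seed = 1)
    expect_equal(unname(orc$components), c(0.4, 0.3, 0.3, 0.2),
                 tolerance = 1e-12)
    expect_equal(orc$te_excess, 1.2, tolerance = 1e-12)
    expect_equal(orc$theta, 0.125, tolerance = 1e-12)
    expect_equal(unname(orc$pm), 0.5 / 1.2, tolerance = 1e-12)
    expect_equal(unname(orc$pai), 0.6 / 1.2, tolerance = 1e-12)
  }
})

test_that("oracle components are additive and stable across seeds", {
  cfg <- sim_config()
  o1 <- true_decomposition_oracle(cfg, "minoritized_vs_nhw", n_mc = 5e4,
                                  seed = 11)
  o2 <- true_decomposition_oracle(cfg, "minoritized_vs_nhw", n_mc = 5e4,
                                  seed = 12)
  expect_equal(sum(o1$components), o1$te_excess, tolerance = 1e-12)
  expect_equal(sum(o2$components), o2$te_excess, tolerance = 1e-12)
  expect_equal(o1$components, o2$components, tolerance = 0.05)
  expect_lt(abs(o1$pai - o2$pai), 0.02)
})

test_that("interaction and mediated components vanish when the mechanism has none", {
  # no exposure effect on the outcome at all: only the mediator pathway left
  cfg <- worked_instance_config()
  cfg$outcome_coefs$beta_A <- c(nh_black = 0, hispanic = 0)
  cfg$outcome_coefs$beta_AM <- c(nh_black = 0, hispanic = 0)
  orc <- true_decomposition_oracle(cfg, "nhb_vs_nhw", n_mc = 100, seed = 1)
  expect_equal(unname(orc$components[c("exc_cde", "exc_intref", "exc_intmed")]),
               c(0, 0, 0), tolerance = 1e-12)
  expect_equal(orc$te_excess, orc$components[["exc_pie"]], tolerance = 1e-12)
  expect_gt(orc$components[["exc_pie"]], 0)
  # no exposure effect on the mediator (pi1 = pi0): mediated components vanish
  cfg2 <- worked_instance_config()
  cfg2$crp_mean_by_group_sex[] <- cfg2$crp_mean_by_group_sex["nh_white", 1]
  orc2 <- true_decomposition_oracle(cfg2, "nhb_vs_nhw", n_mc = 100, seed = 1)
  expect_equal(unname(orc2$components[c("exc_intmed", "exc_pie")]), c(0, 0),
               tolerance = 1e-12)
  # positive interaction with an exposure-mediator path implies positive PAI
  cfg3 <- worked_instance_config()
  orc3 <- true_decomposition_oracle(cfg3, "nhb_vs_nhw", n_mc = 100, seed = 1)
  expect_gt(orc3$pai, 0)
})
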