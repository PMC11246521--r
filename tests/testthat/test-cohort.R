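test_that("cognitive classification partitions the 0-27 scale with exact boundaries", {
  cls <- classify_cognitive_status(0:27)
  expect_equal(cls[1:7], rep("dementia", 7))
  expect_equal(cls[8:12], rep("cind", 5))
  expect_equal(cls[13:28], rep("normal", 16))
  # every integer maps to exactly one class
  expect_false(any(is.na(cls)))
  expect_error(classify_cognitive_status(28), "0, 27")
  expect_error(classify_cognitive_status(-1), "0, 27")
  expect_error(classify_cognitive_status(6.5), "0, 27")
  expect_true(is.na(classify_cognitive_status(NA)))
})

test_that("incident outcome derivation follows first qualifying wave and censoring", {
  d <- function(...) derive_incident_outcome(c(...))
  expect_equal(d("normal", "normal", "normal", "dementia")[c("Y", "t")],
               list(Y = 1L, t = 6))
  expect_equal(d("cind", "dementia", NA, NA)[c("Y", "t")],
               list(Y = 1L, t = 2))
  expect_equal(d("normal", "cind", "cind", "cind")[c("Y", "t")],
               list(Y = 0L, t = 6))
  # CIND-inclusive outcome converts baseline-normal participants at CIND onset
  expect_equal(derive_incident_outcome(c("normal", "cind", "cind", "cind"),
                                       "impairment")[c("Y", "t")],
               list(Y = 1L, t = 2))
  # baseline-CIND participants are still followed for dementia only
  expect_equal(derive_incident_outcome(c("cind", "cind", "cind", "cind"),
                                       "impairment")[c("Y", "t")],
               list(Y = 0L, t = 6))
  # intermittent missing wave: event counted at first observed dementia wave
  expect_equal(d("normal", NA, "dementia", NA)[c("Y", "t")],
               list(Y = 1L, t = 4))
  expect_equal(d("dementia", "dementia", NA, NA)$exclude, "baseline_dementia")
  expect_equal(d("normal", NA, NA, NA)$exclude, "no_followup")
})

test_that("outcome derivation is monotone in added dementia waves", {
  pool <- c("normal", "cind")
  set.seed(42)
  for (rep in 1:50) {
    st <- c(sample(pool, 1), sample(c(pool, "dementia"), 3, replace = TRUE))
    base <- derive_incident_outcome(st)
    for (j in 2:4) {
      st2 <- st
      st2[j] <- "dementia"
      out2 <- derive_incident_outcome(st2)
      expect_gte(out2$Y, base$Y)
      expect_lte(out2$t, base$t)
    }
  }
})

test_that("vectorized outcome derivation matches the per-row operation", {
  set.seed(7)
  pool <- c("normal", "cind", "dementia", NA)
  st <- matrix(sample(pool, 4 * 200, replace = TRUE,
                      prob = c(0.5, 0.2, 0.2, 0.1)), ncol = 4)
  st[, 1] <- sample(c("normal", "cind", "dementia"), 200, TRUE,
                    prob = c(0.7, 0.2, 0.1))
  for (mode in c("dementia", "impairment")) {
    vec <- fwdecomp:::derive_incident_outcome_all(st, mode)
    for (i in seq_len(nrow(st))) {
      ref <- derive_incident_outcome(st[i, ], mode)
      expect_identical(vec$exclude[i], ref$exclude)
      if (is.na(ref$exclude)) {
        expect_identical(vec$Y[i], ref$Y)
        expect_identical(vec$t[i], ref$t)
      }
    }
  }
})

test_that("mediator dichotomization honours fixed and percentile thresholds", {
  x <- dichotomize_mediator(c(4.72, 4.73, 10, 0))
  expect_equal(as.integer(x), c(0L, 1L, 1L, 0L))
  expect_equal(attr(x, "threshold"), 4.73)
  # type-7 quantile of 1:4 at 0.75 is 3.25; only the value 4 is flagged
  q <- dichotomize_mediator(1:4, mode = "percentile", value = 0.75)
  expect_equal(attr(q, "threshold"), 3.25)
  expect_equal(as.integer(q), c(0L, 0L, 0L, 1L))
  expect_error(dichotomize_mediator(numeric(0)), "empty")
  expect_error(dichotomize_mediator(c(1, -2)), "non-negative")
  expect_error(dichotomize_mediator(c(1, NA)), "missing")
})

test_that("analytic samples have the contrast-specific sizes and share the reference arm", {
  rec <- make_records(sizes = c(nh_white = 5462, nh_black = 813, hispanic = 633),
                      events = c(nh_white = 521, nh_black = 171, hispanic = 103))
  d_min <- build_analytic_sample(rec, "minoritized_vs_nhw")
  d_nhb <- build_analytic_sample(rec, "nhb_vs_nhw")
  d_his <- build_analytic_sample(rec, "hisp_vs_nhw")
  expect_equal(nrow(d_min), 6908)
  expect_equal(nrow(d_nhb), 6275)
  expect_equal(nrow(d_his), 6095)
  # both sub-contrasts share the reference arm
  expect_equal(nrow(d_min), nrow(d_nhb) + nrow(d_his) - sum(rec$group == "nh_white"))
  expect_equal(sort(unique(d_nhb$group)), c("nh_black", "nh_white"))
  expect_true(all(d_min$A[d_min$group != "nh_white"] == 1))
  # Y = 0 implies t = 6; Y = 1 implies t in {2, 4, 6}; no missing anywhere
  for (d in list(d_min, d_nhb, d_his)) {
    expect_true(all(d$t[d$Y == 0] == 6))
    expect_true(all(d$t[d$Y == 1] %in% c(2, 4, 6)))
    expect_false(anyNA(d))
  }
})

test_that("complete-case and baseline exclusions are applied and tallied", {
  rec <- make_records()
  rec$bmi[3] <- NA           # incomplete covariate
  rec$cog0[7] <- 2L          # prevalent dementia at baseline
  rec$cog2[9] <- rec$cog4[9] <- rec$cog6[9] <- NA  # no follow-up
  d <- build_analytic_sample(rec, "minoritized_vs_nhw")
  expect_equal(nrow(d), nrow(rec) - 3L)
  excl <- attr(d, "exclusions")
  expect_equal(unname(excl[c("baseline_dementia", "no_followup", "incomplete")]),
               c(1L, 1L, 1L))
  expect_error(
    build_analytic_sample(rec[rec$group == "nh_white", ], "minoritized_vs_nhw"),
    "degenerate"
  )
})

test_that("cohort summary reproduces cumulative incidences as percentages", {
  d <- data.frame(
    group = rep(c("nh_black", "hispanic", "nh_white"), c(813, 633, 5462)),
    Y = 0L
  )
  d$Y[which(d$group == "nh_black")[1:171]] <- 1L
  d$Y[which(d$group == "hispanic")[1:103]] <- 1L
  d$Y[which(d$group == "nh_white")[1:521]] <- 1L
  s <- summarize_cohort(d)
  expect_equal(s$n, 6908)
  expect_equal(s$events, 795)
  expect_equal(s$cumulative_incidence, 100 * 795 / 6908)
  inc <- setNames(s$by_group$incidence_pct, s$by_group$group)
  expect_equal(inc[["nh_black"]], 100 * 171 / 813)
  # zero events
  expect_equal(summarize_cohort(data.frame(group = "nh_white",
                                           Y = 0L))$cumulative_incidence, 0)
  expect_error(summarize_cohort(data.frame()), "empty")
})
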