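# Cohort construction: cognitive classification, incident outcome derivation,
# mediator dichotomization, and assembly of analysis-ready datasets.

GROUPS <- c("nh_white", "nh_black", "hispanic")
EDU_LEVELS <- c("hs_or_less", "college_some", "gt_college")
SMOKE_LEVELS <- c("never", "former", "current")
SEX_LEVELS <- c("female", "male")
CONTRASTS <- c("minoritized_vs_nhw", "nhb_vs_nhw", "hisp_vs_nhw")
COG_COLS <- c("cog0", "cog2", "cog4", "cog6")

#' Classify cognitive status from a 27-point composite score
#'
#' Maps the 27-point cognitive composite (immediate and delayed word recall,
#' serial 7s, backwards counting) to the Langa-Weir three-level classification:
#' scores 0-6 are dementia, 7-11 cognitive impairment non-dementia (CIND), and
#' 12-27 cognitively normal.
#'
#' @param score Integer vector of composite scores in `[0, 27]`. `NA` allowed
#'   (propagated).
#' @return Character vector with values `"dementia"`, `"cind"`, `"normal"`.
#' @examples
#' classify_cognitive_status(c(0, 6, 7, 11, 12, 27))
#' @export
classify_cognitive_status <- function(score) {
  ok <- is.na(score) | (is.numeric(score) & score == round(score) &
                          score >= 0 & score <= 27)
  if (!all(ok)) {
    stop("cognitive scores must be integers in [0, 27]", call. = FALSE)
  }
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score <= 6] <- "dementia"
  out[!is.na(score) & score >= 7 & score <= 11] <- "cind"
  out[!is.na(score) & score >= 12] <- "normal"
  out
}

#' Derive an interval-censored incident outcome from per-wave statuses
#'
#' Participants enter free of dementia (cognitively normal or CIND at
#' baseline) and are followed at 2-year intervals for up to 6 years, until
#' their cognitive classification first meets the outcome criterion or until
#' administrative censoring at 6 years. Under `outcome_mode = "dementia"` the
#' event is a dementia classification at any follow-up wave; under
#' `outcome_mode = "impairment"` (a sensitivity outcome) dementia-or-CIND
#' counts as an event for participants who were cognitively normal at
#' baseline, while baseline-CIND participants are still followed for dementia.
#' An intermittent missing wave followed by an observed event counts the event
#' at the first observed qualifying wave.
#'
#' @param statuses Character vector of length 4: baseline plus follow-ups at
#'   +2, +4, +6 years, values in `dementia`/`cind`/`normal` or `NA`.
#' @param outcome_mode `"dementia"` (default) or `"impairment"`.
#' @return List with elements `Y` (0/1), `t` (years, in `{2, 4, 6}`), and
#'   `exclude` (`NA`, or `"baseline_dementia"` / `"no_followup"`).
#' @export
derive_incident_outcome <- function(statuses, outcome_mode = c("dementia", "impairment")) {
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(length(statuses) == 4L)
  base <- statuses[1L]
  fu <- statuses[-1L]
  if (!is.na(base) && base == "dementia") {
    return(list(Y = NA_integer_, t = NA_real_, exclude = "baseline_dementia"))
  }
  if (all(is.na(fu))) {
    return(list(Y = NA_integer_, t = NA_real_, exclude = "no_followup"))
  }
  event_states <- if (outcome_mode == "impairment" && !is.na(base) && base == "normal") {
    c("dementia", "cind")
  } else {
    "dementia"
  }
  hit <- which(!is.na(fu) & fu %in% event_states)
  if (length(hit)) {
    list(Y = 1L, t = 2 * hit[1L], exclude = NA_character_)
  } else {
    list(Y = 0L, t = 6, exclude = NA_character_)
  }
}

# Vectorized outcome derivation over a status matrix (baseline + 3
# follow-ups); same semantics as derive_incident_outcome row by row.
derive_incident_outcome_all <- function(status, outcome_mode = "dementia") {
  n <- nrow(status)
  base <- status[, 1L]
  fu <- status[, -1L, drop = FALSE]
  exclude <- rep(NA_character_, n)
  exclude[!is.na(base) & base == "dementia"] <- "baseline_dementia"
  exclude[is.na(exclude) & rowSums(!is.na(fu)) == 0L] <- "no_followup"
  hit <- fu == "dementia"
  if (outcome_mode == "impairment") {
    from_normal <- !is.na(base) & base == "normal"
    hit <- hit | (from_normal & fu == "cind")
  }
  hit[is.na(hit)] <- FALSE
  first <- max.col(hit, ties.method = "first")
  first[rowSums(hit) == 0L] <- NA_integer_
  Y <- ifelse(is.na(first), 0L, 1L)
  t <- ifelse(is.na(first), 6, 2 * first)
  Y[!is.na(exclude)] <- NA_integer_
  t[!is.na(exclude)] <- NA_real_
  list(Y = Y, t = t, exclude = exclude)
}

#' Dichotomize the mediator at a high-inflammation threshold
#'
#' Flags serum C-reactive protein at or above a cutoff denoting high systemic
#' inflammation. The default cutoff 4.73 ug/mL is the 75th percentile of the
#' source biomarker sample; alternatively the threshold can be recomputed as
#' an empirical percentile of the supplied vector (linear-interpolation
#' type-7 quantile).
#'
#' @param crp Numeric vector of CRP concentrations (ug/mL), non-negative.
#' @param mode `"fixed_threshold"` (default) or `"percentile"`.
#' @param value The absolute cutoff in fixed mode (default 4.73), or the
#'   percentile (default 0.75) in percentile mode.
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return Integer 0/1 vector; attribute `"threshold"` holds the cutoff used.
#' @examples
#' dichotomize_mediator(c(4.72, 4.73, 10))
#' dichotomize_mediator(1:4, mode = "percentile", value = 0.75)
#' @export
dichotomize_mediator <- function(crp, mode = c("fixed_threshold", "percentile"),
                                 value = if (mode == "percentile") 0.75 else 4.73,
                                 quantile_type = 7) {
  mode <- match.arg(mode)
  if (length(crp) == 0L) stop("empty CRP vector", call. = FALSE)
  if (any(is.na(crp))) stop("CRP vector contains missing values", call. = FALSE)
  if (any(crp < 0)) stop("CRP must be non-negative", call. = FALSE)
  thr <- if (mode == "fixed_threshold") {
    value
  } else {
    if (value <= 0 || value >= 1) stop("percentile must be in (0, 1)", call. = FALSE)
    unname(stats::quantile(crp, probs = value, type = quantile_type))
  }
  structure(as.integer(crp >= thr), threshold = thr)
}

#' Named covariate adjustment sets
#'
#' The four sequential adjustment sets used throughout: `unadjusted` (none),
#' `demographic` (age, sex, education, APOE-e4 carrier status, survey wave),
#' `risk_factors` (demographic plus smoking status, alcohol consumption, body
#' mass index) and `chronic` (risk factors plus chronic condition count).
#'
#' @param set One of `"unadjusted"`, `"demographic"`, `"risk_factors"`,
#'   `"chronic"`.
#' @return Character vector of covariate column names (possibly empty).
#' @export
adjustment_set <- function(set = c("chronic", "risk_factors", "demographic", "unadjusted")) {
  set <- match.arg(set)
  switch(set,
    unadjusted = character(0),
    demographic = c("age", "sex", "education", "apoe4", "wave"),
    risk_factors = c("age", "sex", "education", "apoe4", "wave",
                     "smoking", "alcohol", "bmi"),
    chronic = c("age", "sex", "education", "apoe4", "wave",
                "smoking", "alcohol", "bmi", "chronic_count")
  )
}

#' Read a person-level cohort CSV
#'
#' Expects one row per participant with columns named after the participant
#' record fields (`id, wave, group, age, sex, education, smoking, alcohol,
#' bmi, chronic_count, apoe4, crp`) and cognitive scores `cog0, cog2, cog4,
#' cog6`; empty cells are missing.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame of participant records.
#' @export
read_cohort <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  validate_records(rec)
  rec
}

validate_records <- function(records) {
  needed <- c("id", "wave", "group", "age", "sex", "education", "smoking",
              "alcohol", "bmi", "chronic_count", "apoe4", "crp", COG_COLS)
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("missing cohort columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  chk_lvl <- function(x, lv, nm) {
    bad <- !is.na(x) & !x %in% lv
    if (any(bad)) stop("invalid ", nm, " value(s): ",
                       paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  chk_lvl(records$group, GROUPS, "group")
  chk_lvl(records$sex, SEX_LEVELS, "sex")
  chk_lvl(records$education, EDU_LEVELS, "education")
  chk_lvl(records$smoking, SMOKE_LEVELS, "smoking")
  if (any(records$crp < 0, na.rm = TRUE)) stop("crp must be >= 0", call. = FALSE)
  if (any(!records$chronic_count %in% 0:8, na.rm = TRUE)) {
    stop("chronic_count must be an integer in 0..8", call. = FALSE)
  }
  for (cc in COG_COLS) classify_cognitive_status(records[[cc]])
  invisible(records)
}

#' Build the analytic dataset for one exposure contrast
#'
#' Restricts person-level records to the two racialized groups of the
#' requested contrast (for `minoritized_vs_nhw`, non-Hispanic Black and
#' Hispanic together versus non-Hispanic white), excludes participants with
#' prevalent dementia at baseline, with no observed follow-up, or with
#' incomplete covariate/mediator information (complete-case), derives the
#' interval-censored incident outcome and person-time, codes the exposure
#' `A` (1 = minoritized side) and the mediator `M` (binary high-CRP by
#' default, or standardized log-CRP when `mediator = "continuous"`), and
#' records which columns act as ordinary confounders `C` versus
#' exposure-affected mediator-outcome confounders `L`.
#'
#' @param records Participant records (see [read_cohort()]).
#' @param contrast One of `"minoritized_vs_nhw"`, `"nhb_vs_nhw"`,
#'   `"hisp_vs_nhw"`.
#' @param outcome_mode `"dementia"` or `"impairment"` (CIND counted with
#'   dementia for baseline-normal participants).
#' @param mediator `"binary"` or `"continuous"`.
#' @param threshold_mode,threshold Passed to [dichotomize_mediator()] for the
#'   binary mediator.
#' @param adjust Adjustment set name (see [adjustment_set()]) or a character
#'   vector of covariate column names.
#' @param lset `NULL` (default: all covariates are ordinary confounders), or
#'   a character subset of `c("apoe4", "education")` to treat as
#'   exposure-affected confounders `L` (removed from `C`).
#' @return A data frame of class `"analytic_dataset"` with columns `A`, `M`,
#'   `Y`, `t` and the covariates, plus attributes `contrast`, `covariates`,
#'   `lvars`, `mediator_kind`, `outcome_mode`, `threshold` and an exclusion
#'   tally `exclusions`.
#' @export
build_analytic_sample <- function(records, contrast = CONTRASTS,
                                  outcome_mode = c("dementia", "impairment"),
                                  mediator = c("binary", "continuous"),
                                  threshold_mode = c("fixed_threshold", "percentile"),
                                  threshold = if (match.arg(threshold_mode) == "percentile") 0.75 else 4.73,
                                  adjust = "chronic", lset = NULL) {
  contrast <- match.arg(contrast)
  outcome_mode <- match.arg(outcome_mode)
  mediator <- match.arg(mediator)
  threshold_mode <- match.arg(threshold_mode)
  validate_records(records)
  covs <- if (length(adjust) == 1L && adjust %in%
                c("chronic", "risk_factors", "demographic", "unadjusted")) {
    adjustment_set(adjust)
  } else {
    as.character(adjust)
  }
  if (!is.null(lset)) {
    lset <- match.arg(lset, c("apoe4", "education"), several.ok = TRUE)
    covs <- setdiff(covs, lset)
  } else {
    lset <- character(0)
  }

  keep_groups <- switch(contrast,
    minoritized_vs_nhw = GROUPS,
    nhb_vs_nhw = c("nh_white", "nh_black"),
    hisp_vs_nhw = c("nh_white", "hispanic")
  )
  excl <- c(off_contrast = 0L, baseline_dementia = 0L, no_followup = 0L,
            incomplete = 0L)
  in_contrast <- !is.na(records$group) & records$group %in% keep_groups
  excl["off_contrast"] <- sum(!in_contrast)
  rec <- records[in_contrast, , drop = FALSE]

  scores <- as.matrix(rec[COG_COLS])
  status <- matrix(classify_cognitive_status(as.vector(scores)), ncol = 4L)
  out <- derive_incident_outcome_all(status, outcome_mode)
  excl["baseline_dementia"] <- sum(out$exclude == "baseline_dementia", na.rm = TRUE)
  excl["no_followup"] <- sum(out$exclude == "no_followup", na.rm = TRUE)
  ok <- is.na(out$exclude)
  rec <- rec[ok, , drop = FALSE]
  Y <- out$Y[ok]
  t <- out$t[ok]

  used <- unique(c("group", covs, lset, "crp"))
  complete <- stats::complete.cases(rec[used])
  excl["incomplete"] <- sum(!complete)
  rec <- rec[complete, , drop = FALSE]
  Y <- Y[complete]
  t <- t[complete]
  if (!nrow(rec) || !any(rec$group != "nh_white") || !any(rec$group == "nh_white")) {
    stop("degenerate contrast: an exposure arm is empty", call. = FALSE)
  }

  A <- as.integer(rec$group != "nh_white")
  if (mediator == "binary") {
    M <- dichotomize_mediator(rec$crp, mode = threshold_mode, value = threshold)
    thr <- attr(M, "threshold")
    M <- as.integer(M)
  } else {
    lc <- log(pmax(rec$crp, .Machine$double.eps))
    M <- as.numeric(scale(lc))
    thr <- NA_real_
  }

  dat <- data.frame(A = A, M = M, Y = Y, t = t,
                    rec[unique(c("group", covs, lset))],
                    row.names = NULL, check.names = FALSE)
  for (fc in intersect(c("sex", "education", "smoking"), names(dat))) {
    lv <- switch(fc, sex = SEX_LEVELS, education = EDU_LEVELS,
                 smoking = SMOKE_LEVELS)
    dat[[fc]] <- factor(dat[[fc]], levels = lv)
  }
  if ("wave" %in% names(dat)) dat$wave <- factor(dat$wave)
  structure(dat,
            class = c("analytic_dataset", "data.frame"),
            contrast = contrast, covariates = covs, lvars = lset,
            mediator_kind = mediator, outcome_mode = outcome_mode,
            threshold = thr, exclusions = excl)
}

#' Descriptive cohort summary
#'
#' Summarizes baseline covariates by incident status (mean/SD for continuous
#' covariates, n/percent for categorical ones) and reports 6-year cumulative
#' incidence overall and by racialized group, as a percentage
#' `100 * sum(Y) / n`.
#'
#' @param data An `analytic_dataset` (or any data frame with `Y` and `group`
#'   columns plus covariates).
#' @return A list of class `"cohort_summary"` with elements `n`, `events`,
#'   `cumulative_incidence` (percent), `by_group` (data frame with `n`,
#'   `events`, `incidence_pct`), and `covariates` (tidy descriptive table).
#' @export
summarize_cohort <- function(data) {
  if (!nrow(data)) stop("empty dataset", call. = FALSE)
  n <- nrow(data)
  events <- sum(data$Y)
  by_group <- NULL
  if ("group" %in% names(data)) {
    sp <- split(data$Y, data$group)
    by_group <- data.frame(
      group = names(sp),
      n = vapply(sp, length, 0L),
      events = vapply(sp, sum, 0L),
      row.names = NULL
    )
    by_group$incidence_pct <- 100 * by_group$events / by_group$n
  }
  skip <- c("A", "M", "Y", "t", "group")
  covs <- setdiff(names(data), skip)
  rows <- list()
  for (v in covs) {
    x <- data[[v]]
    if (is.numeric(x)) {
      for (lab in c("incident", "no_event", "overall")) {
        xi <- switch(lab, incident = x[data$Y == 1],
                     no_event = x[data$Y == 0], overall = x)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = NA_character_, stratum = lab,
          n = length(xi), mean = mean(xi), sd = stats::sd(xi), pct = NA_real_)
      }
    } else {
      for (lev in levels(factor(x))) {
        for (lab in c("incident", "no_event", "overall")) {
          xi <- switch(lab, incident = x[data$Y == 1],
                       no_event = x[data$Y == 0], overall = x)
          rows[[length(rows) + 1L]] <- data.frame(
            variable = v, level = lev, stratum = lab,
            n = sum(xi == lev), mean = NA_real_, sd = NA_real_,
            pct = 100 * mean(xi == lev))
        }
      }
    }
  }
  structure(list(
    n = n, events = events,
    cumulative_incidence = 100 * events / n,
    by_group = by_group,
    covariates = if (length(rows)) do.call(rbind, rows) else NULL
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: n = %d, incident events = %d (%.1f%% cumulative incidence)\n",
              x$n, x$events, x$cumulative_incidence))
  if (!is.null(x$by_group)) {
    cat("By racialized group:\n")
    bg <- x$by_group
    bg$incidence_pct <- round(bg$incidence_pct, 1)
    print(bg, row.names = FALSE)
  }
  invisible(x)
}
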