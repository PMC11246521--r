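# End-to-end orchestration: simulate (or read) a cohort, build analytic
# samples, fit the incidence and mediator model suites, run the
# decompositions and sensitivity analyses, and write a reproducible report
# bundle. All randomness flows from a single configured seed via derived
# per-stage substreams, so stages are independently reproducible and the
# whole bundle is byte-identical across reruns.

#' Default pipeline configuration
#'
#' @param n Synthetic cohort size (ignored when `input_csv` is supplied).
#' @param input_csv Optional path to a person-level cohort CSV; when `NULL`
#'   a synthetic cohort is generated from [sim_config()].
#' @param contrasts Contrasts to decompose.
#' @param estimators Estimators to run per contrast (`"regression"`,
#'   `"analog"`).
#' @param B Bootstrap resamples per decomposition.
#' @param seed Master seed.
#' @param mediator,outcome_mode,adjust,threshold,threshold_mode See
#'   [build_analytic_sample()].
#' @param sim Optional list of [sim_config()] overrides.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n = 6908, input_csv = NULL,
                            contrasts = CONTRASTS,
                            estimators = c("regression", "analog"),
                            B = 1000L, seed = 1L,
                            mediator = "binary", outcome_mode = "dementia",
                            adjust = "chronic", threshold = 4.73,
                            threshold_mode = "fixed_threshold",
                            sim = list()) {
  structure(list(n = n, input_csv = input_csv, contrasts = contrasts,
                 estimators = estimators, B = B, seed = seed,
                 mediator = mediator, outcome_mode = outcome_mode,
                 adjust = adjust, threshold = threshold,
                 threshold_mode = threshold_mode, sim = sim),
            class = "pipeline_config")
}

# Derived substream seeds (kept below 2^31).
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * k) %% 2147483647L)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> build -> descriptive table -> incidence-rate
#' and odds-ratio suites -> four-way decompositions (with bootstrap and
#' mediational E-values) -> internal-consistency verification, and writes a
#' report bundle to `out_dir`: `table1.csv` (+ `counts.json` sidecar with
#' exclusion tallies), `table2_irr.csv`, `table2_or.csv`,
#' `table3_<contrast>_<estimator>.csv` / `.json`, `sensitivity.json` and
#' `run_log.txt`. Deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file with the
#'   same fields, or a plain list).
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) a list with the in-memory results and the file paths
#'   written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("fwrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) {
    known <- names(formals(pipeline_config))
    bad <- setdiff(names(config), known)
    if (length(bad)) stop("unknown pipeline config field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    config <- do.call(pipeline_config, config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("fwdecomp pipeline, package version %s",
                         as.character(utils::packageVersion("fwdecomp"))),
                 sprintf("seed = %d, B = %d", config$seed, config$B))

  if (!is.null(config$input_csv)) {
    records <- read_cohort(config$input_csv)
    log_lines <- c(log_lines, sprintf("input: %s (%d records)",
                                      basename(config$input_csv), nrow(records)))
  } else {
    cfg <- do.call(sim_config, c(list(n = config$n), config$sim))
    records <- generate_cohort(cfg, seed = substream(config$seed, 1L))$records
    log_lines <- c(log_lines, sprintf("input: synthetic cohort, n = %d", config$n))
  }

  build_args <- list(outcome_mode = config$outcome_mode,
                     mediator = config$mediator,
                     threshold_mode = config$threshold_mode,
                     threshold = config$threshold, adjust = config$adjust)
  dat_all <- do.call(build_analytic_sample,
                     c(list(records, contrast = "minoritized_vs_nhw"),
                       build_args))
  summ <- summarize_cohort(dat_all)
  utils::write.csv(summ$covariates, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  excl <- attr(dat_all, "exclusions")
  jsonlite::write_json(
    list(n = summ$n, events = summ$events,
         cumulative_incidence_pct = summ$cumulative_incidence,
         by_group = summ$by_group, exclusions = as.list(excl)),
    file.path(out_dir, "counts.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("analytic n = %d, events = %d, exclusions: %s",
                         summ$n, summ$events,
                         paste(names(excl), excl, sep = "=", collapse = ", ")))

  irr <- sequential_irr_suite(dat_all)
  utils::write.csv(irr, file.path(out_dir, "table2_irr.csv"), row.names = FALSE)
  ors <- mediator_or_suite(dat_all)
  utils::write.csv(ors, file.path(out_dir, "table2_or.csv"), row.names = FALSE)

  results <- list()
  sens <- list()
  k <- 10L
  for (ctr in config$contrasts) {
    for (est in config$estimators) {
      k <- k + 1L
      fit <- fwdecomp(records, contrast = ctr, estimator = est,
                      outcome_mode = config$outcome_mode,
                      mediator = config$mediator,
                      threshold_mode = config$threshold_mode,
                      threshold = config$threshold, adjust = config$adjust,
                      B = config$B, seed = substream(config$seed, k))
      key <- paste(ctr, est, sep = "_")
      results[[key]] <- fit
      tab <- fwdecomp_table(fit)
      stem <- file.path(out_dir, paste0("table3_", key))
      utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
      jsonlite::write_json(
        list(contrast = ctr, estimator = fit$estimator, n = fit$n,
             B = fit$B, n_failed_resamples = fit$n_failed,
             table = tab,
             sensitivity = list(nie_rr = fit$sensitivity$nie_rr,
                                evalue_point = fit$sensitivity$evalue_point,
                                evalue_ci = fit$sensitivity$evalue_ci)),
        paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      vr <- verify_internal_consistency(fit)
      if (!vr$pass) stop("internal consistency check failed for ", key,
                         call. = FALSE)
      sens[[key]] <- list(nie_rr = fit$sensitivity$nie_rr,
                          evalue_point = fit$sensitivity$evalue_point,
                          evalue_ci = fit$sensitivity$evalue_ci)
      log_lines <- c(log_lines,
                     sprintf("%s: te_excess = %.4f, pm = %.4f, pai = %.4f, failed resamples = %d, consistency = pass",
                             key, fit$te_excess, fit$pm, fit$pai, fit$n_failed))
    }
  }
  jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(results = results, out_dir = out_dir,
                 files = list.files(out_dir, full.names = TRUE)))
}

#' Verify the arithmetic identities of a decomposition report
#'
#' Checks, on the emitted (or fitted) numbers, that the four percent
#' attributable shares sum to one, that percent mediated equals the mediated
#' interaction share plus the pure indirect share, percent due to
#' interaction equals the two interaction shares, percent eliminated equals
#' everything but the controlled direct share, and that the four excess
#' components sum to the total excess relative risk.
#'
#' @param x A fitted `"fwdecomp"` object, a report data frame with columns
#'   `quantity` and `estimate`, or the path to a `table3_*.csv` file.
#' @param tol Tolerance. Defaults to `1e-8` for a fitted object (the
#'   identities are algebraic) and `0.02` for tabulated numbers, which may
#'   have been rounded to two decimals.
#' @return List with `pass` (logical) and `checks` (data frame of identity,
#'   discrepancy, pass).
#' @export
verify_internal_consistency <- function(x, tol = NULL) {
  if (is.character(x)) x <- utils::read.csv(x)
  if (inherits(x, "fwdecomp")) {
    est <- coef(x)
    if (is.null(tol)) tol <- 1e-8
  } else {
    est <- stats::setNames(x$estimate, x$quantity)
    if (is.null(tol)) tol <- 0.02
  }
  need <- c("p_cde", "p_intref", "p_intmed", "p_pie", "pm", "pai", "pe")
  miss <- setdiff(need, names(est))
  if (length(miss)) stop("report is missing quantities: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  checks <- data.frame(
    identity = c("p_cde + p_intref + p_intmed + p_pie = 1",
                 "pm = p_intmed + p_pie",
                 "pai = p_intref + p_intmed",
                 "pe = p_intref + p_intmed + p_pie"),
    discrepancy = c(
      est[["p_cde"]] + est[["p_intref"]] + est[["p_intmed"]] + est[["p_pie"]] - 1,
      est[["pm"]] - est[["p_intmed"]] - est[["p_pie"]],
      est[["pai"]] - est[["p_intref"]] - est[["p_intmed"]],
      est[["pe"]] - est[["p_intref"]] - est[["p_intmed"]] - est[["p_pie"]])
  )
  if (all(c(FW_QUANTITIES[1:5]) %in% names(est))) {
    checks <- rbind(checks, data.frame(
      identity = "exc_cde + exc_intref + exc_intmed + exc_pie = te_excess",
      discrepancy = est[["exc_cde"]] + est[["exc_intref"]] +
        est[["exc_intmed"]] + est[["exc_pie"]] - est[["te_excess"]]))
  }
  checks$pass <- abs(checks$discrepancy) <= tol
  list(pass = all(checks$pass), checks = checks)
}
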