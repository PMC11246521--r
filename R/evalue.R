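# Mediational E-values: the minimum strength of association, on the risk
# ratio scale, that an unmeasured mediator-outcome confounder would need
# with both the mediator and the outcome to explain away the observed
# indirect effect.

#' E-value for a risk ratio
#'
#' `RR + sqrt(RR * (RR - 1))` for `RR >= 1`; for protective ratios the
#' formula is applied to `1/RR`, so the function is symmetric under
#' reciprocals and equals 1 at the null.
#'
#' @param rr Positive risk ratio(s).
#' @return E-value(s), always `>= 1`.
#' @examples
#' evalue_rr(c(1, 2, 0.5))
#' @export
evalue_rr <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("risk ratio must be positive", call. = FALSE)
  }
  r <- pmax(rr, 1 / rr)
  r + sqrt(r * (r - 1))
}

#' Mediational E-value for the natural indirect effect
#'
#' Computes the total natural indirect effect risk ratio
#' `E[Y(1, M_1)] / E[Y(1, M_0)]` from standardized counterfactual means and
#' converts it (and the confidence limit closer to the null) into E-values:
#' the point E-value is the confounder strength needed to explain the
#' indirect effect away entirely; the CI E-value is the strength needed to
#' shift the interval to include the null (1 when the interval already
#' crosses it). A pure-indirect-effect variant
#' (`E[Y(0, M_1)] / E[Y(0, M_0)]`) is available via `target`.
#'
#' @param means A `"counterfactual_means"` object (or a single numeric risk
#'   ratio).
#' @param ci Optional length-2 confidence interval for the indirect-effect
#'   risk ratio.
#' @param target `"indirect_effect"` (total natural indirect effect,
#'   default) or `"pure_indirect"`.
#' @return List of class `"evalue_result"`: `nie_rr`, `evalue_point`,
#'   `evalue_ci` (`NA` without a CI), `target`.
#' @export
mediational_evalue <- function(means, ci = NULL,
                               target = c("indirect_effect", "pure_indirect")) {
  target <- match.arg(target)
  rr <- if (is.numeric(means)) {
    means[[1L]]
  } else if (target == "indirect_effect") {
    means$ey_nat["1", "1"] / means$ey_nat["1", "0"]
  } else {
    means$ey_nat["0", "1"] / means$ey_nat["0", "0"]
  }
  ev_ci <- NA_real_
  if (!is.null(ci)) {
    ci <- sort(as.numeric(ci))
    if (length(ci) != 2L || any(!is.finite(ci))) {
      stop("ci must be two finite limits", call. = FALSE)
    }
    ev_ci <- if (ci[1L] <= 1 && ci[2L] >= 1) 1 else {
      evalue_rr(ci[which.min(abs(log(ci)))])
    }
  }
  structure(list(nie_rr = rr, evalue_point = evalue_rr(rr),
                 evalue_ci = ev_ci, target = target),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, digits = 3, ...) {
  cat(sprintf("Mediational E-value (%s): RR = %.*f, E-value = %.*f",
              x$target, digits, x$nie_rr, digits, x$evalue_point))
  if (!is.na(x$evalue_ci)) cat(sprintf(", CI E-value = %.*f", digits, x$evalue_ci))
  cat("\n")
  invisible(x)
}
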