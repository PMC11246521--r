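# S3 methods for fitted decomposition objects.

TABLE3_LABELS <- c(
  exc_cde = "RERI Controlled Direct Effect",
  exc_intref = "RERI Interaction Reference",
  exc_intmed = "RERI Interaction Mediation",
  exc_pie = "RERI Pure Indirect Effect",
  te_excess = "Total Excess Relative Risk",
  p_cde = "% Controlled Direct Effect",
  p_intref = "% Interaction Reference",
  p_intmed = "% Interaction Mediation",
  p_pie = "% Pure Indirect Effect",
  pm = "Percent Mediated",
  pai = "Percent due to Interaction",
  pe = "Percent Eliminated",
  nie_rr = "Indirect Effect Risk Ratio"
)

# Full quantity table (unrounded) for a fitted object.
fwdecomp_table <- function(x) {
  est <- coef(x)
  tab <- data.frame(quantity = names(est),
                    label = unname(TABLE3_LABELS[names(est)]),
                    estimate = unname(est))
  if (!is.null(x$ci)) {
    tab$lcl <- x$ci[tab$quantity, "lcl"]
    tab$ucl <- x$ci[tab$quantity, "ucl"]
    tab$p <- x$pvals[tab$quantity]
  }
  rownames(tab) <- NULL
  tab
}

#' @export
coef.fwdecomp <- function(object, ...) {
  stats::setNames(
    c(object$components, object$te_excess, object$proportions,
      object$pm, object$pai, object$pe, object$nie_rr),
    FW_QUANTITIES)
}

#' @export
confint.fwdecomp <- function(object, parm, level, ...) {
  if (is.null(object$ci)) stop("fitted without bootstrap (B = 0)", call. = FALSE)
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @rdname fwdecomp
#' @param x,object A fitted `"fwdecomp"` object.
#' @param digits Digits for display.
#' @param ... Unused.
#' @export
print.fwdecomp <- function(x, digits = 2, ...) {
  cat(sprintf("Four-way decomposition (%s, %s mediator)\n", x$estimator,
              x$mediator_kind))
  cat(sprintf("Contrast: %s, n = %d; bootstrap B = %d (seed %d)\n",
              x$contrast, x$n, x$B, x$seed))
  tab <- fwdecomp_table(x)
  show <- tab[tab$quantity != "te_excess", ]
  num <- vapply(show, is.numeric, TRUE)
  show[num] <- lapply(show[num], round, digits)
  print(show[-1L], row.names = FALSE)
  cat(sprintf("Total excess relative risk: %.*f\n", digits, x$te_excess))
  if (isTRUE(x$unreliable)) {
    cat(sprintf("Warning: %d bootstrap resamples failed; inference unreliable\n",
                x$n_failed))
  }
  invisible(x)
}

#' @export
summary.fwdecomp <- function(object, ...) {
  structure(list(fit = object, table = fwdecomp_table(object)),
            class = "summary.fwdecomp")
}

#' @export
print.summary.fwdecomp <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  f <- x$fit
  cat("\nModel fits:\n")
  for (nm in names(f$fits)) {
    ft <- f$fits[[nm]]
    cat(sprintf("  %s: %s, converged = %s\n", nm, ft$family, ft$converged))
  }
  if (!is.null(f$sensitivity)) {
    cat("\n")
    print(f$sensitivity, digits = digits)
  }
  invisible(x)
}

#' @rdname fwdecomp
#' @export
plot.fwdecomp <- function(x, ...) {
  comp <- x$components
  labs <- c("CDE", "INTref", "INTmed", "PIE")
  has_ci <- !is.null(x$ci)
  ylim <- if (has_ci) {
    range(0, x$ci[names(comp), ], comp)
  } else range(0, comp)
  bp <- graphics::barplot(comp, names.arg = labs,
                          ylab = "Excess relative risk",
                          main = sprintf("Four-way decomposition (%s)",
                                         x$contrast),
                          ylim = ylim + c(0, 0.1 * diff(range(ylim))), ...)
  if (has_ci) {
    graphics::arrows(bp, x$ci[names(comp), "lcl"], bp,
                     x$ci[names(comp), "ucl"],
                     angle = 90, code = 3, length = 0.06)
  }
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
print.fwdecomp_points <- function(x, digits = 4, ...) {
  cat("Four-way decomposition point estimates\n")
  print(round(c(x$components, te_excess = x$te_excess), digits))
  print(round(c(x$proportions, pm = x$pm, pai = x$pai, pe = x$pe), digits))
  invisible(x)
}

#' @export
print.counterfactual_means <- function(x, digits = 4, ...) {
  cat(sprintf("Standardized counterfactual means (T = %g years)\n", x$ref_time))
  cat("E[Y(a, m)]:\n"); print(round(x$ey, digits))
  cat("E[Y(a, M_a*)]:\n"); print(round(x$ey_nat, digits))
  cat(sprintf("theta = %.*f, indirect-effect RR = %.*f\n", digits, x$theta,
              digits, x$nie_rr))
  invisible(x)
}
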