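# Interim test statistic for two-arm binary data: the unadjusted logistic
# regression of outcome on arm. For a 2x2 table the MLE has the closed Wald
# form used here; agreement with an iteratively-reweighted GLM fit is part
# of the test suite.

#' Wald logistic summary of a two-arm binary interim
#'
#' Fits the unadjusted logistic model `logit(p) = b0 + b1 * arm` to the
#' interim 2x2 table. For non-degenerate tables the MLE is the empirical
#' log-odds-ratio `b1 = log[(et/(nt-et)) / (ec/(nc-ec))]` with
#' `SE = sqrt(1/ec + 1/(nc-ec) + 1/et + 1/(nt-et))`.
#'
#' The z-statistic uses the benefit-positive convention `z = -b1 / SE`: an
#' odds ratio below 1 (fewer events on treatment) gives a positive z.
#'
#' If any single cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) to keep the statistic defined. If the outcome is
#' constant in both arms (all zero or all one), the table carries no
#' information on the odds ratio: the fit is flagged indeterminate and
#' `z = 0` with a warning.
#'
#' @param control_events,control_n Events and total in the control arm.
#' @param treat_events,treat_n Events and total in the treatment arm.
#' @param stage,t Optional stage index and information fraction, recorded in
#'   the result.
#' @return An object of class `interim_fit` with elements `control_events`,
#'   `control_n`, `treat_events`, `treat_n`, `beta1` (log-OR), `se`, `z`
#'   (benefit-positive), `or`, `indeterminate`, `stage`, `t`.
#' @export
#' @examples
#' fit_interim(100, 300, 80, 300)
fit_interim <- function(control_events, control_n, treat_events, treat_n,
                        stage = NA_integer_, t = NA_real_) {
  ec <- control_events; nc <- control_n
  et <- treat_events; nt <- treat_n
  if (any(c(ec, nc, et, nt) < 0) || ec > nc || et > nt || nc == 0 || nt == 0)
    stop("invalid counts: need 0 <= events <= n and n > 0 in both arms")
  indeterminate <- FALSE
  cells <- c(ec, nc - ec, et, nt - et)
  if ((ec == 0 && et == 0) || (ec == nc && et == nt)) {
    indeterminate <- TRUE
    warning("outcome constant in both arms; interim carries no information (z set to 0)")
    beta1 <- 0
    se <- Inf
    z <- 0
  } else {
    if (any(cells == 0)) cells <- cells + 0.5
    beta1 <- log(cells[3] / cells[4]) - log(cells[1] / cells[2])
    se <- sqrt(sum(1 / cells))
    z <- -beta1 / se
  }
  structure(
    list(control_events = ec, control_n = nc, treat_events = et, treat_n = nt,
         beta1 = beta1, se = se, z = z, or = exp(beta1),
         indeterminate = indeterminate, stage = stage, t = t),
    class = "interim_fit"
  )
}

#' @export
print.interim_fit <- function(x, ...) {
  cat(sprintf("Interim 2x2 fit%s: control %d/%d, treatment %d/%d\n",
              if (!is.na(x$stage)) sprintf(" (stage %d, t = %.3g)", x$stage, x$t) else "",
              x$control_events, x$control_n, x$treat_events, x$treat_n))
  cat(sprintf("  OR %.4f (log-OR %.4f, SE %.4f), benefit-positive z %.4f%s\n",
              x$or, x$beta1, x$se, x$z,
              if (x$indeterminate) " [indeterminate]" else ""))
  invisible(x)
}

#' Group-sequential decision for one interim or final summary
#'
#' Compares the benefit-positive z-statistic of an [fit_interim()] summary
#' with the stage's critical values. At an interim: `|z| >= u_k` stops for
#' efficacy (checked first); otherwise `z <= l_k` (when futility bounds are
#' present) stops for futility; otherwise the trial continues. At the final
#' analysis `|z| >= u_m` rejects and anything else accepts.
#'
#' @param fit An `interim_fit` (or any list with element `z`).
#' @param bounds A `boundary_set`.
#' @param stage Stage index, 1-based; the final analysis is
#'   `length(bounds$t)`.
#' @return One of `"stop_efficacy"`, `"stop_futility"`, `"continue"`,
#'   `"final_reject"`, `"final_accept"`.
#' @export
gs_decision <- function(fit, bounds, stage = fit$stage) {
  stopifnot(inherits(bounds, "boundary_set"))
  m <- length(bounds$t)
  if (is.na(stage) || stage < 1 || stage > m)
    stop("`stage` must index a stage of the boundary set")
  z <- fit$z
  if (stage == m) {
    return(if (abs(z) >= bounds$u[m]) "final_reject" else "final_accept")
  }
  if (abs(z) >= bounds$u[stage]) return("stop_efficacy")
  if (!is.null(bounds$l) && z <= bounds$l[stage]) return("stop_futility")
  "continue"
}
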