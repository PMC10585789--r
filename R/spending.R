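#' Specify an error-spending design family
#'
#' Defines how the overall type I error `alpha` (two-sided) and type II error
#' `beta` are allocated across interim looks as a function of the information
#' fraction. Supported families:
#' \describe{
#'   \item{OBF}{O'Brien-Fleming-type spending,
#'     `a(t) = 2 - 2 * Phi(qnorm(1 - a/2) / sqrt(t))`, `a(0) = 0`.}
#'   \item{HSD}{Hwang-Shih-DeCani,
#'     `a(t) = a * (1 - exp(-gamma * t)) / (1 - exp(-gamma))`, reducing to
#'     `a * t` when `gamma = 0`. Negative `gamma` spends conservatively
#'     early; the default `gamma = -4` places the boundaries between
#'     Haybittle-Peto and O'Brien-Fleming in early-look conservatism.}
#'   \item{HP}{Haybittle-Peto. Not a spending family: interim critical values
#'     are fixed at 3 with 1.96 at the final look; [spend()] errors for HP
#'     and there is no futility monitoring.}
#' }
#' The beta-spending function uses the same functional form with `alpha`
#' replaced by `beta` (and, for HSD, the same `gamma`).
#'
#' @param family `"OBF"`, `"HSD"` or `"HP"`.
#' @param alpha Overall two-sided significance level.
#' @param beta Overall type II error (1 - power).
#' @param gamma HSD shape parameter.
#' @param futility Logical: monitor futility via beta-spending (always
#'   `FALSE` for HP).
#' @return An object of class `spending_spec`.
#' @export
#' @examples
#' spending_spec("HSD", gamma = -4)
spending_spec <- function(family = c("OBF", "HSD", "HP"), alpha = 0.05,
                          beta = 0.10, gamma = -4,
                          futility = family[1] != "HP") {
  family <- match.arg(family)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (!is.numeric(beta) || beta <= 0 || beta >= 1) stop("`beta` must lie in (0, 1)")
  if (family == "HP" && isTRUE(futility))
    stop("the Haybittle-Peto design has no futility boundaries")
  structure(
    list(family = family, alpha = alpha, beta = beta,
         gamma = if (family == "HSD") gamma else NA_real_,
         futility = isTRUE(futility) && family != "HP"),
    class = "spending_spec"
  )
}

#' @export
print.spending_spec <- function(x, ...) {
  cat(sprintf("Spending spec: %s, two-sided alpha %.4g, beta %.4g%s%s\n",
              x$family, x$alpha, x$beta,
              if (x$family == "HSD") sprintf(", gamma %.4g", x$gamma) else "",
              if (x$futility) ", binding futility" else ", efficacy only"))
  invisible(x)
}

#' Cumulative error spent at an information fraction
#'
#' @param spec A [spending_spec()] with family OBF or HSD.
#' @param t Information fraction(s) in `[0, 1]` (vectorised).
#' @param which Spend type I error (`"alpha"`) or type II error (`"beta"`).
#' @return Cumulative probability spent by `t`; 0 at `t = 0` and the full
#'   level at `t = 1`.
#' @export
#' @examples
#' spend(spending_spec("OBF"), 0.5)         # ~0.00558
#' spend(spending_spec("HSD", gamma = 0), 0.4) # 0.02
spend <- function(spec, t, which = c("alpha", "beta")) {
  stopifnot(inherits(spec, "spending_spec"))
  which <- match.arg(which)
  if (spec$family == "HP")
    stop("Haybittle-Peto has no spending function; its boundaries are fixed constants")
  if (any(t < 0 | t > 1)) stop("information fraction `t` must lie in [0, 1]")
  level <- if (which == "alpha") spec$alpha else spec$beta
  if (spec$family == "OBF") {
    out <- ifelse(t == 0, 0, 2 - 2 * pnorm(qnorm(1 - level / 2) / sqrt(pmax(t, 1e-300))))
  } else {
    g <- spec$gamma
    out <- if (g == 0) level * t else level * (1 - exp(-g * t)) / (1 - exp(-g))
  }
  pmin(pmax(out, 0), level)
}
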