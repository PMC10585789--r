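#' Define a two-arm binary-endpoint trial scenario
#'
#' A scenario is the data-generating truth for the simulation engine: per-arm
#' event probabilities, the maximum sample size, and the number of equally
#' spaced interim analyses. Allocation is always exact 1:1.
#'
#' @param name Text label for the scenario.
#' @param n_max Maximum (final-analysis) sample size across both arms.
#' @param p_control Event probability in the control arm, in (0, 1).
#' @param p_treatment Event probability in the experimental arm, in (0, 1).
#' @param n_interims Number of equally spaced interim analyses `K >= 0`;
#'   interim `k` occurs at information fraction `k / (K + 1)`.
#' @param hypothesis Optional tag, `"null"` or `"alternative"`, recording
#'   which hypothesis the scenario encodes (used by [compute_oc()] defaults).
#'
#' @return An object of class `trial_scenario`.
#' @seealso [make_preset()] for the ADRENAL / NICE-SUGAR presets.
#' @export
#' @examples
#' trial_scenario("example", 1000, 0.33, 0.28, n_interims = 2)
trial_scenario <- function(name, n_max, p_control, p_treatment, n_interims = 0,
                           hypothesis = NA_character_) {
  stopifnot(is.character(name), length(name) == 1)
  n_max <- as.integer(n_max)
  n_interims <- as.integer(n_interims)
  if (is.na(n_max) || n_max < 2) stop("`n_max` must be an integer >= 2")
  if (n_max %% 2 != 0) stop("`n_max` must be even for exact 1:1 allocation")
  # degenerate rates 0 and 1 are admitted for testing the generator; real
  # designs use interior probabilities
  if (!is.numeric(p_control) || p_control < 0 || p_control > 1)
    stop("`p_control` must lie in [0, 1]")
  if (!is.numeric(p_treatment) || p_treatment < 0 || p_treatment > 1)
    stop("`p_treatment` must lie in [0, 1]")
  if (is.na(n_interims) || n_interims < 0) stop("`n_interims` must be >= 0")
  if (!is.na(hypothesis)) hypothesis <- match.arg(hypothesis, c("null", "alternative"))
  structure(
    list(name = name, n_max = n_max, p_control = p_control,
         p_treatment = p_treatment, allocation_ratio = 1,
         n_interims = n_interims, hypothesis = hypothesis),
    class = "trial_scenario"
  )
}

#' Preset scenarios replicating the ADRENAL and NICE-SUGAR design assumptions
#'
#' ADRENAL: 3658 patients with 90-day mortality 33% in both arms under the
#' null, and an absolute reduction of 5% (33% vs 28%, odds ratio 0.79) under
#' the alternative. NICE-SUGAR: 6022 patients, 30% vs 30% under the null and
#' 30% vs 26.2% (odds ratio 0.83) under the alternative.
#'
#' @param name `"ADRENAL"` or `"NICE-SUGAR"`.
#' @param hypothesis `"null"` or `"alternative"`.
#' @param n_interims Number of equally spaced interim analyses.
#' @return A [trial_scenario()] object.
#' @export
#' @examples
#' make_preset("ADRENAL", "alternative", n_interims = 4)
make_preset <- function(name = c("ADRENAL", "NICE-SUGAR"),
                        hypothesis = c("null", "alternative"),
                        n_interims = 2) {
  name <- match.arg(name)
  hypothesis <- match.arg(hypothesis)
  p <- switch(name,
    "ADRENAL"    = c(n = 3658, pc = 0.33, pt = if (hypothesis == "null") 0.33 else 0.28),
    "NICE-SUGAR" = c(n = 6022, pc = 0.30, pt = if (hypothesis == "null") 0.30 else 0.262)
  )
  trial_scenario(paste0(name, " (", hypothesis, ")"),
                 n_max = p[["n"]], p_control = p[["pc"]], p_treatment = p[["pt"]],
                 n_interims = n_interims, hypothesis = hypothesis)
}

#' Equally spaced interim information fractions
#'
#' @param n_interims Number of interim analyses `K >= 0`.
#' @return Numeric vector `k / (K + 1)`, `k = 1..K` (length 0 when `K = 0`);
#'   the final analysis at `t = 1` is not included.
#' @export
#' @examples
#' information_schedule(4) # 0.2 0.4 0.6 0.8
information_schedule <- function(n_interims) {
  n_interims <- as.integer(n_interims)
  if (is.na(n_interims) || n_interims < 0) stop("`n_interims` must be >= 0")
  if (n_interims == 0) return(numeric(0))
  seq_len(n_interims) / (n_interims + 1)
}

#' The design odds ratio implied by a scenario's event probabilities
#'
#' @param scenario A [trial_scenario()].
#' @return `odds(p_treatment) / odds(p_control)`.
#' @export
scenario_odds_ratio <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  exp(qlogis(scenario$p_treatment) - qlogis(scenario$p_control))
}

#' The expected standardised statistic at full information (design drift)
#'
#' Expected value of the benefit-positive Wald z-statistic of the unadjusted
#' logistic fit at the final analysis, under the scenario's true rates:
#' `-log(OR) / SE` with `SE` evaluated at the expected cell counts.
#'
#' @param scenario A [trial_scenario()].
#' @return Positive drift when the treatment arm has the lower event rate.
#' @export
scenario_drift <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  n_arm <- scenario$n_max / 2
  pc <- scenario$p_control
  pt <- scenario$p_treatment
  se <- sqrt(1 / (n_arm * pc) + 1 / (n_arm * (1 - pc)) +
             1 / (n_arm * pt) + 1 / (n_arm * (1 - pt)))
  -(qlogis(pt) - qlogis(pc)) / se
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat("Two-arm trial scenario:", x$name, "\n")
  cat(sprintf("  n_max %d, control rate %.3f, treatment rate %.3f (OR %.3f)\n",
              x$n_max, x$p_control, x$p_treatment, scenario_odds_ratio(x)))
  cat(sprintf("  %d interim analyses at t = %s\n", x$n_interims,
              paste(signif(information_schedule(x$n_interims), 3), collapse = ", ")))
  invisible(x)
}

#' Generate patient-level outcomes for one simulated trial
#'
#' Patients are allocated by strict alternation (control, treatment, control,
#' ...), so arm totals differ by at most one at any enrolment cut and are
#' equal whenever the cut size is even (the final analysis always is).
#' Outcomes are independent Bernoulli draws with the arm-specific event
#' probability, available immediately; recruitment is assumed paused during
#' interim analyses.
#'
#' @param scenario A [trial_scenario()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `trial_data` object: a data frame with columns `order`, `arm`
#'   (0 = control, 1 = treatment) and `outcome` (1 = event), with the
#'   scenario attached as an attribute.
#' @export
#' @examples
#' td <- generate_trial(make_preset("ADRENAL", "null", 2), seed = 1)
#' table(td$arm)
generate_trial <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n <- scenario$n_max
  arm <- rep_len(c(0L, 1L), n)
  p <- ifelse(arm == 0L, scenario$p_control, scenario$p_treatment)
  outcome <- rbinom(n, 1L, p)
  out <- data.frame(order = seq_len(n), arm = arm, outcome = outcome)
  attr(out, "scenario") <- scenario
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Enrolment cut size at an information fraction
#'
#' @param n_max Maximum sample size.
#' @param t Information fraction in (0, 1].
#' @return `round(t * n_max)` patients.
#' @export
cut_size <- function(n_max, t) {
  if (any(t <= 0 | t > 1)) stop("information fraction `t` must lie in (0, 1]")
  as.integer(round(t * n_max))
}

#' Summarise a trial at an interim information fraction
#'
#' Takes the first `round(t * n_max)` enrolled patients and returns the
#' two-arm event/total counts together with the Wald logistic summary from
#' [fit_interim()].
#'
#' @param trial A `trial_data` object from [generate_trial()].
#' @param t Information fraction in (0, 1].
#' @param stage Optional stage index recorded in the summary.
#' @return An `interim_fit` object (see [fit_interim()]).
#' @export
cut_at_information <- function(trial, t, stage = NA_integer_) {
  stopifnot(inherits(trial, "trial_data"))
  if (length(t) != 1 || t <= 0 || t > 1) stop("information fraction `t` must lie in (0, 1]")
  n_cut <- cut_size(nrow(trial), t)
  head_rows <- trial[seq_len(n_cut), ]
  ec <- sum(head_rows$outcome[head_rows$arm == 0L])
  nc <- sum(head_rows$arm == 0L)
  et <- sum(head_rows$outcome[head_rows$arm == 1L])
  nt <- sum(head_rows$arm == 1L)
  fit_interim(ec, nc, et, nt, stage = stage, t = t)
}
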