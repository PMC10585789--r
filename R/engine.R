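#' Construct an interim monitoring rule
#'
#' Binds one of the five monitoring strategies to an interim schedule:
#' \itemize{
#'   \item `"HP"`: Haybittle-Peto fixed boundaries ([hp_boundaries()]).
#'   \item `"OBF"`, `"HSD"`: error-spending boundaries with binding futility
#'     solved by [solve_boundaries()].
#'   \item `"PostP"`, `"PredP"`: Bayesian posterior- / predictive-probability
#'     rules with a [bayes_prior()] and [bayes_thresholds()].
#' }
#'
#' @param kind Strategy name.
#' @param n_interims Number of equally spaced interim analyses.
#' @param alpha,beta,gamma Error rates and HSD shape for the frequentist
#'   designs.
#' @param futility Monitor futility (OBF/HSD only; HP never does).
#' @param boundaries Optional pre-solved `boundary_set` (overrides solving).
#' @param prior,thresholds Bayesian rule components.
#' @param n_draws Monte-Carlo draws per predictive-probability evaluation.
#' @param grid_size Quadrature nodes for Bayesian posterior tails.
#' @return An object of class `decision_rule`.
#' @export
#' @examples
#' decision_rule("HP", n_interims = 2)
decision_rule <- function(kind = c("HP", "OBF", "HSD", "PostP", "PredP"),
                          n_interims, alpha = 0.05, beta = 0.10, gamma = -4,
                          futility = TRUE, boundaries = NULL,
                          prior = bayes_prior(),
                          thresholds = bayes_thresholds(), n_draws = 500,
                          grid_size = 257) {
  kind <- match.arg(kind)
  n_interims <- as.integer(n_interims)
  if (is.na(n_interims) || n_interims < 0) stop("`n_interims` must be >= 0")
  if (kind %in% c("HP", "OBF", "HSD")) {
    if (is.null(boundaries)) {
      boundaries <- if (kind == "HP") {
        hp_boundaries(n_interims, alpha = alpha)
      } else {
        solve_boundaries(
          spending_spec(kind, alpha = alpha, beta = beta, gamma = gamma,
                        futility = futility),
          information_schedule(n_interims)
        )
      }
    }
    if (length(boundaries$t) != n_interims + 1)
      stop("`boundaries` stage count does not match `n_interims`")
    rule <- list(kind = kind, n_interims = n_interims, boundaries = boundaries,
                 prior = NULL, thresholds = NULL, n_draws = NA_integer_,
                 grid_size = grid_size)
  } else {
    stopifnot(inherits(prior, "bayes_prior"), inherits(thresholds, "bayes_thresholds"))
    rule <- list(kind = kind, n_interims = n_interims, boundaries = NULL,
                 prior = prior, thresholds = thresholds,
                 n_draws = as.integer(n_draws), grid_size = grid_size)
  }
  structure(rule, class = "decision_rule")
}

#' @export
print.decision_rule <- function(x, ...) {
  cat(sprintf("Decision rule: %s with %d interim(s)\n", x$kind, x$n_interims))
  if (!is.null(x$boundaries)) print(x$boundaries)
  if (x$kind == "PostP")
    cat(sprintf("  efficacy > %.3g; futility: Pr(OR < %.3g) and Pr(OR > %.3g) both < %.3g\n",
                x$thresholds$efficacy, x$thresholds$futility_margin,
                1 / x$thresholds$futility_margin, x$thresholds$futility_prob))
  if (x$kind == "PredP")
    cat(sprintf("  stop-high %.3g / stop-low %.3g on PredP of final success (posterior > %.3g); %d draws\n",
                x$thresholds$predp_high, x$thresholds$predp_low,
                x$thresholds$efficacy, x$n_draws))
  invisible(x)
}

.rule_schedule <- function(rule) c(information_schedule(rule$n_interims), 1)

# decision for one stage from raw counts, shared by run_trial() and replay()
.stage_decision <- function(rule, ec, nc, et, nt, stage, is_final,
                            nc_final = NULL, nt_final = NULL) {
  if (rule$kind %in% c("HP", "OBF", "HSD")) {
    fit <- fit_interim(ec, nc, et, nt, stage = stage)
    decision <- gs_decision(fit, rule$boundaries, stage)
    return(list(decision = decision, fit = fit, detail = fit))
  }
  if (rule$kind == "PostP") {
    post <- posterior_summary(ec, nc, et, nt, prior = rule$prior,
                              margin = rule$thresholds$futility_margin,
                              grid_size = max(rule$grid_size, 257))
    decision <- postp_decision(post, rule$thresholds, is_final = is_final)
    return(list(decision = decision, fit = fit_interim(ec, nc, et, nt, stage = stage),
                detail = post))
  }
  # PredP
  pp <- predictive_probability(ec, nc, et, nt,
                               control_remaining = nc_final - nc,
                               treat_remaining = nt_final - nt,
                               prior = rule$prior,
                               success_threshold = rule$thresholds$efficacy,
                               n_draws = rule$n_draws,
                               grid_size = rule$grid_size)
  decision <- if (is_final) {
    if (pp >= 1) "final_reject" else "final_accept"
  } else {
    predp_decision(pp, rule$thresholds)
  }
  list(decision = decision, fit = fit_interim(ec, nc, et, nt, stage = stage),
       detail = pp)
}

new_trial_result <- function(stage, reason, n_stop, or, z, history, rule_kind) {
  structure(
    list(stage = stage, reason = reason, n_stop = n_stop, or = or, z = z,
         history = history, rule_kind = rule_kind),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial result (%s): %s at stage %d, n = %d\n",
              x$rule_kind, x$reason, x$stage, x$n_stop))
  cat(sprintf("  estimated OR at stop %.4f (benefit-positive z %.3f)\n", x$or, x$z))
  invisible(x)
}

#' Run one simulated trial through its interim schedule
#'
#' Evaluates the monitoring rule at each equally spaced interim and at the
#' final analysis, stopping at the first boundary or threshold crossing
#' (boundaries are binding). The treatment-effect estimate recorded at the
#' stop is the unadjusted odds ratio from the data available at the stopping
#' cut, with no bias correction.
#'
#' @param trial A `trial_data` object from [generate_trial()].
#' @param rule A [decision_rule()] whose `n_interims` matches the trial's
#'   scenario.
#' @return A `trial_result` with the stopping stage, reason
#'   (`stop_efficacy` / `stop_futility` / `final_reject` / `final_accept`,
#'   the first two reported as `efficacy` / `futility`), sample size at
#'   stop, estimated OR, and the per-stage history.
#' @export
run_trial <- function(trial, rule) {
  stopifnot(inherits(trial, "trial_data"), inherits(rule, "decision_rule"))
  scenario <- attr(trial, "scenario")
  if (scenario$n_interims != rule$n_interims)
    stop("rule has ", rule$n_interims, " interims but the trial's scenario has ",
         scenario$n_interims)
  t_all <- .rule_schedule(rule)
  m <- length(t_all)
  n_final <- scenario$n_max
  nc_final <- ceiling(n_final / 2)
  nt_final <- floor(n_final / 2)
  history <- vector("list", m)
  for (k in seq_len(m)) {
    fit <- cut_at_information(trial, t_all[k], stage = k)
    st <- .stage_decision(rule, fit$control_events, fit$control_n,
                          fit$treat_events, fit$treat_n, stage = k,
                          is_final = (k == m),
                          nc_final = nc_final, nt_final = nt_final)
    history[[k]] <- st$detail
    dec <- st$decision
    if (dec != "continue") {
      reason <- switch(dec, stop_efficacy = "efficacy",
                       stop_futility = "futility", dec)
      return(new_trial_result(k, reason, fit$control_n + fit$treat_n,
                              fit$or, fit$z, history[seq_len(k)], rule$kind))
    }
  }
  stop("internal error: final stage did not return a decision") # nocov
}

#' Replay externally supplied per-stage summaries against a monitoring rule
#'
#' Applies the same decision logic as [run_trial()] to a user-supplied table
#' of per-stage two-arm counts, enabling retrospective re-analysis of any
#' trial from its interim summary tables.
#'
#' @param stage_table A data frame, or path to a CSV file, with columns
#'   `stage`, `t`, `control_events`, `control_n`, `treat_events`, `treat_n`,
#'   one row per analysis in increasing `t`, the last row being the final
#'   analysis (`t = 1`). The row count must equal the rule's
#'   `n_interims + 1`.
#' @param rule A [decision_rule()].
#' @return A `trial_result`.
#' @export
replay <- function(stage_table, rule) {
  stopifnot(inherits(rule, "decision_rule"))
  if (is.character(stage_table)) stage_table <- read.csv(stage_table)
  need <- c("stage", "t", "control_events", "control_n", "treat_events", "treat_n")
  missing_cols <- setdiff(need, names(stage_table))
  if (length(missing_cols) > 0)
    stop("stage table is missing column(s): ", paste(missing_cols, collapse = ", "))
  tab <- stage_table[order(stage_table$t), need]
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    bad <- any(is.na(row)) || any(row[-(1:2)] < 0) ||
      row$control_events > row$control_n || row$treat_events > row$treat_n ||
      row$t <= 0 || row$t > 1
    if (bad) stop("malformed stage table at row ", i, ": ",
                  paste(sprintf("%s=%s", need, unlist(row)), collapse = ", "))
  }
  if (any(diff(tab$t) <= 0)) stop("stage table `t` must be strictly increasing")
  m <- rule$n_interims + 1
  if (nrow(tab) != m)
    stop("stage table has ", nrow(tab), " rows but the rule expects ", m)
  nc_final <- tab$control_n[m]
  nt_final <- tab$treat_n[m]
  history <- vector("list", m)
  for (k in seq_len(m)) {
    st <- .stage_decision(rule, tab$control_events[k], tab$control_n[k],
                          tab$treat_events[k], tab$treat_n[k], stage = k,
                          is_final = (k == m),
                          nc_final = nc_final, nt_final = nt_final)
    history[[k]] <- st$detail
    dec <- st$decision
    if (dec != "continue") {
      reason <- switch(dec, stop_efficacy = "efficacy",
                       stop_futility = "futility", dec)
      fit <- st$fit
      return(new_trial_result(k, reason, tab$control_n[k] + tab$treat_n[k],
                              fit$or, fit$z, history[seq_len(k)], rule$kind))
    }
  }
  stop("internal error: final stage did not return a decision") # nocov
}
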