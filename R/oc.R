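# Vectorised simulation of many trials at once: per-stage event increments
# are binomial draws per arm (the sum of the patient-level Bernoulli
# outcomes between cuts), and the decision logic is applied stage by stage
# across all still-running trials. run_trial() and this engine share the
# same stage sizes, statistics and decision functions; their agreement is
# asserted in the test suite.

.stage_layout <- function(scenario) {
  t_all <- c(information_schedule(scenario$n_interims), 1)
  n_cut <- cut_size(scenario$n_max, t_all)
  nc <- as.integer(ceiling(n_cut / 2))
  nt <- as.integer(floor(n_cut / 2))
  list(t = t_all, n_cut = n_cut, nc = nc, nt = nt,
       d_nc = diff(c(0L, nc)), d_nt = diff(c(0L, nt)))
}

# vectorised Wald logistic z and OR from cumulative 2x2 counts
.z_or_from_counts <- function(ec, nc, et, nt) {
  a <- ec; b <- nc - ec; cc <- et; d <- nt - et
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
  cc[zero] <- cc[zero] + 0.5; d[zero] <- d[zero] + 0.5
  beta1 <- log(cc / d) - log(a / b)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- -beta1 / se
  indet <- (ec == 0 & et == 0) | (ec == nc & et == nt)
  z[indet] <- 0
  beta1[indet] <- 0
  list(z = z, or = exp(beta1))
}

.cum_rows <- function(x) {
  if (nrow(x) == 1) return(x)
  apply(x, 2, cumsum)
}

#' Simulate many trials under one scenario and one monitoring rule
#'
#' Per-stage event counts are drawn directly as binomial increments per arm
#' (equivalent in distribution to patient-level Bernoulli generation with
#' the alternating 1:1 allocation), and the rule's decision logic is applied
#' at each stage with binding stopping.
#'
#' @param scenario A [trial_scenario()].
#' @param rule A [decision_rule()] with matching `n_interims`.
#' @param n_sim Number of simulated trials.
#' @param seed Optional integer seed.
#' @return A data frame of class `trial_sims` with one row per trial:
#'   `trial`, `stage`, `reason` (`efficacy`, `futility`, `final_reject`,
#'   `final_accept`), `n_stop`, `or`, `z`; the scenario and rule kind are
#'   attached as attributes.
#' @export
#' @examples
#' sims <- simulate_trials(make_preset("ADRENAL", "null", 2),
#'                         decision_rule("HP", 2), n_sim = 200, seed = 1)
#' table(sims$reason)
simulate_trials <- function(scenario, rule, n_sim, seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"), inherits(rule, "decision_rule"))
  if (scenario$n_interims != rule$n_interims)
    stop("rule has ", rule$n_interims, " interims but the scenario has ",
         scenario$n_interims)
  n_sim <- as.integer(n_sim)
  if (is.na(n_sim) || n_sim < 1) stop("`n_sim` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lay <- .stage_layout(scenario)
  m <- length(lay$t)
  Ec <- .cum_rows(matrix(rbinom(m * n_sim, rep(lay$d_nc, n_sim), scenario$p_control),
                         nrow = m))
  Et <- .cum_rows(matrix(rbinom(m * n_sim, rep(lay$d_nt, n_sim), scenario$p_treatment),
                         nrow = m))
  out <- .decide_paths(rule, Ec, Et, lay, n_sim)
  attr(out, "scenario") <- scenario
  attr(out, "rule_kind") <- rule$kind
  attr(out, "seed") <- seed
  class(out) <- c("trial_sims", "data.frame")
  out
}

.decide_paths <- function(rule, Ec, Et, lay, n_sim) {
  m <- length(lay$t)
  stage <- integer(n_sim)
  reason <- character(n_sim)
  alive <- seq_len(n_sim)
  or_stop <- z_stop <- numeric(n_sim)
  bayes <- rule$kind %in% c("PostP", "PredP")
  thr <- rule$thresholds
  for (k in seq_len(m)) {
    if (length(alive) == 0) break
    ec <- Ec[k, alive]; et <- Et[k, alive]
    nc <- lay$nc[k]; nt <- lay$nt[k]
    is_final <- k == m
    zo <- .z_or_from_counts(ec, nc, et, nt)
    if (!bayes) {
      u <- rule$boundaries$u[k]
      eff <- abs(zo$z) >= u
      fut <- if (!is_final && !is.null(rule$boundaries$l))
        !eff & zo$z <= rule$boundaries$l[k] else rep(FALSE, length(alive))
    } else if (rule$kind == "PostP") {
      cuts <- c(0, log(thr$futility_margin), -log(thr$futility_margin))
      p <- .chunked_tails(ec, nc, et, nt, rule$prior, cuts, rule$grid_size)
      eff <- pmax(p[, 1], 1 - p[, 1]) > thr$efficacy
      fut <- if (!is_final)
        !eff & p[, 2] < thr$futility_prob & (1 - p[, 3]) < thr$futility_prob
      else rep(FALSE, length(alive))
    } else { # PredP
      if (is_final) {
        p <- .chunked_tails(ec, nc, et, nt, rule$prior, 0, rule$grid_size)
        eff <- pmax(p[, 1], 1 - p[, 1]) > thr$efficacy
        fut <- rep(FALSE, length(alive))
      } else {
        eff <- fut <- logical(length(alive))
        for (i in seq_along(alive)) {
          pp <- predictive_probability(
            ec[i], nc, et[i], nt,
            control_remaining = lay$nc[m] - nc,
            treat_remaining = lay$nt[m] - nt,
            prior = rule$prior, success_threshold = thr$efficacy,
            n_draws = rule$n_draws, grid_size = rule$grid_size)
          dec <- predp_decision(pp, thr)
          eff[i] <- dec == "stop_efficacy"
          fut[i] <- dec == "stop_futility"
        }
      }
    }
    stopping <- if (is_final) rep(TRUE, length(alive)) else (eff | fut)
    if (any(stopping)) {
      idx <- alive[stopping]
      stage[idx] <- k
      reason[idx] <- if (is_final) {
        ifelse(eff[stopping], "final_reject", "final_accept")
      } else {
        ifelse(eff[stopping], "efficacy", "futility")
      }
      or_stop[idx] <- zo$or[stopping]
      z_stop[idx] <- zo$z[stopping]
      alive <- alive[!stopping]
    }
  }
  data.frame(trial = seq_len(n_sim), stage = stage, reason = reason,
             n_stop = lay$n_cut[stage], or = or_stop, z = z_stop)
}

.chunked_tails <- function(ec, nc, et, nt, prior, cuts, grid_size,
                           chunk = 4000L) {
  D <- length(ec)
  out <- matrix(NA_real_, D, length(cuts))
  for (s in seq(1L, D, by = chunk)) {
    e <- s:min(s + chunk - 1L, D)
    out[e, ] <- .or_tail_batch(ec[e], nc, et[e], nt, prior, cuts,
                               max(grid_size, 257))$less
  }
  out
}

#' Operating characteristics of a set of simulated trials
#'
#' Aggregates per-trial stopping records into the standard performance
#' measures: probabilities of an early correct decision (ECD) and early
#' incorrect decision (EID), overall efficacy and interim-futility stopping
#' probabilities, cumulative per-stage stopping curves, expected sample size
#' and its relative reduction, empirical type I error (null truth) or power
#' (alternative truth), and the mean estimated odds ratio at stopping.
#' Under the null, ECD counts futility stops at interims and EID efficacy
#' stops at interims; under the alternative the roles swap. Type I error /
#' power is the overall probability of an efficacy rejection at any analysis
#' including the final one. Monte-Carlo standard errors accompany every
#' probability.
#'
#' @param results A `trial_sims` data frame from [simulate_trials()], or a
#'   list of `trial_result` objects from [run_trial()].
#' @param scenario The generating [trial_scenario()]; defaults to the one
#'   attached to `results`.
#' @param truth `"null"` or `"alternative"`; defaults to the scenario's
#'   hypothesis tag.
#' @return An object of class `oc_report`.
#' @export
compute_oc <- function(results, scenario = attr(results, "scenario"),
                       truth = scenario$hypothesis) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, TRUE, "trial_result"))) {
    kinds <- unique(vapply(results, `[[`, "", "rule_kind"))
    if (length(kinds) != 1)
      stop("mixed-rule results: all trials must come from one (design, K, scenario) cell")
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(stage = r$stage, reason = r$reason, n_stop = r$n_stop,
                 or = r$or, z = r$z)))
  }
  stopifnot(is.data.frame(results), nrow(results) > 0)
  if (is.null(scenario) || !inherits(scenario, "trial_scenario"))
    stop("a `trial_scenario` is required (supply `scenario`)")
  truth <- match.arg(truth, c("null", "alternative"))
  n <- nrow(results)
  m <- scenario$n_interims + 1
  if (any(results$stage > m))
    stop("results contain stages beyond the scenario's schedule; mixed-cell input?")

  p_se <- function(p) sqrt(p * (1 - p) / n)
  eff_any <- results$reason %in% c("efficacy", "final_reject")
  eff_interim <- results$reason == "efficacy"
  fut_interim <- results$reason == "futility"
  ecd <- if (truth == "null") mean(fut_interim) else mean(eff_interim)
  eid <- if (truth == "null") mean(eff_interim) else mean(fut_interim)
  expected_n <- mean(results$n_stop)

  stage_eff <- tabulate(results$stage[eff_any], nbins = m) / n
  stage_fut <- tabulate(results$stage[fut_interim | results$reason == "final_accept"],
                        nbins = m) / n
  structure(
    list(
      truth = truth, scenario = scenario, n_sim = n,
      n_interims = scenario$n_interims,
      ecd = ecd, ecd_se = p_se(ecd),
      eid = eid, eid_se = p_se(eid),
      p_efficacy_overall = mean(eff_any), p_efficacy_overall_se = p_se(mean(eff_any)),
      p_futility_interim = mean(fut_interim), p_futility_interim_se = p_se(mean(fut_interim)),
      cum_p_efficacy = cumsum(stage_eff), cum_p_futility = cumsum(stage_fut),
      expected_n = expected_n,
      expected_n_se = sd(results$n_stop) / sqrt(n),
      rel_n_reduction = 1 - expected_n / scenario$n_max,
      type1_or_power = mean(eff_any),
      mean_or = mean(results$or), mean_or_se = sd(results$or) / sqrt(n)
    ),
    class = "oc_report"
  )
}

#' @export
print.oc_report <- function(x, ...) {
  cat(sprintf("Operating characteristics (%s truth, %d sims): %s\n",
              x$truth, x$n_sim, x$scenario$name))
  cat(sprintf("  %s = %.4f (SE %.4f)\n",
              if (x$truth == "null") "type I error" else "power",
              x$type1_or_power, x$p_efficacy_overall_se))
  cat(sprintf("  ECD = %.4f (SE %.4f), EID = %.4f (SE %.4f)\n",
              x$ecd, x$ecd_se, x$eid, x$eid_se))
  cat(sprintf("  E[N] = %.1f (SE %.1f), reduction vs n_max = %.1f%%\n",
              x$expected_n, x$expected_n_se, 100 * x$rel_n_reduction))
  cat(sprintf("  mean estimated OR at stop = %.4f (SE %.4f)\n",
              x$mean_or, x$mean_or_se))
  invisible(x)
}

#' @export
as.data.frame.oc_report <- function(x, ...) {
  data.frame(
    scenario = x$scenario$name, truth = x$truth, n_interims = x$n_interims,
    n_sim = x$n_sim, ecd = x$ecd, eid = x$eid,
    p_efficacy_overall = x$p_efficacy_overall,
    p_futility_interim = x$p_futility_interim,
    expected_n = x$expected_n, rel_n_reduction = x$rel_n_reduction,
    type1_or_power = x$type1_or_power,
    mean_or = x$mean_or,
    ecd_se = x$ecd_se, eid_se = x$eid_se,
    p_efficacy_overall_se = x$p_efficacy_overall_se,
    expected_n_se = x$expected_n_se, mean_or_se = x$mean_or_se
  )
}

#' Simulate a grid of scenario x design x interim-count cells
#'
#' Runs [simulate_trials()] + [compute_oc()] for every combination and
#' returns one summary row per cell. Each cell draws its own seed from the
#' master seed, so cells are reproducible independently of grid order.
#'
#' @param scenario Preset names (`"ADRENAL"`, `"NICE-SUGAR"`).
#' @param hypothesis `"null"`, `"alternative"` or both.
#' @param design Monitoring strategies (subset of HP, OBF, HSD, PostP,
#'   PredP).
#' @param n_interims Interim counts to cross.
#' @param n_sim Simulated trials per cell.
#' @param seed Master seed.
#' @param n_draws,grid_size Passed to [decision_rule()] for Bayesian cells.
#' @return A data frame of class `oc_grid` (one row per cell, with
#'   Monte-Carlo standard errors); the full `oc_report` objects are in
#'   attribute `"reports"`.
#' @export
oc_grid <- function(scenario = c("ADRENAL", "NICE-SUGAR"),
                    hypothesis = c("null", "alternative"),
                    design = c("HP", "OBF", "HSD", "PostP", "PredP"),
                    n_interims = c(1, 2, 4, 9), n_sim = 10000, seed = 1,
                    n_draws = 500, grid_size = 257) {
  design <- match.arg(design, several.ok = TRUE)
  scenario <- match.arg(scenario, several.ok = TRUE)
  hypothesis <- match.arg(hypothesis, several.ok = TRUE)
  cells <- expand.grid(scenario = scenario, hypothesis = hypothesis,
                       design = design, n_interims = n_interims,
                       stringsAsFactors = FALSE)
  rules <- list()
  reports <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    key <- paste(cell$design, cell$n_interims)
    if (is.null(rules[[key]]))
      rules[[key]] <- decision_rule(cell$design, cell$n_interims,
                                    n_draws = n_draws, grid_size = grid_size)
    sc <- make_preset(cell$scenario, cell$hypothesis, cell$n_interims)
    cell_seed <- (as.integer(seed) + 104729L * i) %% 2147483629L
    sims <- simulate_trials(sc, rules[[key]], n_sim, seed = cell_seed)
    rep_i <- compute_oc(sims)
    reports[[i]] <- rep_i
    rows[[i]] <- cbind(design = cell$design, as.data.frame(rep_i),
                       seed = cell_seed)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  attr(out, "seed") <- seed
  class(out) <- c("oc_grid", "data.frame")
  out
}

#' Mean estimated odds ratio and early-stopping bias
#'
#' Averages the unadjusted OR recorded at each simulated trial's stopping
#' analysis and reports its difference from the true OR. With interim
#' stopping the naive estimator is negatively biased (further from 1) under
#' a true effect, increasingly so with more interims.
#'
#' @param results A `trial_sims` data frame or list of `trial_result`s.
#' @param true_or The generating odds ratio.
#' @return A list with `mean_or`, `bias`, `se` and `n_sim`.
#' @export
bias_summary <- function(results, true_or) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(or = r$or)))
  mean_or <- mean(results$or)
  list(mean_or = mean_or, bias = mean_or - true_or,
       se = sd(results$or) / sqrt(nrow(results)), n_sim = nrow(results))
}
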