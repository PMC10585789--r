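---
title: "Interim monitoring of two-arm binary trials: models, boundaries and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interim monitoring of two-arm binary trials: models, boundaries and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seqmonitor` evaluates interim-monitoring strategies for two-arm randomised
trials with a binary endpoint. The motivating setting is late-phase critical
care: very large trials (thousands of patients), 90-day mortality as the
primary outcome, modest absolute treatment effects, and outcomes observed
quickly relative to recruitment — exactly the setting where a well-chosen
interim schedule can answer the trial question with far fewer patients. The
package ships two presets modelled on large published critical-care trials:
an "ADRENAL-like" configuration (3658 patients, 33% control mortality, 5%
absolute reduction under the alternative, odds ratio 0.79) and a
"NICE-SUGAR-like" configuration (6022 patients, 30% control mortality, 3.8%
absolute reduction, odds ratio 0.83).

```{r}
library(seqmonitor)
make_preset("ADRENAL", "alternative", n_interims = 4)
```

## Data-generating model

Each simulated patient `j` in arm `i` contributes an independent Bernoulli
outcome with probability `p_i`. Allocation is exact 1:1 by strict
alternation, so arm totals differ by at most one patient at any enrolment
cut and are equal at the final analysis; this matches the balance that the
design assumes at every look. Outcomes are treated as available immediately
and recruitment as paused during interim analyses, so an early stop at
information fraction `t` saves the full `(1 - t) * n_max` patients. Interim
analyses are equally spaced: with `K` interims the k-th occurs after
`round(k / (K + 1) * n_max)` patients. The rounding to the nearest patient
(rather than, say, the nearest even number) is our choice; it reproduces
familiar cut sizes such as 2926 of 3658 at 80% information and 4215 of 6022
at 70%, at the cost of a one-patient imbalance at odd cuts.

Neither staggered accrual, outcome lag, missing outcomes nor covariates are
modelled. Passing tests therefore demonstrate the operating characteristics
of the decision rules under idealised information flow, not the attenuation
that recruitment-during-analysis causes in practice.

## The interim statistic

Every look fits the unadjusted logistic model `logit(p) = b0 + b1 * arm` to
the accumulated 2x2 table. For a single binary covariate the MLE is closed
form: `b1` is the empirical log odds ratio and its Wald standard error is
`sqrt(1/e_c + 1/(n_c - e_c) + 1/e_t + 1/(n_t - e_t))`. The monitoring
z-statistic uses a benefit-positive convention, `z = -b1 / se`, so that
fewer events on treatment gives positive `z`; futility boundaries are
curves in this benefit direction only. If a single cell of the table is
empty, 0.5 is added to all four cells (Haldane–Anscombe) to keep the
statistic defined; at the sample sizes simulated here this occurs with
negligible probability. A table with a constant outcome in both arms is
flagged indeterminate and scored as `z = 0`.

## Group-sequential boundaries

Three frequentist rules are implemented.

**Haybittle–Peto (HP)** uses a fixed critical value of 3 at every interim
and 1.96 at the final analysis, with no futility monitoring. It is not an
error-spending design; its simplicity costs almost nothing in type I error
(the interim looks at |z| >= 3 add about 0.2–0.5%).

**O'Brien–Fleming (OBF)** and **Hwang–Shih–DeCani (HSD)** allocate the
overall two-sided `alpha = 0.05` across looks through a spending function
of the information fraction `t`:

* OBF: `a(t) = 2 - 2 * Phi(z_{1 - a/2} / sqrt(t))`, essentially no spending
  early and steep spending near the end;
* HSD: `a(t) = a * (1 - exp(-g t)) / (1 - exp(-g))` with shape `g = -4`,
  chosen so the boundaries sit between HP and OBF in early-look
  conservatism.

Futility uses the matching beta-spending function (`alpha` replaced by
`beta = 0.10`, same `g` for HSD) and is **binding**: a crossed futility
boundary stops the trial, and that truncation is used when computing the
efficacy boundaries.

### Boundary solving

The sequential z-statistics are jointly normal with
`Cov(Z_j, Z_k) = sqrt(t_j / t_k)`. The solver carries the sub-density of
"`Z_k = z` and the trial is still running" across stages on a
Gauss–Legendre grid (512 nodes by default) over each continuation region;
stage transitions and tail crossings are Gaussian and evaluated in closed
form, so no explicit 2-D integration is needed. Per-stage critical values
are found by bracketed root finding (`uniroot` to 1e-9 on the z-scale).

Efficacy boundaries are symmetric `±u_k` and are solved so that the
cumulative probability, under the null, of `|Z| >= u` at or before `t_k` —
with earlier continuation regions truncated by the binding futility bounds,
and efficacy checked before futility — equals the spending value `a(t_k)`.
Two consequences are worth spelling out, because the design was genuinely
open here:

* at the first look (and in the `K = 0` limit) the construction reduces to
  the familiar two-sided form `u = qnorm(1 - a(t)/2)`, giving 1.96 for a
  single analysis;
* at later looks the harm-direction tail `Z <= -u_k` lies below the
  benefit-direction futility bound and is essentially unreachable, so
  nearly the whole incremental spend goes to the benefit side. The total
  null probability of declaring efficacy (at any look, including the final)
  is exactly `alpha` by construction — which is what "the type I error is
  maintained at 5%" means operationally for these designs.

Futility bounds `l_k` spend the beta function under a *design drift*
`theta` — the expected z-statistic at full information under the design
alternative. `theta` is not taken from the scenario: it is calibrated by an
outer root finding so that the efficacy and futility boundaries meet at the
final look. With the boundaries meeting, every trial ends in rejection or
acceptance, all of `beta` is spent, and power at the design drift is
exactly `1 - beta = 90%`.

```{r, eval = FALSE}
b <- solve_boundaries(spending_spec("OBF"), information_schedule(4))
b
sum(exit_probabilities(b, drift = 0)$efficacy)       # 0.05
sum(exit_probabilities(b, drift = b$drift)$efficacy) # 0.90
```

A point that surprises many users: the calibrated design drift (about 3.04
for OBF with four interims) is *smaller* than the drift implied by the
preset scenarios (about 3.28 for both presets, since both trials were sized
for 90% power as fixed designs at two-sided 0.05). Evaluated at the
scenario drift, the binding-futility OBF design has analytic power of about
93.5%, and the simulations reproduce this. "Power maintained at 90%" should
therefore be read as *at least* the nominal level.

`exit_probabilities()` evaluates per-stage efficacy and futility crossing
probabilities under any drift with the same recursion, and is the analytic
oracle against which the simulation engine is tested (agreement within
Monte-Carlo error at 2e5–1e6 simulated z-paths).

Numerical parameters that matter: the Gauss–Legendre grid size (512; the
test suite checks stability under doubling), the root-finding tolerances
(1e-9 inner, 1e-7 for the drift calibration), and the drift search bracket
(1.2–5.5 on the z-scale, ample for any realistic design).

## Bayesian monitoring

The Bayesian rules use the model `Y_j | i ~ Bernoulli(p_i)` with
`logit(p_i) = b0 + b1 * x_i` and a vague `N(0, 4^2)` prior placed
independently on each arm's log-odds (equivalently on `b0` and
`b0 + b1`) — a prior under which all event rates between 0 and 100% are
roughly equally likely. Note this induces a non-normal (though symmetric)
prior on `b1` itself. Because the two arm posteriors factorise, the
posterior of the odds ratio needs only two one-dimensional quadratures: each
arm's log-odds posterior is evaluated on a shared uniform grid (1025 nodes
for one-off summaries, 257 inside the simulation engine) and tails of
`b1 = theta_t - theta_c` follow by discrete convolution. The test suite
pins this engine to a dense 2048x2048 two-dimensional summation oracle
within 1e-4, and to an independence-chain MCMC sampler (the validation-only
`method = "mcmc"`) within 0.005. Deterministic quadrature rather than MCMC
is the production engine because 10,000-replicate simulations with
per-interim posterior computation are not feasible with sampling, and the
model is low-dimensional enough that quadrature is exact to tolerance.

**PostP** stops for efficacy when `max(Pr(OR < 1), Pr(OR > 1)) > 0.99`, and
for futility when `Pr(OR < 0.85) < 0.10` and `Pr(OR > 1/0.85) < 0.10`; the
final analysis classifies success by the efficacy criterion alone. With a
vague prior and large samples the efficacy rule behaves like a constant
`|z| >= 2.326` boundary at every look, which is why it inflates the type I
error as looks accumulate: in our simulations the overall null efficacy
probability is about 4.6% with two interims, 6.0% with four and 8.6% with
nine. That the inflation only emerges from four interims onwards — rather
than from two — is a consequence of using noise-free quadrature
posteriors; samplers with finite draws cross a 99% threshold more often
than the exact posterior does.

**PredP** stops on the probability, under the posterior predictive
distribution of the remaining patients' outcomes, that the completed trial
will meet the final-analysis success criterion (the posterior efficacy
criterion above). Remaining outcomes are drawn per arm from the
grid posterior (500 draws by default); when at most 12 outcomes
per arm remain the predictive distribution is enumerated exactly, and the
Monte-Carlo path is tested against that enumeration. The stop-high/stop-low
cutoffs default to 0.99 and 0.10, *mirroring* the PostP thresholds; they are
package choices, configurable in `bayes_thresholds()`, and results for PredP
designs should be read with that caveat. One structural feature deserves
emphasis: at information fraction 1/3 with no observed effect, the
predictive probability of final success is almost exactly 0.10
(`2 * Phi(-z_{0.99} / sqrt(2))`), i.e. *on* the default stop-low cutoff.
First-look PredP futility behaviour at `t = 1/3` is therefore razor-edge
sensitive to the cutoff and to any noise in the predictive estimate, and
small implementation differences produce large differences in early-stop
rates. REMAP-CAP-style futility margins (`1/1.2`, `1.2`) are available as a
configuration alternative.

## Operating characteristics and bias

`simulate_trials()` draws per-stage event increments directly as binomial
counts (the distribution of the patient-level generator under the
alternating allocation; the equivalence with `run_trial()` on patient-level
data is asserted in the tests) and applies the decision rules stage by
stage with binding stopping. `compute_oc()` aggregates the standard
measures: early correct/incorrect decision probabilities (futility stops
under the null are "correct", efficacy stops under the alternative are
"correct", and conversely), overall efficacy probability at any analysis
(the type I error under the null, power under the alternative), cumulative
per-stage stopping curves, expected sample size with its relative reduction
versus `n_max`, and the mean estimated OR at stopping. Monte-Carlo standard
errors accompany every probability so that reduced-replication runs remain
interpretable; an expected sample size for trials reaching the end counts
exactly `n_max` (recruitment is paused during analyses).

The recorded treatment effect is the *naive* estimate at the stopping cut,
deliberately: the package measures the selection bias of early stopping,
not corrected estimators. Two systematic effects are visible in the
simulations:

* under a true effect, the mean estimated OR falls below the truth,
  increasingly so with more interims (trials that stop early for efficacy
  do so on randomly favourable data);
* under the null, designs with binding futility show a small *positive*
  shift in the mean OR (about +0.03 for OBF with four interims): futility
  stops select benefit-direction z below the futility bound, i.e. tables
  whose observed OR leans above 1. The often-quoted "no bias under the
  null" is exact only for designs without early stopping, and the test
  suite asserts unbiasedness under a no-stopping configuration.

## Problem sizes and reproducibility

Simulation cells in the test suite and the acceptance script use 10,000
replicates for the frequentist designs (the full replication of the study
the presets emulate) and 2,000 replicates for predictive-probability cells,
whose per-interim predictive simulation is the dominant cost; at these
sizes a binomial probability carries a standard error of at most 0.5
points. Every cell derives its own seed from a master seed, so grids are
reproducible cell by cell and identical seeds give byte-identical outputs.

## Known limitations

* Equally spaced looks only, one interim schedule per run; no sample-size
  re-estimation, arm dropping or response-adaptive randomisation.
* The PredP cutoffs and final-success criterion are declared package
  defaults (see above); published operating characteristics for
  predictive-probability designs are highly sensitive to these choices and
  should not be compared across implementations without calibration.
* The frequentist comparisons assume the Wald z from the unadjusted
  logistic fit; score or likelihood-ratio monitoring would shift boundaries
  slightly at small information fractions.
* Real-data replay is structural: the package applies decision logic to
  user-supplied per-stage summary tables, but ships only a synthetic
  fixture.
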