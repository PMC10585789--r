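# seqmonitor

Group-sequential and Bayesian interim monitoring for two-arm trials with a
binary endpoint.

Late-phase critical-care trials randomise thousands of patients to detect
modest absolute differences in short-term mortality. Because the outcome is
observed quickly, pre-planned interim analyses can stop such a trial for
efficacy — or, just as importantly, for futility — long before full
enrolment. `seqmonitor` is for trial statisticians who want to compare
interim-monitoring strategies at the design stage: it computes stopping
boundaries, simulates trials under null and alternative scenarios, and
reports the operating characteristics that drive the design choice (type I
error, power, probabilities of an early correct/incorrect decision,
expected sample size, and the bias of the naive treatment-effect estimate
under early stopping).

Five monitoring strategies are implemented:

* **HP** — Haybittle–Peto: fixed interim critical value 3, final analysis
  at 1.96, no futility monitoring.
* **OBF**, **HSD** — error-spending designs (O'Brien–Fleming-type and
  Hwang–Shih–DeCani with shape γ = −4) with two-sided α = 0.05 spent as
  α(t) across looks, binding futility boundaries from the matching
  β-spending function (β = 0.10), and the design drift calibrated so the
  boundaries meet at the final look and power is exactly 90%. Boundaries
  are solved by recursive numerical integration of the correlated
  z-statistic path (`Cov(Z_j, Z_k) = √(t_j/t_k)`) on a Gauss–Legendre
  grid.
* **PostP** — Bayesian posterior-probability rule: stop for efficacy when
  `max(Pr(OR < 1), Pr(OR > 1)) > 0.99`, for futility when
  `Pr(OR < 0.85) < 0.10` and `Pr(OR > 1/0.85) < 0.10`, under independent
  N(0, 4²) priors on each arm's log-odds.
* **PredP** — Bayesian predictive-probability rule: stop on the posterior
  predictive probability that the completed trial meets the final-analysis
  success criterion (cutoffs 0.99 / 0.10 by default; these are package
  defaults — see the methods vignette).

Interim analyses fit the unadjusted logistic regression of outcome on arm;
the monitoring statistic is the benefit-positive Wald z (`z = −β̂₁/SE`, so
odds ratios below 1 give positive z).

Two scenario presets reproduce the design assumptions of two large
critical-care trials: `"ADRENAL"` (n = 3658, 33% vs 33% under the null,
33% vs 28% under the alternative, OR 0.79) and `"NICE-SUGAR"` (n = 6022,
30% vs 30%, 30% vs 26.2%, OR 0.83).

## Worked example

Solve the O'Brien–Fleming boundaries for four equally spaced interims and
simulate the ADRENAL-like alternative scenario:

```r
library(seqmonitor)

b <- solve_boundaries(spending_spec("OBF"), information_schedule(4))
b
#> Group-sequential boundary set (OBF): 4 interim(s) + final
#>   design drift 3.0365
#>  stage   t efficacy_z futility_z cum_alpha_spent cum_beta_spent
#>      1 0.2      4.383    -2.1392       1.173e-05      0.0002351
#>      2 0.4      2.994    -0.4361       1.942e-03      0.0093022
#>      3 0.6      2.311     0.4838       1.140e-02      0.0337122
#>      4 0.8      1.965     1.1231       2.843e-02      0.0659149
#>      5 1.0      1.673     1.6731       5.000e-02      0.1000000
```

Early efficacy needs |z| ≥ 4.38 at 20% information but only 1.67 at the
final look; the futility curve rises to meet it there, so every trial ends
with a definitive answer and exactly 5% type I error / 90% power at the
design drift are spent by construction.

```r
sc   <- make_preset("ADRENAL", "alternative", n_interims = 4)
rule <- decision_rule("OBF", 4, boundaries = b)
sims <- simulate_trials(sc, rule, n_sim = 10000, seed = 1)
compute_oc(sims)
#> Operating characteristics (alternative truth, 10000 sims): ADRENAL (alternative)
#>   power = 0.9359 (SE 0.0024)
#>   ECD = 0.8390 (SE 0.0037), EID = 0.0427 (SE 0.0020)
#>   E[N] = 2423.6 (SE 6.7), reduction vs n_max = 33.7%
#>   mean estimated OR at stop = 0.7776 (SE 0.0008)
```

Under the true OR of 0.79, 84% of trials stop early for efficacy (an early
correct decision), 4% stop early for futility (an early incorrect one), and
the expected sample size falls by a third — at the cost of a naive OR
estimate biased slightly away from 1. Power exceeds the nominal 90%
because both presets were sized for 90% power as *fixed* designs, and the
binding-futility construction reaches its nominal power at a smaller
design effect.

A single trial can be run patient-level, and external per-stage summary
tables can be replayed against any rule:

```r
run_trial(generate_trial(sc, seed = 7), rule)
#> Trial result (OBF): efficacy at stage 4, n = 2926
#>   estimated OR at stop 0.8441 (benefit-positive z 2.118)

replay(read.csv(system.file("extdata", "replay_synthetic_obf_futility.csv",
                            package = "seqmonitor")), rule)
```

`oc_grid()` crosses scenarios × designs × interim counts with per-cell
seeds, and `run_simulation_config()` drives the same grid from a flat YAML
file (a thin command-line front-end ships in `inst/cli/seqmonitor-cli.R`).

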