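toy_results <- function() {
  # 3 futility stops, 1 efficacy stop, 6 reaching the final analysis
  data.frame(
    trial = 1:10,
    stage = c(1, 2, 2, 3, 5, 5, 5, 5, 5, 5),
    reason = c("futility", "futility", "efficacy", "futility",
               rep("final_accept", 5), "final_reject"),
    n_stop = c(732, 1463, 1463, 2195, rep(3658, 6)),
    or = c(1.02, 0.98, 0.70, 1.01, rep(1, 5), 0.85),
    z = 0
  )
}

test_that("operating characteristics match a hand-countable result set", {
  sc <- make_preset("ADRENAL", "null", 4)
  oc <- compute_oc(toy_results(), scenario = sc, truth = "null")
  expect_equal(oc$ecd, 0.3)
  expect_equal(oc$eid, 0.1)
  expect_equal(oc$p_efficacy_overall, 0.2)
  expect_equal(oc$p_futility_interim, 0.3)
  expect_equal(oc$expected_n, mean(toy_results()$n_stop))
  expect_equal(oc$rel_n_reduction, 1 - oc$expected_n / 3658)
  # role swap under the alternative
  oc_alt <- compute_oc(toy_results(), scenario = sc, truth = "alternative")
  expect_equal(oc_alt$ecd, 0.1)
  expect_equal(oc_alt$eid, 0.3)
  # conservation: P(E) + P(F at interims) + P(final accept) = 1
  expect_equal(oc$p_efficacy_overall + oc$p_futility_interim + 0.5, 1)
  # cumulative stage curves are nondecreasing and end at the totals
  expect_true(all(diff(oc$cum_p_efficacy) >= 0))
  expect_equal(oc$cum_p_efficacy[5], oc$p_efficacy_overall)
})

test_that("degenerate and invalid inputs are handled", {
  sc <- make_preset("ADRENAL", "null", 4)
  one <- compute_oc(toy_results()[1, ], scenario = sc, truth = "null")
  expect_true(all(c(one$ecd, one$eid, one$p_efficacy_overall) %in% c(0, 1)))
  bad <- toy_results()
  bad$stage[1] <- 9
  expect_error(compute_oc(bad, scenario = sc, truth = "null"), "mixed-cell")
})

test_that("all trials reaching the final analysis leave no early decisions", {
  sc <- make_preset("ADRENAL", "null", 1)
  res <- data.frame(trial = 1:5, stage = 2, reason = "final_accept",
                    n_stop = 3658, or = 1, z = 0)
  oc <- compute_oc(res, scenario = sc, truth = "null")
  expect_equal(oc$ecd, 0)
  expect_equal(oc$eid, 0)
  expect_equal(oc$expected_n, 3658)
})

test_that("HP under the null never makes an early correct decision", {
  sc <- make_preset("ADRENAL", "null", 2)
  sims <- simulate_trials(sc, decision_rule("HP", 2), 800, seed = 21)
  oc <- compute_oc(sims)
  expect_equal(oc$ecd, 0)
  expect_gt(oc$expected_n, 0.99 * sc$n_max)
})

test_that("expected sample size decreases with more interims (futility designs)", {
  e_n <- vapply(c(1, 2, 4), function(K) {
    sc <- make_preset("ADRENAL", "null", K)
    rule <- decision_rule("OBF", K, boundaries = cached_bounds("OBF", K))
    compute_oc(simulate_trials(sc, rule, 3000, seed = 100 + K))$expected_n
  }, 0)
  expect_true(all(diff(e_n) < 0))
})

test_that("a no-stopping configuration recovers the true OR (fixed-design MLE)", {
  sc <- make_preset("ADRENAL", "alternative", 2)
  # interim boundaries far out of reach: every trial runs to completion
  rule <- decision_rule("HP", 2, boundaries = hp_boundaries(2, interim_value = 99))
  sims <- simulate_trials(sc, rule, 4000, seed = 9)
  expect_true(all(sims$stage == 3))
  bs <- bias_summary(sims, true_or = scenario_odds_ratio(sc))
  expect_lt(abs(bs$bias), 3 * bs$se)
})

test_that("early stopping biases the estimated OR away from 1 under the alternative", {
  sc <- make_preset("ADRENAL", "alternative", 4)
  rule <- decision_rule("OBF", 4, boundaries = cached_bounds("OBF", 4))
  sims <- simulate_trials(sc, rule, 4000, seed = 10)
  bs <- bias_summary(sims, true_or = scenario_odds_ratio(sc))
  expect_lt(bs$mean_or + 3 * bs$se, scenario_odds_ratio(sc))
  # without stopping, the null scenario is unbiased; binding futility under
  # the null concentrates a small positive selection effect in the stopped
  # trials, so the clean no-bias statement needs the no-stopping rule
  no_stop <- decision_rule("HP", 4, boundaries = hp_boundaries(4, interim_value = 99))
  sims0 <- simulate_trials(make_preset("ADRENAL", "null", 4), no_stop, 4000,
                           seed = 11)
  bs0 <- bias_summary(sims0, true_or = 1)
  expect_lt(abs(bs0$bias), 3 * bs0$se + 0.005)
})

test_that("oc_grid crosses cells reproducibly with per-cell seeds", {
  g1 <- oc_grid(scenario = "ADRENAL", hypothesis = "null", design = "HP",
                n_interims = c(1, 2), n_sim = 60, seed = 4)
  g2 <- oc_grid(scenario = "ADRENAL", hypothesis = "null", design = "HP",
                n_interims = c(1, 2), n_sim = 60, seed = 4)
  expect_equal(as.data.frame(g1), as.data.frame(g2))
  expect_equal(nrow(g1), 2)
  expect_true(all(c("ecd", "eid", "expected_n", "type1_or_power",
                    "mean_or") %in% names(g1)))
})
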