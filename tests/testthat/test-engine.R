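fixture_path <- system.file("extdata", "replay_synthetic_obf_futility.csv",
                            package = "seqmonitor")

test_that("decision rules validate their configuration", {
  hp <- decision_rule("HP", 2)
  expect_s3_class(hp$boundaries, "boundary_set")
  expect_error(decision_rule("HP", -1))
  sc <- make_preset("ADRENAL", "null", 4)
  td <- generate_trial(sc, seed = 1)
  expect_error(run_trial(td, hp), "interims")
})

test_that("replayed summaries reproduce the group-sequential decisions", {
  tab <- read.csv(fixture_path)

  # HP never stops on these unremarkable z-values: final decision at n_max
  hp <- decision_rule("HP", 4)
  res_hp <- replay(tab, hp)
  expect_equal(res_hp$stage, 5)
  expect_equal(res_hp$reason, "final_accept")
  expect_equal(res_hp$n_stop, 3658)

  # OBF with binding futility stops the same data at 80% information
  obf <- decision_rule("OBF", 4, boundaries = cached_bounds("OBF", 4))
  res_obf <- replay(tab, obf)
  expect_equal(res_obf$reason, "futility")
  expect_equal(res_obf$stage, 4)
  expect_equal(res_obf$n_stop, 2926)

  # single-stage replay: |z| > 1.96 rejects at the final analysis
  one <- data.frame(stage = 1, t = 1, control_events = 660, control_n = 2000,
                    treat_events = 560, treat_n = 2000)
  res1 <- replay(one, decision_rule("HP", 0))
  expect_equal(res1$reason, "final_reject")

  # early large effect stops at the first interim
  tab2 <- tab
  tab2$treat_events[1] <- 40
  expect_equal(replay(tab2, obf)$stage, 1)
  expect_equal(replay(tab2, obf)$reason, "efficacy")
  expect_equal(replay(tab2, obf)$n_stop, 732)
})

test_that("malformed replay tables fail with row-level messages", {
  tab <- read.csv(fixture_path)
  obf <- decision_rule("OBF", 4, boundaries = cached_bounds("OBF", 4))
  bad <- tab
  bad$treat_events[3] <- bad$treat_n[3] + 5
  expect_error(replay(bad, obf), "row 3")
  expect_error(replay(tab[, -3], obf), "missing column")
  expect_error(replay(tab[1:3, ], obf), "expects 5")
})

test_that("single-trial runs agree with the vectorised engine", {
  sc <- make_preset("ADRENAL", "alternative", 2)
  rules <- list(
    decision_rule("HP", 2),
    decision_rule("OBF", 2, boundaries = cached_bounds("OBF", 2)),
    decision_rule("PostP", 2)
  )
  lay <- seqmonitor:::.stage_layout(sc)
  n_rep <- 25
  for (rule in rules) {
    for (i in seq_len(n_rep)) {
      td <- generate_trial(sc, seed = 1000 + i)
      res <- run_trial(td, rule)
      # cut the same patient-level data into cumulative stage counts
      Ec <- Et <- matrix(0L, length(lay$t), 1)
      for (k in seq_along(lay$t)) {
        rows <- td[seq_len(lay$n_cut[k]), ]
        Ec[k, 1] <- sum(rows$outcome[rows$arm == 0])
        Et[k, 1] <- sum(rows$outcome[rows$arm == 1])
      }
      vec <- seqmonitor:::.decide_paths(rule, Ec, Et, lay, 1L)
      expect_equal(res$stage, vec$stage)
      expect_equal(res$n_stop, vec$n_stop)
      reason_map <- c(stop_efficacy = "efficacy", stop_futility = "futility")
      expect_equal(res$reason, vec$reason)
      expect_equal(res$or, vec$or, tolerance = 1e-12)
    }
  }
})

test_that("simulated HP stopping fractions match the analytic exit probabilities", {
  sc <- make_preset("ADRENAL", "alternative", 2)
  rule <- decision_rule("HP", 2)
  sims <- simulate_trials(sc, rule, n_sim = 4000, seed = 77)
  p_eff <- mean(sims$reason %in% c("efficacy", "final_reject"))
  p_true <- sum(exit_probabilities(rule$boundaries, scenario_drift(sc))$efficacy)
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(p_eff - p_true), 3 * se + 0.005)
})

test_that("stopping is binding and sample size tracks the stage", {
  sc <- make_preset("ADRENAL", "null", 4)
  rule <- decision_rule("OBF", 4, boundaries = cached_bounds("OBF", 4))
  sims <- simulate_trials(sc, rule, n_sim = 1500, seed = 5)
  lay <- seqmonitor:::.stage_layout(sc)
  expect_true(all(sims$n_stop == lay$n_cut[sims$stage]))
  expect_true(all(sims$n_stop <= sc$n_max))
  expect_true(all(sims$reason[sims$stage < 5] %in% c("efficacy", "futility")))
  expect_true(all(sims$reason[sims$stage == 5] %in% c("final_reject", "final_accept")))
  # HP can never stop for futility
  hp_sims <- simulate_trials(sc, decision_rule("HP", 4), n_sim = 1000, seed = 6)
  expect_false(any(hp_sims$reason == "futility"))
  # identical seed, identical trials
  expect_identical(sims, simulate_trials(sc, rule, n_sim = 1500, seed = 5))
})
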