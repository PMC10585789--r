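# independent oracle: direct two-dimensional summation of the joint
# posterior of the two arm log-odds on a dense product grid
oracle_or_tails <- function(ec, nc, et, nt, cuts, prior_sd = 4, n_grid = 2048) {
  arm <- function(e, n) {
    ctr <- qlogis((e + 0.5) / (n + 1))
    s <- sqrt(1 / (e + 0.5) + 1 / (n - e + 0.5))
    x <- seq(ctr - 10 * s, ctr + 10 * s, length.out = n_grid)
    lp <- dnorm(x, 0, prior_sd, log = TRUE) + e * plogis(x, log.p = TRUE) +
      (n - e) * plogis(-x, log.p = TRUE)
    p <- exp(lp - max(lp))
    list(x = x, p = p / sum(p))
  }
  ac <- arm(ec, nc)
  at <- arm(et, nt)
  diff <- outer(ac$x, at$x, function(xc, xt) xt - xc)
  w <- outer(ac$p, at$p)
  h <- at$x[2] - at$x[1]
  # fractional coverage of the boundary cells (piecewise-constant density)
  vapply(cuts, function(cc) sum(w * pmin(pmax((cc - diff) / h + 0.5, 0), 1)), 0)
}

test_that("quadrature posterior matches a dense two-dimensional oracle", {
  cases <- list(c(30, 100, 25, 100), c(121, 366, 112, 366),
                c(10, 30, 3, 30), c(483, 1463, 420, 1463))
  cuts <- c(0, log(0.85), -log(0.85))
  for (cs in cases) {
    ps <- posterior_summary(cs[1], cs[2], cs[3], cs[4])
    orc <- oracle_or_tails(cs[1], cs[2], cs[3], cs[4], cuts)
    expect_lt(abs(ps$pr_or_less_1 - orc[1]), 1e-4)
    expect_lt(abs(ps$pr_or_less_margin - orc[2]), 1e-4)
    expect_lt(abs(ps$pr_or_greater_invmargin - (1 - orc[3])), 1e-4)
  }
})

test_that("posterior tails behave at the symmetry and evidence limits", {
  sym <- posterior_summary(40, 120, 40, 120)
  expect_equal(sym$pr_or_less_1, 0.5, tolerance = 1e-8)
  expect_equal(sym$pr_or_less_1 + sym$pr_or_greater_1, 1)
  expect_lte(sym$pr_or_less_margin, sym$pr_or_less_1)

  strong <- posterior_summary(50, 100, 10, 100)
  expect_gt(strong$pr_or_less_1, 0.9999)
})

test_that("grid and MCMC posteriors agree across the simulated regimes", {
  set.seed(7)
  rates <- cbind(pc = runif(50, 0.2, 0.4), pt = runif(50, 0.2, 0.4))
  sizes <- sample(c(30, 100, 366, 1100, 3000), 50, replace = TRUE)
  for (i in seq_len(50)) {
    n <- sizes[i]
    ec <- rbinom(1, n, rates[i, 1])
    et <- rbinom(1, n, rates[i, 2])
    g <- posterior_summary(ec, n, et, n)
    m <- posterior_summary(ec, n, et, n, method = "mcmc", n_iter = 120000)
    expect_lt(abs(g$pr_or_less_1 - m$pr_or_less_1), 0.005)
    expect_lt(abs(g$pr_or_less_margin - m$pr_or_less_margin), 0.005)
    expect_lt(abs(g$pr_or_greater_invmargin - m$pr_or_greater_invmargin), 0.005)
  }
})

test_that("with vague priors and large samples the posterior matches the Wald tail", {
  # Bernstein-von Mises sanity check at n >= 1000 per arm
  for (cs in list(c(400, 1200, 360, 1200), c(330, 1000, 280, 1000))) {
    ps <- posterior_summary(cs[1], cs[2], cs[3], cs[4])
    f <- fit_interim(cs[1], cs[2], cs[3], cs[4])
    expect_equal(ps$pr_or_less_1, pnorm(f$z), tolerance = 0.01)
  }
})

test_that("posterior-probability decisions follow the thresholds", {
  thr <- bayes_thresholds()
  mk <- function(p1, pm, pim) {
    structure(list(pr_or_less_1 = p1, pr_or_greater_1 = 1 - p1,
                   pr_or_less_margin = pm, pr_or_greater_invmargin = pim,
                   mean_log_or = 0, margin = 0.85, method = "grid"),
              class = "posterior_summary")
  }
  expect_equal(postp_decision(mk(0.995, 0.5, 0.001), thr), "stop_efficacy")
  expect_equal(postp_decision(mk(0.004, 0.001, 0.5), thr), "stop_efficacy")
  expect_equal(postp_decision(mk(0.6, 0.05, 0.04), thr), "stop_futility")
  expect_equal(postp_decision(mk(0.5, 0.3, 0.2), thr), "continue")
  expect_equal(postp_decision(mk(0.995, 0.5, 0.001), thr, is_final = TRUE),
               "final_reject")
  expect_equal(postp_decision(mk(0.6, 0.05, 0.04), thr, is_final = TRUE),
               "final_accept")
})

test_that("predictive probability: limits, enumeration oracle, monotonicity", {
  # nothing remaining: deterministic success indicator
  done_yes <- predictive_probability(50, 100, 10, 100, 0, 0)
  done_no <- predictive_probability(30, 100, 30, 100, 0, 0)
  expect_equal(as.numeric(done_yes), 1)
  expect_equal(as.numeric(done_no), 0)

  # overwhelming interim effect: near-certain final success
  big <- predictive_probability(300, 600, 100, 600, 100, 100, n_draws = 200)
  expect_gt(big, 0.99)

  # Monte-Carlo estimate agrees with exact enumeration (<= 12 per arm)
  set.seed(31)
  exact <- predictive_probability(12, 30, 5, 30, 6, 6)
  expect_identical(attr(exact, "method"), "enumeration")
  mc <- predictive_probability(12, 30, 5, 30, 6, 6, enum_limit = 0,
                               n_draws = 4000)
  expect_identical(attr(mc, "method"), "monte-carlo")
  se <- max(attr(mc, "se"), sqrt(as.numeric(exact) * (1 - exact) / 4000))
  expect_lt(abs(as.numeric(mc) - as.numeric(exact)), 3 * se + 1e-3)

  # monotone in the strength of the interim effect (totals held fixed)
  pps <- vapply(seq(2, 16, by = 2), function(e)
    as.numeric(predictive_probability(16, 40, e, 40, 10, 10)), 0)
  expect_true(all(diff(pps) <= 1e-9))
})

test_that("predictive-probability decisions follow the cutoffs", {
  thr <- bayes_thresholds()
  expect_equal(predp_decision(1.0, thr), "stop_efficacy")
  expect_equal(predp_decision(0.0, thr), "stop_futility")
  expect_equal(predp_decision(0.5, thr), "continue")
  expect_error(predp_decision(1.2, thr))
})

test_that("prior and threshold constructors validate their arguments", {
  expect_error(bayes_prior(sd = 0))
  expect_error(bayes_thresholds(efficacy = 1.2))
  expect_equal(bayes_prior()$sd, 4)
})
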