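# Bayesian monitoring under the model Y_j | arm i ~ Bernoulli(p_i) with
# logit(p_i) = b0 + b1 * x_i and independent normal priors on each arm's
# log-odds. The two arm posteriors factorise, so odds-ratio tail
# probabilities are obtained by deterministic one-dimensional quadrature of
# each arm's log-odds posterior on a shared uniform grid followed by a
# discrete convolution; an independence-chain MCMC sampler is provided as a
# validation mode only.

#' Vague normal prior on each arm's log-odds
#'
#' The default N(0, 4^2) prior on logit(p) makes all event rates between 0
#' and 100% roughly equally likely a priori. The same prior is placed
#' independently on both arms (equivalently on `b0` and `b0 + b1`), which
#' induces a non-normal but symmetric prior on the log odds ratio `b1`
#' itself.
#'
#' @param mean,sd Prior mean and standard deviation of the log-odds.
#' @return An object of class `bayes_prior`.
#' @export
bayes_prior <- function(mean = 0, sd = 4) {
  if (!is.numeric(sd) || sd <= 0) stop("prior `sd` must be positive")
  structure(list(mean = mean, sd = sd), class = "bayes_prior")
}

#' Stopping thresholds for the Bayesian monitoring rules
#'
#' Posterior-probability (PostP) rule: stop for efficacy when the posterior
#' probability that the arms differ, `max(Pr(OR < 1), Pr(OR > 1))`, exceeds
#' `efficacy`; stop for futility when both `Pr(OR < margin)` and
#' `Pr(OR > 1 / margin)` fall below `futility_prob`.
#'
#' Predictive-probability (PredP) rule: stop for efficacy when the
#' predictive probability of final-analysis success is at least
#' `predp_high`, for futility when it is at most `predp_low`; final-analysis
#' success is the posterior efficacy criterion evaluated on the completed
#' data. The PredP cutoffs are a design choice of this package (defaults
#' mirror the PostP thresholds) and should be calibrated by simulation for
#' any new application.
#'
#' @param efficacy Posterior probability threshold for efficacy.
#' @param futility_margin Odds-ratio margin for futility (the rule uses
#'   `margin` and `1 / margin`); `1/1.2` gives the REMAP-CAP-style margins.
#' @param futility_prob Probability floor for the futility rule.
#' @param predp_high,predp_low PredP stop-high and stop-low cutoffs.
#' @return An object of class `bayes_thresholds`.
#' @export
bayes_thresholds <- function(efficacy = 0.99, futility_margin = 0.85,
                             futility_prob = 0.10, predp_high = 0.99,
                             predp_low = 0.10) {
  vals <- c(efficacy, futility_margin, futility_prob, predp_high, predp_low)
  if (any(vals <= 0) || any(vals >= 1 + 1e-12) ||
      efficacy >= 1 || predp_high > 1 || futility_margin >= 1)
    stop("thresholds must lie strictly between 0 and 1 (margin below 1)")
  structure(list(efficacy = efficacy, futility_margin = futility_margin,
                 futility_prob = futility_prob, predp_high = predp_high,
                 predp_low = predp_low),
            class = "bayes_thresholds")
}

# normal approximation to an arm's log-odds posterior (grid placement only);
# vectorised over e and n
.arm_post_approx <- function(e, n, prior) {
  n <- rep_len(n, length(e))
  c_lik <- qlogis((e + 0.5) / (n + 1))
  w <- ifelse(n == 0, 0, 1 / (1 / (e + 0.5) + 1 / (n - e + 0.5)))
  wp <- 1 / prior$sd^2
  list(center = ifelse(n == 0, prior$mean,
                       (w * c_lik + wp * prior$mean) / (w + wp)),
       sd = 1 / sqrt(w + wp))
}

# Tail probabilities P(b1 < cut) of the log odds ratio b1 = theta_t -
# theta_c for a batch of 2x2 tables sharing comparable count magnitudes.
# ec, et (and optionally nc, nt) are vectors over the batch. Returns a list
# with matrix `less` (batch x cuts) and vector `mean_b1`.
.or_tail_batch <- function(ec, nc, et, nt, prior, cuts = 0, grid_size = 257) {
  D <- max(length(ec), length(et))
  ec <- rep_len(ec, D); et <- rep_len(et, D)
  nc <- rep_len(nc, D); nt <- rep_len(nt, D)
  apx_c <- .arm_post_approx(ec, nc, prior)
  apx_t <- .arm_post_approx(et, nt, prior)
  centers <- c(apx_c$center, apx_t$center)
  sds <- c(apx_c$sd, apx_t$sd)
  lo <- min(centers - 9 * sds) - max(abs(cuts), 0.2)
  hi <- max(centers + 9 * sds) + max(abs(cuts), 0.2)
  x <- seq(lo, hi, length.out = grid_size)
  h <- x[2] - x[1]
  lp <- plogis(x, log.p = TRUE)        # log p
  l1p <- plogis(-x, log.p = TRUE)      # log (1 - p)
  lpr <- dnorm(x, prior$mean, prior$sd, log = TRUE)

  norm_post <- function(e, n) {
    ll <- outer(lp, e) + outer(l1p, n - e) + lpr
    ll <- exp(sweep(ll, 2, apply(ll, 2, max), "-"))
    sweep(ll, 2, colSums(ll), "/")
  }
  Pc <- norm_post(ec, nc)
  Pt <- norm_post(et, nt)
  # mid-cell CDF of the treatment-arm posterior on the grid
  Ft <- apply(Pt, 2, cumsum) - Pt / 2
  if (D == 1) Ft <- matrix(Ft, ncol = 1)

  shift_cdf <- function(cut) {
    # F_t evaluated at x_j + cut via linear interpolation on the grid
    s <- cut / h
    j0 <- floor(s)
    frac <- s - j0
    idx <- seq_len(grid_size)
    take <- function(off) {
      jj <- idx + off
      out <- matrix(0, grid_size, D)
      inside <- jj >= 1 & jj <= grid_size
      out[inside, ] <- Ft[jj[inside], , drop = FALSE]
      out[jj > grid_size, ] <- 1
      out
    }
    (1 - frac) * take(j0) + frac * take(j0 + 1)
  }
  less <- vapply(cuts, function(cc) colSums(Pc * shift_cdf(cc)), numeric(D))
  less <- matrix(pmin(pmax(less, 0), 1), nrow = D)
  mean_b1 <- colSums(Pt * x) - colSums(Pc * x)
  list(less = less, mean_b1 = mean_b1)
}

# independence-chain Metropolis sampler for one arm's log-odds posterior
.arm_mcmc <- function(e, n, prior, n_iter, burn = 500) {
  apx <- .arm_post_approx(e, n, prior)
  psd <- 1.4 * apx$sd
  prop <- rnorm(n_iter + burn, apx$center, psd)
  logpost <- dnorm(prop, prior$mean, prior$sd, log = TRUE) +
    e * plogis(prop, log.p = TRUE) + (n - e) * plogis(-prop, log.p = TRUE)
  logq <- dnorm(prop, apx$center, psd, log = TRUE)
  lw <- logpost - logq
  lu <- log(runif(n_iter + burn))
  draws <- numeric(n_iter + burn)
  cur <- apx$center
  curw <- dnorm(cur, prior$mean, prior$sd, log = TRUE) +
    e * plogis(cur, log.p = TRUE) + (n - e) * plogis(-cur, log.p = TRUE) -
    dnorm(cur, apx$center, psd, log = TRUE)
  for (i in seq_along(draws)) {
    if (lu[i] < lw[i] - curw) {
      cur <- prop[i]
      curw <- lw[i]
    }
    draws[i] <- cur
  }
  draws[(burn + 1):(burn + n_iter)]
}

#' Posterior summary of the odds ratio at an interim
#'
#' Computes tail probabilities of the odds ratio under independent normal
#' priors on each arm's log-odds and binomial likelihoods. The default
#' method is deterministic quadrature: each arm's one-dimensional log-odds
#' posterior is evaluated on a shared uniform grid and the odds-ratio tails
#' are obtained by discrete convolution. `method = "mcmc"` runs an
#' independence-chain Metropolis sampler per arm instead and is intended for
#' validation of the quadrature, not for production simulation.
#'
#' @inheritParams fit_interim
#' @param prior A [bayes_prior()].
#' @param method `"grid"` (deterministic quadrature) or `"mcmc"`.
#' @param margin Odds-ratio futility margin; tails are reported at `margin`
#'   and `1 / margin`.
#' @param grid_size Number of grid nodes (grid method).
#' @param n_iter Posterior draws per arm (mcmc method).
#' @return An object of class `posterior_summary` with elements `pr_or_less_1`,
#'   `pr_or_greater_1`, `pr_or_less_margin`, `pr_or_greater_invmargin`,
#'   `mean_log_or`, `margin`, `method`.
#' @export
#' @examples
#' posterior_summary(100, 300, 80, 300)
posterior_summary <- function(control_events, control_n, treat_events, treat_n,
                              prior = bayes_prior(),
                              method = c("grid", "mcmc"), margin = 0.85,
                              grid_size = 1025, n_iter = 50000) {
  method <- match.arg(method)
  stopifnot(inherits(prior, "bayes_prior"))
  if (any(c(control_events, treat_events) < 0) || control_events > control_n ||
      treat_events > treat_n)
    stop("invalid counts: need 0 <= events <= n in both arms")
  cuts <- c(0, log(margin), -log(margin))
  if (method == "grid") {
    res <- .or_tail_batch(control_events, control_n, treat_events, treat_n,
                          prior, cuts, grid_size)
    less <- res$less[1, ]
    mean_b1 <- res$mean_b1[1]
  } else {
    thc <- .arm_mcmc(control_events, control_n, prior, n_iter)
    tht <- .arm_mcmc(treat_events, treat_n, prior, n_iter)
    b1 <- tht - thc
    less <- vapply(cuts, function(cc) mean(b1 < cc), 0)
    mean_b1 <- mean(b1)
  }
  structure(
    list(pr_or_less_1 = less[1], pr_or_greater_1 = 1 - less[1],
         pr_or_less_margin = less[2], pr_or_greater_invmargin = 1 - less[3],
         mean_log_or = mean_b1, margin = margin, method = method),
    class = "posterior_summary"
  )
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior odds-ratio summary (%s):\n", x$method))
  cat(sprintf("  Pr(OR < 1) = %.4f, Pr(OR > 1) = %.4f\n",
              x$pr_or_less_1, x$pr_or_greater_1))
  cat(sprintf("  Pr(OR < %.3g) = %.4f, Pr(OR > %.3g) = %.4f\n",
              x$margin, x$pr_or_less_margin, 1 / x$margin,
              x$pr_or_greater_invmargin))
  cat(sprintf("  posterior mean log-OR = %.4f\n", x$mean_log_or))
  invisible(x)
}

#' Posterior-probability (PostP) stopping decision
#'
#' @param post A [posterior_summary()].
#' @param thresholds A [bayes_thresholds()].
#' @param is_final Is this the final analysis? At the final look the
#'   efficacy criterion alone classifies success or failure.
#' @return One of `"stop_efficacy"`, `"stop_futility"`, `"continue"`,
#'   `"final_reject"`, `"final_accept"`.
#' @export
postp_decision <- function(post, thresholds = bayes_thresholds(),
                           is_final = FALSE) {
  stopifnot(inherits(post, "posterior_summary"),
            inherits(thresholds, "bayes_thresholds"))
  eff <- max(post$pr_or_less_1, post$pr_or_greater_1) > thresholds$efficacy
  if (is_final) return(if (eff) "final_reject" else "final_accept")
  if (eff) return("stop_efficacy")
  if (post$pr_or_less_margin < thresholds$futility_prob &&
      post$pr_or_greater_invmargin < thresholds$futility_prob)
    return("stop_futility")
  "continue"
}

#' Predictive probability of final-analysis success
#'
#' Probability, under the posterior predictive distribution of the remaining
#' patients' outcomes, that the completed trial meets the final-analysis
#' success criterion: posterior `max(Pr(OR < 1), Pr(OR > 1))` above the
#' efficacy threshold. When the remaining outcomes per arm are at most
#' `enum_limit` the predictive distribution is enumerated exactly; otherwise
#' a Monte-Carlo estimate over `n_draws` posterior-predictive datasets is
#' returned (deterministic given the RNG state).
#'
#' @inheritParams posterior_summary
#' @param control_remaining,treat_remaining Remaining patients per arm.
#' @param success_threshold Posterior probability defining final success.
#' @param n_draws Monte-Carlo draws.
#' @param enum_limit Per-arm remaining-count bound below which exact
#'   enumeration is used.
#' @return The predictive probability, with attributes `method`
#'   (`"enumeration"` or `"monte-carlo"`) and `se` (MC standard error, 0 for
#'   enumeration).
#' @export
predictive_probability <- function(control_events, control_n, treat_events,
                                   treat_n, control_remaining, treat_remaining,
                                   prior = bayes_prior(),
                                   success_threshold = 0.99, n_draws = 500,
                                   enum_limit = 12, grid_size = 257) {
  if (control_remaining < 0 || treat_remaining < 0)
    stop("remaining counts must be >= 0")
  mc <- control_remaining; mt <- treat_remaining
  ncf <- control_n + mc; ntf <- treat_n + mt

  success <- function(ecf, etf) {
    less <- .or_tail_batch(ecf, ncf, etf, ntf, prior, 0, grid_size)$less[, 1]
    pmax(less, 1 - less) > success_threshold
  }

  if (mc == 0 && mt == 0) {
    pp <- as.numeric(success(control_events, treat_events))
    return(structure(pp, method = "none-remaining", se = 0))
  }

  # current-data posterior of each arm on its own grid
  arm_grid <- function(e, n) {
    apx <- .arm_post_approx(e, n, prior)
    x <- seq(apx$center - 9 * apx$sd, apx$center + 9 * apx$sd,
             length.out = grid_size)
    d <- dnorm(x, prior$mean, prior$sd, log = TRUE) +
      e * plogis(x, log.p = TRUE) + (n - e) * plogis(-x, log.p = TRUE)
    d <- exp(d - max(d))
    list(x = x, p = d / sum(d))
  }
  gc_ <- arm_grid(control_events, control_n)
  gt_ <- arm_grid(treat_events, treat_n)

  if (mc <= enum_limit && mt <= enum_limit) {
    qc <- as.vector(outer(0:mc, gc_$x, function(j, th) dbinom(j, mc, plogis(th))) %*% gc_$p)
    qt <- as.vector(outer(0:mt, gt_$x, function(j, th) dbinom(j, mt, plogis(th))) %*% gt_$p)
    combos <- expand.grid(jc = 0:mc, jt = 0:mt)
    S <- success(control_events + combos$jc, treat_events + combos$jt)
    Smat <- matrix(S, nrow = mc + 1, ncol = mt + 1)
    pp <- as.numeric(t(qc) %*% Smat %*% qt)
    return(structure(pp, method = "enumeration", se = 0))
  }

  draw_arm <- function(g, m) {
    idx <- sample.int(length(g$x), n_draws, replace = TRUE, prob = g$p)
    th <- g$x[idx] + runif(n_draws, -0.5, 0.5) * (g$x[2] - g$x[1])
    rbinom(n_draws, m, plogis(th))
  }
  ec_f <- control_events + if (mc > 0) draw_arm(gc_, mc) else 0L
  et_f <- treat_events + if (mt > 0) draw_arm(gt_, mt) else 0L
  S <- success(ec_f, et_f)
  pp <- mean(S)
  structure(pp, method = "monte-carlo", se = sqrt(pp * (1 - pp) / n_draws))
}

#' Predictive-probability (PredP) stopping decision
#'
#' @param pp Predictive probability of final success, in `[0, 1]`.
#' @param thresholds A [bayes_thresholds()].
#' @return `"stop_efficacy"` if `pp >= predp_high`, `"stop_futility"` if
#'   `pp <= predp_low`, otherwise `"continue"`.
#' @export
predp_decision <- function(pp, thresholds = bayes_thresholds()) {
  stopifnot(inherits(thresholds, "bayes_thresholds"))
  pp <- as.numeric(pp)
  if (is.na(pp) || pp < 0 || pp > 1) stop("`pp` must lie in [0, 1]")
  if (pp >= thresholds$predp_high) return("stop_efficacy")
  if (pp <= thresholds$predp_low) return("stop_futility")
  "continue"
}
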