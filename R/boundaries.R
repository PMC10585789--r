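# Boundary solving by recursive numerical integration of the sequential
# z-statistic (Cov(Z_j, Z_k) = sqrt(t_j / t_k)). The recursion carries the
# sub-density of (Z_k, trial still running) on a Gauss-Legendre grid over the
# continuation region of each stage; stage-to-stage transition kernels and
# tail crossing probabilities are Gaussian and evaluated in closed form.

new_boundary_set <- function(t, u, l, alpha_spent, beta_spent, drift, spec,
                             grid_size) {
  structure(
    list(t = t, u = u, l = l, alpha_spent = alpha_spent,
         beta_spent = beta_spent, drift = drift, spec = spec,
         grid_size = grid_size),
    class = "boundary_set"
  )
}

# stage-1 tail: Z_1 ~ N(theta * sqrt(t1), 1)
.gs_stage1_tail <- function(c, t1, theta, lower) {
  pnorm(c, mean = theta * sqrt(t1), lower.tail = lower)
}

# P(Z_k >=/<= c, continued through stage k-1) from the stored sub-density
.gs_cross <- function(state, tk, tk1, theta, c, lower) {
  dt <- tk - tk1
  z <- (c * sqrt(tk) - state$x * sqrt(tk1) - theta * dt) / sqrt(dt)
  sum(state$w * state$d * pnorm(z, lower.tail = lower))
}

# propagate the sub-density onto a Gauss-Legendre grid over (a, b) at stage k
.gs_advance <- function(state, tk, tk1, theta, a, b, grid_size) {
  gl <- pracma::gaussLegendre(grid_size, a, b)
  if (is.null(state)) {
    d <- dnorm(gl$x, mean = theta * sqrt(tk))
  } else {
    dt <- tk - tk1
    kern <- outer(gl$x * sqrt(tk), state$x * sqrt(tk1),
                  function(y, x) dnorm((y - x - theta * dt) / sqrt(dt)))
    d <- as.vector(kern %*% (state$w * state$d)) * sqrt(tk) / sqrt(dt)
  }
  list(x = gl$x, w = gl$w, d = d)
}

# One full boundary pass for a given design drift. Efficacy bounds are
# symmetric +/-u_k solved under the null so that the cumulative two-sided
# crossing probability (with binding truncation by earlier continuation
# regions, efficacy checked before futility) equals the alpha spend at t_k;
# futility bounds l_k are solved under `theta` so that cumulative
# benefit-direction futility crossing equals the beta spend.
.gs_pass <- function(t_all, pa, pb, theta, futility, grid_size) {
  m <- length(t_all)
  u <- numeric(m)
  l <- if (futility) rep(NA_real_, m) else NULL
  s0 <- s1 <- NULL
  for (k in seq_len(m)) {
    tk <- t_all[k]
    tk1 <- if (k == 1) 0 else t_all[k - 1]
    eff_p <- function(uu) {
      if (k == 1) {
        .gs_stage1_tail(uu, tk, 0, FALSE) + .gs_stage1_tail(-uu, tk, 0, TRUE)
      } else {
        .gs_cross(s0, tk, tk1, 0, uu, FALSE) + .gs_cross(s0, tk, tk1, 0, -uu, TRUE)
      }
    }
    if (pa[k] <= 0) {
      u[k] <- 12
    } else if (eff_p(0.05) <= pa[k]) {
      # continuation mass exhausted (extreme drift during calibration)
      u[k] <- 0.05
    } else {
      u[k] <- uniroot(function(uu) eff_p(uu) - pa[k], c(0.05, 12),
                      tol = 1e-9, maxiter = 200)$root
    }
    if (futility) {
      fut_p <- function(ll) {
        if (k == 1) {
          .gs_stage1_tail(ll, tk, theta, TRUE) - .gs_stage1_tail(-u[k], tk, theta, TRUE)
        } else {
          .gs_cross(s1, tk, tk1, theta, ll, TRUE) - .gs_cross(s1, tk, tk1, theta, -u[k], TRUE)
        }
      }
      if (pb[k] <= 0) {
        l[k] <- -u[k]
      } else if (fut_p(u[k]) < pb[k]) {
        # cannot spend the full beta increment below u_k: boundaries cross
        l[k] <- u[k] + 1
      } else {
        l[k] <- uniroot(function(ll) fut_p(ll) - pb[k], c(-u[k] + 1e-9, u[k]),
                        tol = 1e-9, maxiter = 200)$root
      }
    }
    if (k < m) {
      a <- if (futility) max(l[k], -u[k]) else -u[k]
      b <- u[k]
      # boundaries already crossed at an interim: the candidate drift is too
      # large; signal a negative gap so the calibration backs off
      if (a >= b) return(list(u = u, l = l, gap = -2))
      s0 <- .gs_advance(s0, tk, tk1, 0, a, b, grid_size)
      s1 <- if (futility) .gs_advance(s1, tk, tk1, theta, a, b, grid_size) else NULL
    }
  }
  list(u = u, l = l, gap = if (futility) u[m] - l[m] else NA_real_)
}

#' Haybittle-Peto boundaries
#'
#' Fixed interim critical values of 3 on the absolute z-scale, with 1.96 at
#' the final analysis and no futility monitoring.
#'
#' @param n_interims Number of interim analyses `K >= 0`.
#' @param alpha Two-sided significance level of the final test (final
#'   critical value `qnorm(1 - alpha / 2)`, 1.96 at the default 0.05).
#' @param interim_value Fixed interim critical value (default 3).
#' @return A `boundary_set`.
#' @export
#' @examples
#' hp_boundaries(2) # u = 3, 3, 1.96
hp_boundaries <- function(n_interims, alpha = 0.05, interim_value = 3) {
  n_interims <- as.integer(n_interims)
  if (is.na(n_interims) || n_interims < 0) stop("`n_interims` must be >= 0")
  t_all <- c(information_schedule(n_interims), 1)
  u <- c(rep(interim_value, n_interims), qnorm(1 - alpha / 2))
  spec <- spending_spec("HP", alpha = alpha, futility = FALSE)
  new_boundary_set(t_all, u, NULL, alpha_spent = rep(NA_real_, length(t_all)),
                   beta_spent = NULL, drift = NA_real_, spec = spec,
                   grid_size = NA_integer_)
}

#' Solve error-spending group-sequential boundaries
#'
#' Computes per-stage efficacy critical values `u_k` (symmetric `+/-u_k` on
#' the z-scale) and, when the spec monitors futility, binding
#' benefit-direction futility values `l_k`, by recursive numerical
#' integration of the correlated z-statistic path.
#'
#' Efficacy values satisfy, under the null, cumulative two-sided crossing
#' probability equal to the alpha-spending function at each stage, with
#' earlier continuation regions truncated by the binding futility bounds
#' (efficacy is checked before futility, so the harm-direction tail
#' `Z <= -u_k` counts as a rejection). Futility values spend the
#' beta-spending function under the design drift `theta` (the expected
#' z-statistic at full information under the design alternative), and
#' `theta` itself is calibrated by root finding so that the efficacy and
#' futility boundaries meet at the final analysis; total power at the design
#' drift is then exactly `1 - beta`.
#'
#' @param spec A [spending_spec()] with family `"OBF"` or `"HSD"`.
#' @param schedule Strictly increasing interim information fractions in
#'   (0, 1); the final analysis at `t = 1` is appended automatically.
#' @param grid_size Gauss-Legendre nodes per stage for the recursion.
#' @param drift_interval Search bracket for the design drift calibration.
#' @return A `boundary_set` with stage fractions `t` (including 1), efficacy
#'   values `u`, futility values `l` (`NULL` without futility), cumulative
#'   alpha/beta spent, and the calibrated design drift.
#' @export
#' @examples
#' \donttest{
#' b <- solve_boundaries(spending_spec("OBF"), information_schedule(4))
#' as.data.frame(b)
#' }
solve_boundaries <- function(spec, schedule = information_schedule(1),
                             grid_size = 512, drift_interval = c(1.2, 5.5)) {
  stopifnot(inherits(spec, "spending_spec"))
  if (spec$family == "HP")
    stop("use hp_boundaries() for the Haybittle-Peto design")
  if (length(schedule) > 0) {
    if (any(diff(schedule) <= 0)) stop("`schedule` must be strictly increasing")
    if (any(schedule <= 0 | schedule >= 1)) stop("`schedule` must lie strictly in (0, 1)")
  }
  t_all <- c(schedule, 1)
  m <- length(t_all)
  ca <- spend(spec, t_all, "alpha")
  pa <- diff(c(0, ca))
  futility <- spec$futility && m > 1
  cb <- if (futility) spend(spec, t_all, "beta") else NULL
  pb <- if (futility) diff(c(0, cb)) else NULL

  if (!futility) {
    pass <- .gs_pass(t_all, pa, pb = NULL, theta = 0, futility = FALSE,
                     grid_size = grid_size)
    # drift giving power 1 - beta against the efficacy bounds (benefit side)
    bs <- new_boundary_set(t_all, pass$u, NULL, ca, NULL, NA_real_, spec, grid_size)
    pow <- function(th) sum(exit_probabilities(bs, th)$efficacy) - (1 - spec$beta)
    bs$drift <- uniroot(pow, drift_interval, tol = 1e-7, extendInt = "upX")$root
    return(bs)
  }

  gap <- function(th) .gs_pass(t_all, pa, pb, th, TRUE, grid_size)$gap
  lo <- drift_interval[1]; hi <- drift_interval[2]
  glo <- gap(lo); ghi <- gap(hi)
  if (glo * ghi > 0)
    stop("boundary solver: drift calibration failed to bracket a root ",
         sprintf("(gap %.3g at %.2f, %.3g at %.2f)", glo, lo, ghi, hi))
  theta <- uniroot(gap, c(lo, hi), f.lower = glo, f.upper = ghi,
                   tol = 1e-7, maxiter = 200)$root
  pass <- .gs_pass(t_all, pa, pb, theta, TRUE, grid_size)
  # enforce the meet exactly at the final look
  meet <- (pass$u[m] + pass$l[m]) / 2
  pass$u[m] <- pass$l[m] <- meet
  new_boundary_set(t_all, pass$u, pass$l, ca, cb, theta, spec, grid_size)
}

#' Per-stage exit probabilities of a boundary set under a given drift
#'
#' Evaluates, by the same recursive integration used to solve the
#' boundaries, the probability of stopping for efficacy (two-sided crossing,
#' efficacy checked first) and futility at each stage when the true drift of
#' the z-statistic at full information is `drift`.
#'
#' @param bounds A `boundary_set`.
#' @param drift Expected z-statistic at `t = 1` (benefit-positive).
#' @param grid_size Gauss-Legendre nodes per stage.
#' @return A data frame with columns `stage`, `t`, `efficacy`, `futility`,
#'   with the final-stage acceptance probability in attribute `"accept"`;
#'   all probabilities sum to one.
#' @export
#' @examples
#' ep <- exit_probabilities(hp_boundaries(2), drift = 0)
#' sum(ep$efficacy) # ~0.052
exit_probabilities <- function(bounds, drift = 0, grid_size = 512) {
  stopifnot(inherits(bounds, "boundary_set"))
  t_all <- bounds$t
  u <- bounds$u
  l <- bounds$l
  m <- length(t_all)
  eff <- fut <- numeric(m)
  s <- NULL
  for (k in seq_len(m)) {
    tk <- t_all[k]
    tk1 <- if (k == 1) 0 else t_all[k - 1]
    if (k == 1) {
      eff[k] <- .gs_stage1_tail(u[k], tk, drift, FALSE) +
        .gs_stage1_tail(-u[k], tk, drift, TRUE)
      if (!is.null(l) && k < m)
        fut[k] <- max(0, .gs_stage1_tail(min(l[k], u[k]), tk, drift, TRUE) -
                        .gs_stage1_tail(-u[k], tk, drift, TRUE))
    } else {
      eff[k] <- .gs_cross(s, tk, tk1, drift, u[k], FALSE) +
        .gs_cross(s, tk, tk1, drift, -u[k], TRUE)
      if (!is.null(l) && k < m)
        fut[k] <- max(0, .gs_cross(s, tk, tk1, drift, min(l[k], u[k]), TRUE) -
                        .gs_cross(s, tk, tk1, drift, -u[k], TRUE))
    }
    if (k < m) {
      a <- if (!is.null(l)) max(l[k], -u[k]) else -u[k]
      s <- .gs_advance(s, tk, tk1, drift, a, u[k], grid_size)
    }
  }
  out <- data.frame(stage = seq_len(m), t = t_all, efficacy = eff, futility = fut)
  attr(out, "accept") <- max(0, 1 - sum(eff) - sum(fut))
  attr(out, "drift") <- drift
  out
}

#' @export
as.data.frame.boundary_set <- function(x, ...) {
  m <- length(x$t)
  data.frame(
    stage = seq_len(m),
    t = x$t,
    efficacy_z = x$u,
    futility_z = if (is.null(x$l)) rep(NA_real_, m) else x$l,
    cum_alpha_spent = x$alpha_spent,
    cum_beta_spent = if (is.null(x$beta_spent)) rep(NA_real_, m) else x$beta_spent
  )
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("Group-sequential boundary set (%s): %d interim(s) + final\n",
              x$spec$family, length(x$t) - 1))
  if (!is.na(x$drift)) cat(sprintf("  design drift %.4f\n", x$drift))
  print(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
plot.boundary_set <- function(x, ...) {
  df <- as.data.frame(x)
  ylim <- range(c(df$efficacy_z, df$futility_z, 0), na.rm = TRUE)
  plot(df$t, df$efficacy_z, type = "b", pch = 16, ylim = ylim,
       xlab = "information fraction", ylab = "critical value (z-scale)",
       main = sprintf("%s boundaries", x$spec$family), ...)
  if (!is.null(x$l)) {
    graphics::lines(df$t, df$futility_z, type = "b", pch = 1, lty = 2)
    graphics::legend("topright", legend = c("efficacy", "futility"),
                     lty = c(1, 2), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}
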