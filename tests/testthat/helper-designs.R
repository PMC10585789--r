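# Shared lazily-solved boundary sets (solving OBF/HSD designs is the
# expensive step; each design x schedule is solved once per test run).
.design_cache <- new.env(parent = emptyenv())

cached_bounds <- function(family, n_interims, grid_size = 512) {
  key <- paste(family, n_interims, grid_size, sep = "_")
  if (is.null(.design_cache[[key]])) {
    .design_cache[[key]] <- solve_boundaries(
      spending_spec(family),
      information_schedule(n_interims),
      grid_size = grid_size
    )
  }
  .design_cache[[key]]
}

# Monte-Carlo simulation of the correlated sequential z-statistic path,
# independent of the package's recursive-integration code: increments of
# the underlying Brownian-motion score process are plain normal draws.
simulate_z_paths <- function(t_all, drift, n_paths) {
  m <- length(t_all)
  dt <- diff(c(0, t_all))
  S <- matrix(0, n_paths, m)
  acc <- rep(0, n_paths)
  for (k in seq_len(m)) {
    acc <- acc + rnorm(n_paths, mean = drift * dt[k], sd = sqrt(dt[k]))
    S[, k] <- acc
  }
  sweep(S, 2, sqrt(t_all), "/")
}

# Apply group-sequential decisions to simulated z paths (efficacy first,
# binding futility), returning per-stage exit fractions.
mc_exit_fractions <- function(z, u, l = NULL) {
  m <- ncol(z)
  n <- nrow(z)
  stopped <- rep(FALSE, n)
  eff <- fut <- numeric(m)
  for (k in seq_len(m)) {
    hit_e <- !stopped & abs(z[, k]) >= u[k]
    hit_f <- if (!is.null(l) && k < m) !stopped & !hit_e & z[, k] <= l[k]
             else rep(FALSE, n)
    eff[k] <- mean(hit_e)
    fut[k] <- mean(hit_f)
    stopped <- stopped | hit_e | hit_f
  }
  list(efficacy = eff, futility = fut)
}
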