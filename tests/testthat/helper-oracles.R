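# Independent oracles used by the property tests. Each is a deliberately
# naive implementation kept separate from the package code paths it checks.

# Bare pixel matrix of a channel image (drops class and label attribute).
px <- function(img) {
  m <- unclass(img)
  attr(m, "channel_label") <- NULL
  m
}

# Brute-force 3x3 mean filter: double loop over the in-bounds neighborhood.
brute_mean_filter3 <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0; n <- 0
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        acc <- acc + mat[rr, cc]; n <- n + 1
      }
    }
    out[r, c] <- acc / n
  }
  out
}

# Closed-form OLS via the normal equations on (t in minutes, y).
normal_equations_slope <- function(time_s, y) {
  t_min <- time_s / 60
  X <- cbind(1, t_min)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(slope_per_min = beta[2], intercept = beta[1],
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Explicit-Euler integration of the pool ODE at a fine step, using the
# package's flux definitions only through finite evaluation of the model
# right-hand side via integrate_pool's public flux semantics is NOT allowed
# here; instead the fluxes are re-derived from first principles for the
# standard hypoxia schedule (WT preset, no treatment).
euler_pool_wt <- function(model, schedule, t_end, dt = 0.1) {
  ph <- schedule$phases
  o2_at <- function(t) ph$o2_percent[findInterval(pmin(pmax(t, ph$start_s[1]),
                                                       ph$end_s[nrow(ph)] - 1e-9),
                                                  ph$start_s)]
  hyp_start <- ph$start_s[ph$o2_percent < 1][1]
  reox_start <- NA
  for (i in 2:nrow(ph))
    if (ph$o2_percent[i - 1] < 1 && ph$o2_percent[i] >= 5) reox_start <- ph$start_s[i]
  vox <- function(t) {
    b <- if (!is.na(reox_start) && t >= reox_start)
      model$burst_A * exp(-(t - reox_start) / model$tau_burst) else 0
    o2 <- o2_at(t)
    model$k_ero * o2 / (o2 + model$K_O2) + b
  }
  vred <- function(t) {
    cf <- if (o2_at(t) < 1) exp(-(t - hyp_start) / model$tau_pep) else 1
    model$k_pep * cf + model$k_gsh
  }
  times <- seq(0, t_end, by = dt)
  x <- numeric(length(times))
  x[1] <- vox(0) / (vox(0) + vred(0))
  for (i in seq_len(length(times) - 1)) {
    t <- times[i]
    x[i + 1] <- x[i] + dt * (vox(t) * (1 - x[i]) - vred(t) * x[i])
  }
  data.frame(time_s = times, x = x)
}

# Brute-force root finding of the Nernst relation for the glutathione
# partition: solve E(gssg) = E_target for gssg by bisection.
partition_by_rootfinding <- function(E_mV, gsh_molar, E0 = -240,
                                     const = physical_constants()) {
  s <- const$gas_constant * const$temperature_K / (2 * const$faraday) * 1000
  f <- function(gssg) E0 - s * log(gsh_molar^2 / gssg) - E_mV
  gssg <- uniroot(f, c(1e-30, 1e6), tol = 1e-15)$root
  list(gssg_molar = gssg, ratio = gsh_molar / gssg)
}

# Default schedule and a rolling mean used by trace signature checks.
roll_mean <- function(y, k = 15) as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))

mean_trace <- function(sim) mean_log_ratio_trace(correct_and_ratio(sim$traces))
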