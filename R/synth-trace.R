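# Minimal ODE model of luminal glutathione-pool redox dynamics under
# hypoxia-reoxygenation schedules, emitting biosensor fluorescence traces
# with ground truth.
#
# State: x(t) in [0, 1], oxidized fraction of the luminal
# glutathione-equivalent pool. Dynamics:
#   dx/dt = v_ox(t) (1 - x) - v_red(t) x
#   v_ox  = k_ero * gf * O2/(O2 + K_O2) + gf * A exp(-(t - t_reox)/tau_burst)
#   v_red = k_pep * cf(t) + k_gsh * bf(t) + k_dtt * [DTT](t)
# gf is the genotype scale on oxidizing (ERO-derived) fluxes; cf models the
# nascent-peptide reducing flux (1 under normoxia, decaying with tau_pep
# during hypoxia as translation slows, 0 under cycloheximide); bf models the
# glutathione-import flux (exp(-t/tau_BSO) under BSO). The pool maps to a
# potential via [GSH] = (1-x) G_tot, [GSSG] = x G_tot / 2, and the sensor is
# assumed at thermodynamic equilibrium with that potential.

#' Kinetic model of luminal redox dynamics
#'
#' Parameters of the single-pool two-flux model (see the package vignette for
#' the rationale behind each default). All rates are per second. With
#' `k_ero = NULL` the maximal ERO oxidation rate is calibrated in closed form
#' so that the wild-type steady state at `calibrate_o2` percent oxygen sits at
#' `calibrate_E_mV` (default -241 mV).
#'
#' @param k_ero Maximal ERO oxidation rate (1/s), or `NULL` to calibrate.
#' @param K_O2 Oxygen half-saturation of the ERO flux, in percent O2.
#' @param k_pep Nascent-peptide reducing flux (1/s).
#' @param k_gsh Glutathione-import reducing flux (1/s).
#' @param burst_A Amplitude of the re-oxygenation oxidation burst (1/s).
#' @param tau_burst Burst decay time (s).
#' @param burst_gf_min Genotype-factor threshold below which no burst is
#'   generated: the effective burst amplitude is
#'   `burst_A * max(0, (gf - burst_gf_min) / (1 - burst_gf_min))`, encoding
#'   that mutants with little residual ERO capacity show a monotone
#'   re-oxygenation recovery without a transient peak, while single
#'   knockdowns still burst.
#' @param tau_pep Decay time of the peptide flux during hypoxia (s).
#' @param tau_BSO Decay time of the glutathione flux under BSO (s).
#' @param k_dtt Reducing flux per micromolar perfused DTT (1/s/uM).
#' @param G_tot Pool size in mol/L glutathione equivalents.
#' @param couple_midpoint_mV GSSG/2GSH couple midpoint (mV).
#' @param genotype_factors Named vector of genotype scale factors gf.
#' @param calibrate_E_mV,calibrate_o2 Calibration target for `k_ero`.
#' @param sensor A [sensor_spec()] coupled at equilibrium.
#' @param const A [physical_constants()].
#' @return An object of class `kinetic_model` (with `k_ero` filled in).
#' @export
kinetic_model <- function(k_ero = NULL, K_O2 = 1, k_pep = 1.4e-3,
                          k_gsh = 2e-4, burst_A = 2e-5, tau_burst = 600,
                          burst_gf_min = 0.2,
                          tau_pep = 3000, tau_BSO = 14400, k_dtt = 4e-5,
                          G_tot = 2.5e-3, couple_midpoint_mV = -240,
                          genotype_factors = c("WT" = 1, "ero1" = 0.6,
                                               "amiERO2" = 0.5,
                                               "ero1 ero2" = 0.15),
                          calibrate_E_mV = -241, calibrate_o2 = 20,
                          sensor = sensor_rogfp2il(),
                          const = physical_constants()) {
  rates <- c(K_O2, k_pep, k_gsh, burst_A, tau_burst, tau_pep, tau_BSO, k_dtt)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  m <- structure(list(k_ero = k_ero, K_O2 = K_O2, k_pep = k_pep,
                      k_gsh = k_gsh, burst_A = burst_A,
                      tau_burst = tau_burst, burst_gf_min = burst_gf_min,
                      tau_pep = tau_pep,
                      tau_BSO = tau_BSO, k_dtt = k_dtt, G_tot = G_tot,
                      couple_midpoint_mV = couple_midpoint_mV,
                      genotype_factors = genotype_factors,
                      sensor = sensor, const = const),
                 class = "kinetic_model")
  if (is.null(k_ero)) {
    xs <- pool_oxidation_at_potential(calibrate_E_mV, m)
    o2f <- calibrate_o2 / (calibrate_o2 + K_O2)
    m$k_ero <- xs / (1 - xs) * (k_pep + k_gsh) / o2f
  }
  m
}

# Pool oxidized fraction whose implied potential equals E (closed form:
# 2 G (1-x)^2 / x = exp((E0' - E)/s), the smaller quadratic root).
pool_oxidation_at_potential <- function(E_mV, model) {
  s <- nernst_slope_mV(model$const, 2)
  mass <- exp((model$couple_midpoint_mV - E_mV) / s)
  G2 <- 2 * model$G_tot
  b <- 2 * G2 + mass
  (b - sqrt(b^2 - 4 * G2^2)) / (2 * G2)
}

#' Potential and sensor oxidation implied by a pool state
#'
#' @param x Pool oxidized fraction in (0, 1).
#' @param model A [kinetic_model()].
#' @return List with `E_mV` and sensor `oxd`.
#' @export
pool_to_sensor <- function(x, model) {
  x <- pmin(1 - 1e-12, pmax(1e-12, x))
  E <- potential_from_pool((1 - x) * model$G_tot, x * model$G_tot / 2,
                           model$couple_midpoint_mV, model$const)
  list(E_mV = E, oxd = oxd_from_potential(E, model$sensor, model$const))
}

# Environment lookup at (possibly dead-time shifted) time points
schedule_env <- function(t, schedule) {
  ph <- schedule$phases
  te <- pmax(t - schedule$dead_time_s, ph$start_s[1])
  te <- pmin(te, ph$end_s[nrow(ph)] - 1e-9)
  idx <- findInterval(te, ph$start_s)
  list(o2 = ph$o2_percent[idx], dtt = ph$dtt_uM[idx],
       phase_start = ph$start_s[idx], t_eff = te)
}

# Vectorized fluxes of the kinetic model at times t
pool_fluxes <- function(t, schedule, model, gf, treatment = "none") {
  env <- schedule_env(t, schedule)
  hypoxic <- env$o2 < 1
  cf <- ifelse(hypoxic, exp(-(env$t_eff - env$phase_start) / model$tau_pep), 1)
  if (treatment == "CHX") cf <- cf * 0
  bf <- if (treatment == "BSO") exp(-env$t_eff / model$tau_BSO) else rep(1, length(t))
  # re-oxygenation bursts at every hypoxia -> normoxia transition
  ph <- schedule$phases
  burst <- numeric(length(t))
  burst_scale <- max(0, (gf - model$burst_gf_min) / (1 - model$burst_gf_min))
  if (nrow(ph) > 1 && model$burst_A > 0 && burst_scale > 0) {
    for (i in 2:nrow(ph)) {
      if (ph$o2_percent[i - 1] < 1 && ph$o2_percent[i] >= 5) {
        tr <- ph$start_s[i]
        on <- env$t_eff >= tr
        burst[on] <- burst[on] + model$burst_A * burst_scale *
          exp(-(env$t_eff[on] - tr) / model$tau_burst)
      }
    }
  }
  v_ox <- model$k_ero * gf * env$o2 / (env$o2 + model$K_O2) + burst
  v_red <- model$k_pep * cf + model$k_gsh * bf + model$k_dtt * env$dtt
  list(v_ox = v_ox, v_red = v_red)
}

#' Integrate the luminal pool ODE
#'
#' Classical fixed-step fourth-order Runge-Kutta on
#' `dx/dt = v_ox(t)(1 - x) - v_red(t) x`, with the initial state at the
#' steady state of the fluxes at t = 0.
#'
#' @param schedule A [phase_schedule()].
#' @param model A [kinetic_model()].
#' @param gf Genotype scale factor (or a genotype name found in
#'   `model$genotype_factors`).
#' @param treatment `"none"`, `"CHX"` or `"BSO"`.
#' @param t_out Output time grid in seconds (defaults to 60 s sampling over
#'   the schedule).
#' @param dt Integration step in seconds.
#' @param x0 Initial pool oxidation; default `NULL` starts at the steady
#'   state of the fluxes at t = 0.
#' @return Data frame with `time_s`, `x`, `E_mV`, `oxd`.
#' @export
integrate_pool <- function(schedule, model = kinetic_model(), gf = 1,
                           treatment = c("none", "CHX", "BSO"),
                           t_out = NULL, dt = 1, x0 = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"),
            inherits(model, "kinetic_model"))
  treatment <- match.arg(treatment)
  if (is.character(gf)) {
    if (!gf %in% names(model$genotype_factors))
      stop("unknown genotype: ", gf)
    gf <- model$genotype_factors[[gf]]
  }
  ph <- schedule$phases
  t0 <- ph$start_s[1]; t1 <- ph$end_s[nrow(ph)]
  if (is.null(t_out)) t_out <- seq(t0, t1, by = 60)
  if (any(t_out < t0 | t_out > t1)) stop("t_out outside schedule span")
  n <- ceiling((t1 - t0) / dt)
  tgrid <- t0 + dt * seq(0, 2 * n) / 2          # dt/2 spacing for RK4 stages
  fl <- pool_fluxes(tgrid, schedule, model, gf, treatment)
  vox <- fl$v_ox; vred <- fl$v_red
  if (any(!is.finite(vox)) || any(!is.finite(vred)))
    stop(sprintf("non-finite fluxes (gf=%g, treatment=%s)", gf, treatment))
  x <- numeric(n + 1)
  x[1] <- if (is.null(x0)) vox[1] / (vox[1] + vred[1]) else x0
  for (i in seq_len(n)) {
    j <- 2 * i - 1                               # index of t in tgrid
    a1 <- vox[j]; r1 <- vred[j]
    a2 <- vox[j + 1]; r2 <- vred[j + 1]
    a3 <- vox[j + 2]; r3 <- vred[j + 2]
    xi <- x[i]
    k1 <- a1 * (1 - xi) - r1 * xi
    x2 <- xi + dt / 2 * k1
    k2 <- a2 * (1 - x2) - r2 * x2
    x3 <- xi + dt / 2 * k2
    k3 <- a2 * (1 - x3) - r2 * x3
    x4 <- xi + dt * k3
    k4 <- a3 * (1 - x4) - r3 * x4
    x[i + 1] <- min(1, max(0, xi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)))
  }
  tx <- t0 + dt * seq(0, n)
  xo <- stats::approx(tx, x, xout = t_out)$y
  ps <- pool_to_sensor(xo, model)
  data.frame(time_s = t_out, x = xo, E_mV = ps$E_mV, oxd = ps$oxd)
}

#' Simulate plate-reader fluorescence traces with ground truth
#'
#' Integrates the luminal pool model, couples the sensor at equilibrium, and
#' renders two-channel fluorescence per well using the spectral model:
#' sensor wells get a per-well brightness factor (leaf-disk variability),
#' blank wells of the same genotype carry autofluorescence only (constant
#' `1.2 * autofluor_level` in the 400-excited and `0.8 * autofluor_level` in
#' the 482-excited channel), so the per-genotype blank-mean subtraction of
#' [correct_and_ratio()] is exact on noiseless output.
#'
#' @param schedule A [phase_schedule()].
#' @param model A [kinetic_model()].
#' @param genotype Genotype name (must be in `model$genotype_factors`).
#' @param treatment `"none"`, `"CHX"` or `"BSO"`.
#' @param spectral A [spectral_model()] (set `noise = "none"` for noiseless
#'   traces).
#' @param n_wells,n_blanks Numbers of sensor and blank wells.
#' @param sample_interval_s Sampling interval of the plate reader.
#' @param brightness_cv Lognormal coefficient of variation of per-well sensor
#'   brightness.
#' @param seed Integer seed (mandatory).
#' @param dt Integration step.
#' @return List with `traces` (a [trace_set()]) and `truth` (data frame
#'   `time_s`, `x`, `E_mV`, `oxd`, `ratio`, `log10_ratio`, plus generator
#'   parameters as attributes).
#' @export
simulate_trace <- function(schedule = fig_hypoxia_schedule(),
                           model = kinetic_model(), genotype = "WT",
                           treatment = c("none", "CHX", "BSO"),
                           spectral = spectral_model(), n_wells = 8,
                           n_blanks = 3, sample_interval_s = 60,
                           brightness_cv = 0.15, seed, dt = 1) {
  treatment <- match.arg(treatment)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(spectral, "spectral_model"))
  set.seed(seed)
  ph <- schedule$phases
  t_out <- seq(ph$start_s[1], ph$end_s[nrow(ph)] - 1e-9, by = sample_interval_s)
  truth <- integrate_pool(schedule, model, gf = genotype,
                          treatment = treatment, t_out = t_out, dt = dt)
  truth$ratio <- ratio_from_oxd(truth$oxd, implied_calibration(spectral))
  truth$log10_ratio <- log10(truth$ratio)
  af400 <- 1.2 * spectral$autofluor_level
  af482 <- 0.8 * spectral$autofluor_level
  mix405 <- spectral$f405_red * (1 - truth$oxd) + spectral$f405_ox * truth$oxd
  mix488 <- spectral$f488_red * (1 - truth$oxd) + spectral$f488_ox * truth$oxd
  nt <- length(t_out)
  noisy <- function(x) {
    m <- apply_noise(matrix(x, ncol = 1), spectral)
    as.numeric(m)
  }
  rows <- list(); wells <- list()
  add_well <- function(id, blank, bw) {
    i400 <- if (blank) rep(af400, nt) else bw * mix405 + af400
    i482 <- if (blank) rep(af482, nt) else bw * mix488 + af482
    rows[[length(rows) + 1]] <<- data.frame(
      time_s = rep(t_out, 2), well_id = id,
      excitation = rep(c(400L, 482L), each = nt),
      intensity = c(noisy(i400), noisy(i482)))
    wells[[length(wells) + 1]] <<- data.frame(
      well_id = id, genotype = genotype, treatment = treatment,
      is_blank = blank)
  }
  bw <- stats::rlnorm(n_wells, meanlog = -brightness_cv^2 / 2, sdlog = brightness_cv)
  for (w in seq_len(n_wells)) add_well(sprintf("S%02d", w), FALSE, bw[w])
  for (b in seq_len(n_blanks)) add_well(sprintf("B%02d", b), TRUE, NA)
  attr(truth, "generator") <- list(seed = seed, genotype = genotype,
                                   treatment = treatment, model = model,
                                   spectral = spectral)
  list(traces = trace_set(do.call(rbind, rows), do.call(rbind, wells)),
       truth = truth)
}

#' Late-hypoxia slope of a log-ratio series
#'
#' OLS slope over the second half of the hypoxic phase -- the window in which
#' the gradual ERO-dependent re-oxidation dominates the trace.
#'
#' @param series Data frame with `time_s` and `log10_ratio`.
#' @param schedule A [phase_schedule()] with a phase named `hypoxia`.
#' @param hypoxia Phase name.
#' @return Slope in log10 ratio per minute.
#' @export
late_hypoxia_slope <- function(series, schedule, hypoxia = "hypoxia") {
  b <- phase_bounds(schedule, hypoxia)
  if (is.null(b)) stop("schedule has no phase named ", hypoxia)
  w <- c(mean(b), b[2])
  fit_slope(series$time_s, series$log10_ratio, w)$slope_per_min
}

#' Estimate the genotype factor from a measured trace
#'
#' Inverts the monotone map from the genotype scale factor gf to the
#' late-hypoxia slope of the noiseless model trace: a reference table of
#' slopes is computed over a gf grid (noiseless integration, same schedule,
#' model and spectral calibration), then the measured slope is interpolated
#' back to a gf estimate.
#'
#' @param series Measured series with `time_s`, `log10_ratio`.
#' @param schedule,model,spectral Generator settings assumed known.
#' @param gf_grid Grid of genotype factors for the reference table.
#' @param reference Optional precomputed table (from
#'   `genotype_slope_table()`) to avoid recomputation across many fits.
#' @return List with `gf` (estimate, clamped to the grid range) and `slope`.
#' @export
fit_genotype_factor <- function(series, schedule = fig_hypoxia_schedule(),
                                model = kinetic_model(),
                                spectral = spectral_model(),
                                gf_grid = seq(0.05, 1.2, by = 0.05),
                                reference = NULL) {
  if (is.null(reference))
    reference <- genotype_slope_table(schedule, model, spectral, gf_grid)
  sl <- late_hypoxia_slope(series, schedule)
  sl_cl <- min(max(sl, min(reference$slope)), max(reference$slope))
  gf <- stats::approx(reference$slope, reference$gf, xout = sl_cl, ties = "ordered")$y
  list(gf = gf, slope = sl)
}

#' @rdname fit_genotype_factor
#' @export
genotype_slope_table <- function(schedule = fig_hypoxia_schedule(),
                                 model = kinetic_model(),
                                 spectral = spectral_model(),
                                 gf_grid = seq(0.05, 1.2, by = 0.05)) {
  cal <- implied_calibration(spectral)
  slopes <- vapply(gf_grid, function(g) {
    tr <- integrate_pool(schedule, model, gf = g, dt = 5)
    lr <- log10(ratio_from_oxd(tr$oxd, cal))
    late_hypoxia_slope(data.frame(time_s = tr$time_s, log10_ratio = lr),
                       schedule)
  }, numeric(1))
  ord <- order(slopes)
  data.frame(gf = gf_grid[ord], slope = slopes[ord])
}
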