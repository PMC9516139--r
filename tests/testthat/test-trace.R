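# Plate-reader / perfusion trace analysis: blank correction, segmentation,
# slope fits, feature extraction.

make_traces <- function(times, wells_spec) {
  # wells_spec: list(well_id = list(genotype, blank, i400, i482)) with i4xx
  # either scalars or vectors over times
  rows <- list(); meta <- list()
  for (id in names(wells_spec)) {
    w <- wells_spec[[id]]
    rows[[id]] <- data.frame(
      time_s = rep(times, 2), well_id = id,
      excitation = rep(c(400L, 482L), each = length(times)),
      intensity = c(rep_len(w$i400, length(times)),
                    rep_len(w$i482, length(times))))
    meta[[id]] <- data.frame(well_id = id, genotype = w$genotype,
                             treatment = "none", is_blank = w$blank)
  }
  trace_set(do.call(rbind, rows), do.call(rbind, meta))
}

test_that("trace_set validates schema, duplicates and metadata", {
  ts <- make_traces(c(0, 60), list(
    A1 = list(genotype = "WT", blank = FALSE, i400 = 110, i482 = 210),
    B1 = list(genotype = "WT", blank = TRUE, i400 = 10, i482 = 10)))
  expect_s3_class(ts, "trace_set")
  expect_equal(nrow(ts$traces), 8)

  dup <- rbind(ts$traces, ts$traces[1, ])
  expect_error(trace_set(dup, ts$wells), "duplicated")
  bad <- ts$traces; bad$excitation[1] <- 500L
  expect_error(trace_set(bad, ts$wells), "unknown excitation")
  expect_error(trace_set(ts$traces, ts$wells[-1, ]), "without metadata")
})

test_that("correct_and_ratio subtracts per-genotype blanks and flags misses", {
  times <- seq(0, 240, by = 60)
  ts <- make_traces(times, list(
    A1 = list(genotype = "WT", blank = FALSE, i400 = 110, i482 = 210),
    B1 = list(genotype = "WT", blank = TRUE, i400 = 10, i482 = 10)))
  out <- correct_and_ratio(ts)
  expect_equal(out$ratio, rep(0.5, length(times)))
  expect_equal(out$log10_ratio, rep(log10(0.5), length(times)), tolerance = 1e-12)

  # sample equal to blank in one channel -> flagged missing, not fabricated
  ts2 <- make_traces(times, list(
    A1 = list(genotype = "WT", blank = FALSE, i400 = 10, i482 = 210),
    B1 = list(genotype = "WT", blank = TRUE, i400 = 10, i482 = 10)))
  out2 <- correct_and_ratio(ts2)
  expect_true(all(out2$missing))
  expect_true(all(is.na(out2$ratio)))

  ts3 <- make_traces(times, list(
    A1 = list(genotype = "mut", blank = FALSE, i400 = 110, i482 = 210),
    B1 = list(genotype = "WT", blank = TRUE, i400 = 10, i482 = 10)))
  expect_error(correct_and_ratio(ts3), "missing blanks.*mut")
})

test_that("segment_phases uses half-open intervals and the dead-time shift", {
  sch <- fig_hypoxia_schedule()
  s <- data.frame(time_s = c(1800, 3600, 16199, 16200))
  got <- segment_phases(s, sch)
  expect_equal(got$phase, c("normoxia", "hypoxia", "hypoxia", "reoxygenation"))

  perf <- phase_schedule(data.frame(
    name = c("buffer", "treatment", "washout"),
    start_s = c(0, 120, 180), end_s = c(120, 180, 600),
    o2_percent = 20, dtt_uM = c(0, 50, 0)), dead_time_s = 60)
  # 30 s after a valve switch, tissue still sees the previous solution
  got2 <- segment_phases(data.frame(time_s = c(150, 185, 230)), perf)
  expect_equal(got2$phase, c("buffer", "treatment", "treatment"))

  expect_error(phase_schedule(data.frame(name = c("a", "b"),
                                         start_s = c(0, 100), end_s = c(50, 200),
                                         o2_percent = 20)),
               "contiguous")
  expect_error(segment_phases(data.frame(time_s = 40000), sch), "cover")
})

test_that("fit_slope equals the normal-equations oracle and handles edge cases", {
  t <- seq(0, 540, by = 60)
  y <- -0.01 * (t / 60) + 0.2
  f <- fit_slope(t, y, c(0, 600))
  expect_equal(f$slope_per_min, -0.01, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  expect_equal(fit_slope(t, rep(0.3, length(t)), c(0, 600))$slope_per_min, 0)

  set.seed(5)
  for (i in 1:10) {
    tt <- sort(runif(25, 0, 1000))
    yy <- rnorm(25)
    got <- fit_slope(tt, yy, c(0, 1000))
    oracle <- normal_equations_slope(tt, yy)
    expect_equal(got$slope_per_min, oracle$slope_per_min, tolerance = 1e-9)
    expect_equal(got$intercept, oracle$intercept, tolerance = 1e-9)
    expect_equal(got$r_squared, oracle$r_squared, tolerance = 1e-9)
  }

  expect_error(fit_slope(t[1:2], y[1:2], c(0, 600)), "fewer than 3")
  ym <- y; ym[1:3] <- NA  # 30% missing
  expect_error(fit_slope(t, ym, c(0, 600)), "missing")
})

test_that("extract_features matches the constructed piecewise fixture", {
  sch <- fig_hypoxia_schedule()
  t <- seq(0, 28740, by = 60)
  y <- numeric(length(t))
  hy <- t >= 3600 & t < 16200
  y[hy] <- -0.2 * (t[hy] - 3600) / (16140 - 3600)      # -0.2 at last hypoxia sample
  re <- t >= 16200
  y[re] <- 0.3 * exp(-(t[re] - 16200) / 1500)          # step to +0.3, decay to 0
  fe <- extract_features(data.frame(time_s = t, log10_ratio = y), sch)
  expect_equal(fe$steady_state_i, 0)
  expect_equal(fe$reox_peak_ii, 0.5, tolerance = 1e-6)   # 0.3 - (-0.2)
  expect_equal(fe$recovery_iii, 0.3, tolerance = 1e-3)
  expect_lt(fe$reduction_rate$slope_per_min, 0)
  expect_lt(fe$oxidation_rate$slope_per_min, 0)  # onset window sits on the decay

  # flat series: i = constant, ii = iii = 0, rates 0
  fe0 <- extract_features(data.frame(time_s = t, log10_ratio = rep(0.12, length(t))), sch)
  expect_equal(fe0$steady_state_i, 0.12)
  expect_equal(fe0$reox_peak_ii, 0)
  expect_equal(fe0$recovery_iii, 0)
  expect_equal(fe0$reduction_rate$slope_per_min, 0)

  # shift invariance of ii/iii; i shifts
  fe_sh <- extract_features(data.frame(time_s = t, log10_ratio = y + 0.4), sch)
  expect_equal(fe_sh$reox_peak_ii, fe$reox_peak_ii)
  expect_equal(fe_sh$recovery_iii, fe$recovery_iii)
  expect_equal(fe_sh$steady_state_i, fe$steady_state_i + 0.4)

  # absent phases give NULL features, never silent zeros
  sch2 <- phase_schedule(data.frame(name = "normoxia", start_s = 0,
                                    end_s = 30000, o2_percent = 20))
  fe2 <- extract_features(data.frame(time_s = t, log10_ratio = y), sch2)
  expect_null(fe2$reox_peak_ii)
  expect_null(fe2$reduction_rate)
  expect_equal(fe2$steady_state_i, mean(y[t >= 28200 & t < 30000]))
})

test_that("steepest-slope windows find the fastest phases", {
  t <- seq(0, 1000, by = 10)
  y <- ifelse(t < 500, 0, (t - 500) * 0.001)
  f <- steepest_slope_window(t, y, 0, 1000, width_s = 200, sign = 1)
  expect_gte(f$window[1], 400)
  f2 <- steepest_slope_window(t, -y, 0, 1000, width_s = 200, sign = -1)
  expect_lt(f2$slope_per_min, 0)
})

test_that("noiseless simulator traces reproduce the ground-truth log ratio", {
  sim <- simulate_trace(seed = 31, spectral = spectral_model(noise = "none"),
                        n_wells = 3, n_blanks = 2)
  mt <- mean_trace(sim)
  expect_equal(mt$log10_ratio, sim$truth$log10_ratio, tolerance = 1e-9)
})
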