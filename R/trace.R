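# Time-series analysis of biosensor fluorescence from plate-reader hypoxia
# assays and perfusion experiments: per-genotype autofluorescence subtraction,
# ratio/log-ratio traces, phase segmentation, feature extraction and linear
# reduction / re-oxidation rates.

VALID_EXCITATIONS <- c(400L, 405L, 482L, 488L)
NUMERATOR_EX <- c(400L, 405L)   # short-wavelength excitation (numerator)

#' Time-resolved two-channel fluorescence with well metadata
#'
#' @param traces Data frame with columns `time_s`, `well_id`, `excitation`
#'   (400/405 and 482/488 accepted; 400/405 is the ratio numerator) and
#'   `intensity`. Every (well, excitation) series must share the time grid.
#' @param wells Data frame with columns `well_id`, `genotype`, `treatment`,
#'   `is_blank` (logical; blank wells carry autofluorescence only).
#' @return An object of class `trace_set` (list with `traces` and `wells`).
#' @export
trace_set <- function(traces, wells) {
  need_t <- c("time_s", "well_id", "excitation", "intensity")
  need_w <- c("well_id", "genotype", "treatment", "is_blank")
  if (!all(need_t %in% names(traces)))
    stop("traces must have columns: ", paste(need_t, collapse = ", "))
  if (!all(need_w %in% names(wells)))
    stop("wells must have columns: ", paste(need_w, collapse = ", "))
  traces$excitation <- as.integer(traces$excitation)
  bad_ex <- which(!traces$excitation %in% VALID_EXCITATIONS)
  if (length(bad_ex))
    stop("unknown excitation label in traces rows: ",
         paste(utils::head(bad_ex, 5), collapse = ", "))
  key <- paste(traces$time_s, traces$well_id, traces$excitation)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (time, well, excitation) rows: ",
         paste(utils::head(dup, 5), collapse = ", "))
  unknown <- setdiff(unique(traces$well_id), wells$well_id)
  if (length(unknown))
    stop("wells without metadata: ", paste(unknown, collapse = ", "))
  wells$is_blank <- as.logical(wells$is_blank)
  # shared time grid per (well, excitation)
  grids <- tapply(traces$time_s,
                  list(paste(traces$well_id, traces$excitation)),
                  function(t) paste(sort(t), collapse = ","))
  if (length(unique(unlist(grids))) > 1)
    stop("all (well, excitation) series must share the same time grid")
  structure(list(traces = traces, wells = wells), class = "trace_set")
}

#' Phase schedule of an experiment
#'
#' Ordered, contiguous, non-overlapping phases covering the recording. Each
#' phase has a name, half-open time interval \[start_s, end_s), an oxygen
#' level `o2_percent` and an optional perfused DTT concentration `dtt_uM`.
#' `dead_time_s` shifts the schedule as experienced by the tissue (dead
#' volume of perfusion tubing; about 1 min in typical setups).
#'
#' @param phases Data frame with columns `name`, `start_s`, `end_s`,
#'   `o2_percent` and optionally `dtt_uM`.
#' @param dead_time_s Dead-volume delay in seconds (>= 0).
#' @return An object of class `phase_schedule`.
#' @examples
#' fig_hypoxia_schedule()
#' @export
phase_schedule <- function(phases, dead_time_s = 0) {
  need <- c("name", "start_s", "end_s", "o2_percent")
  if (!all(need %in% names(phases)))
    stop("phases must have columns: ", paste(need, collapse = ", "))
  if (is.null(phases$dtt_uM)) phases$dtt_uM <- 0
  phases <- phases[order(phases$start_s), , drop = FALSE]
  if (any(phases$end_s <= phases$start_s))
    stop("each phase must satisfy start_s < end_s")
  if (nrow(phases) > 1 &&
      any(abs(phases$start_s[-1] - phases$end_s[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  structure(list(phases = phases, dead_time_s = dead_time_s),
            class = "phase_schedule")
}

#' Standard hypoxia-reoxygenation plate-reader schedule
#'
#' One hour of normoxia (20% O2), 3.5 h of hypoxia (0.1% O2), 3.5 h of
#' re-oxygenation (20% O2).
#'
#' @return A [phase_schedule()].
#' @export
fig_hypoxia_schedule <- function() {
  phase_schedule(data.frame(
    name = c("normoxia", "hypoxia", "reoxygenation"),
    start_s = c(0, 3600, 16200),
    end_s = c(3600, 16200, 28800),
    o2_percent = c(20, 0.1, 20)))
}

#' Autofluorescence correction and log-ratio computation
#'
#' For each genotype and excitation channel, the time-resolved mean of that
#' genotype's blank wells is subtracted from every sensor well. The corrected
#' numerator (400/405 nm) over denominator (482/488 nm) ratio is computed and
#' log10-transformed. Time points where either corrected channel is <= 0 are
#' flagged missing (`NA`), never fabricated.
#'
#' @param ts A [trace_set()]; every genotype needs at least one blank well.
#' @return Data frame with columns `well_id`, `genotype`, `treatment`,
#'   `time_s`, `ratio`, `log10_ratio`, `missing`.
#' @export
correct_and_ratio <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  tr <- merge(ts$traces, ts$wells, by = "well_id")
  tr$role <- ifelse(tr$excitation %in% NUMERATOR_EX, "num", "den")
  out <- list()
  for (g in unique(tr$genotype)) {
    tg <- tr[tr$genotype == g, , drop = FALSE]
    bl <- tg[tg$is_blank, , drop = FALSE]
    if (nrow(bl) == 0)
      stop("missing blanks for genotype: ", g)
    blank_mean <- stats::aggregate(intensity ~ time_s + role, data = bl, FUN = mean)
    names(blank_mean)[3] <- "blank"
    sm <- tg[!tg$is_blank, , drop = FALSE]
    if (nrow(sm) == 0) next
    sm <- merge(sm, blank_mean, by = c("time_s", "role"))
    sm$corrected <- sm$intensity - sm$blank
    wide <- stats::reshape(
      sm[, c("well_id", "treatment", "time_s", "role", "corrected")],
      idvar = c("well_id", "treatment", "time_s"),
      timevar = "role", direction = "wide")
    num <- wide$corrected.num; den <- wide$corrected.den
    missing <- !(num > 0 & den > 0) | is.na(num) | is.na(den)
    ratio <- ifelse(missing, NA_real_, num / den)
    out[[g]] <- data.frame(well_id = wide$well_id, genotype = g,
                           treatment = wide$treatment, time_s = wide$time_s,
                           ratio = ratio, log10_ratio = log10(ratio),
                           missing = missing)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$well_id, res$time_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Average the log-ratio trace over wells
#'
#' @param series Output of [correct_and_ratio()], typically one genotype and
#'   treatment.
#' @return Data frame with `time_s` and `log10_ratio` (mean over wells,
#'   missing points excluded).
#' @export
mean_log_ratio_trace <- function(series) {
  ok <- series[!series$missing, , drop = FALSE]
  agg <- stats::aggregate(log10_ratio ~ time_s, data = ok, FUN = mean)
  agg[order(agg$time_s), , drop = FALSE]
}

#' Label time points with their schedule phase
#'
#' Intervals are half-open \[start_s, end_s); a perfusion dead time shifts the
#' schedule forward before labeling (a sample taken 30 s after a valve switch
#' with a 60 s dead volume is still labeled with the previous phase).
#'
#' @param series Data frame with a `time_s` column.
#' @param schedule A [phase_schedule()] covering the series time span.
#' @return `series` with an added `phase` column.
#' @export
segment_phases <- function(series, schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  ph <- schedule$phases
  t_eff <- series$time_s - schedule$dead_time_s
  t_eff <- pmax(t_eff, ph$start_s[1])   # samples within the dead time: first phase
  if (any(series$time_s - schedule$dead_time_s >= ph$end_s[nrow(ph)]))
    stop("schedule does not cover the series time span")
  idx <- findInterval(t_eff, ph$start_s)
  series$phase <- ph$name[idx]
  series
}

#' Ordinary least-squares slope of a log-ratio series
#'
#' Fits `y ~ time` by OLS within a time window and reports the slope per
#' minute. Missing (`NA`) points are excluded; the fit proceeds only if at
#' least three points and at least 80% of the window's points remain.
#'
#' @param time_s Time in seconds.
#' @param y Response (conventionally log10 ratio).
#' @param window Numeric length-2 vector `[t0, t1]` in seconds (half-open).
#' @return A list with `slope_per_min`, `intercept`, `r_squared`, `n`,
#'   `window`.
#' @export
fit_slope <- function(time_s, y, window = range(time_s)) {
  sel <- time_s >= window[1] & time_s < window[2] + 1e-9
  t_all <- time_s[sel]; y_all <- y[sel]
  ok <- is.finite(y_all)
  if (sum(ok) < 3) stop("fewer than 3 usable points in fit window")
  if (length(y_all) > 0 && sum(ok) / length(y_all) < 0.8)
    stop("more than 20% of window points are missing")
  tm <- t_all[ok] / 60; yy <- y_all[ok]
  mt <- mean(tm); my <- mean(yy)
  sxx <- sum((tm - mt)^2)
  if (sxx == 0) stop("degenerate fit window: no time spread")
  slope <- sum((tm - mt) * (yy - my)) / sxx
  intercept <- my - slope * mt
  ss_res <- sum((yy - intercept - slope * tm)^2)
  ss_tot <- sum((yy - my)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope_per_min = slope, intercept = intercept, r_squared = r2,
       n = sum(ok), window = window)
}

#' Fixed-width window of steepest slope
#'
#' Slides a window of `width_s` seconds over `[t0, t1)` and returns the window
#' maximizing `sign * slope` (sign +1 for the steepest rise, -1 for the
#' steepest fall).
#'
#' @param time_s,y Series.
#' @param t0,t1 Search interval in seconds.
#' @param width_s Window width in seconds.
#' @param sign +1 or -1.
#' @param step_s Slide step (default `width_s / 4`).
#' @return The [fit_slope()] result of the best window.
#' @export
steepest_slope_window <- function(time_s, y, t0, t1, width_s, sign = 1,
                                  step_s = width_s / 4) {
  starts <- seq(t0, t1 - width_s, by = step_s)
  if (!length(starts)) stop("search interval shorter than window width")
  best <- NULL; best_val <- -Inf
  for (s in starts) {
    f <- try(fit_slope(time_s, y, c(s, s + width_s)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (sign * f$slope_per_min > best_val) {
      best_val <- sign * f$slope_per_min; best <- f
    }
  }
  if (is.null(best)) stop("no usable window found")
  best
}

#' Configuration of trace feature extraction
#'
#' @param steady_window_s Length of the steady-state window at the end of the
#'   first (normoxic) phase used for feature (i); default 30 min.
#' @param recovery_window_s Length of the end-of-recording window for feature
#'   (iii); default 30 min.
#' @param reduction_window_s Length of the reduction-rate window starting at
#'   hypoxia onset; default 20 min.
#' @param oxidation_window_s Length of the re-oxidation-rate window starting
#'   at re-oxygenation onset; default 10 min.
#' @param auto_windows If `TRUE`, rates use the steepest-slope window of the
#'   configured width inside their phase instead of the phase-onset window.
#' @param normoxia,hypoxia,reoxygenation Phase names in the schedule.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(steady_window_s = 1800, recovery_window_s = 1800,
                           reduction_window_s = 1200, oxidation_window_s = 600,
                           auto_windows = FALSE,
                           normoxia = "normoxia", hypoxia = "hypoxia",
                           reoxygenation = "reoxygenation") {
  structure(list(steady_window_s = steady_window_s,
                 recovery_window_s = recovery_window_s,
                 reduction_window_s = reduction_window_s,
                 oxidation_window_s = oxidation_window_s,
                 auto_windows = auto_windows,
                 normoxia = normoxia, hypoxia = hypoxia,
                 reoxygenation = reoxygenation),
            class = "feature_config")
}

phase_bounds <- function(schedule, name) {
  ph <- schedule$phases
  i <- match(name, ph$name)
  if (is.na(i)) return(NULL)
  c(ph$start_s[i], ph$end_s[i])
}

#' Extract hypoxia-reoxygenation trace features
#'
#' Computes, from a single log10-ratio series and its phase schedule:
#' \describe{
#'   \item{steady_state_i}{mean log10 ratio over the final `steady_window_s`
#'     of the normoxic phase (feature i).}
#'   \item{reox_peak_ii}{maximum log10 ratio within the re-oxygenation phase
#'     minus the log10 ratio at re-oxygenation onset, where the onset value is
#'     read from the last sample of the preceding phase so that an
#'     instantaneous burst at the phase switch is fully counted (feature ii).}
#'   \item{recovery_iii}{that maximum minus the mean over the final
#'     `recovery_window_s` of the recording (feature iii).}
#'   \item{reduction_rate}{[fit_slope()] over `reduction_window_s` from
#'     hypoxia onset (or the steepest-fall window when `auto_windows`).}
#'   \item{oxidation_rate}{[fit_slope()] over `oxidation_window_s` from
#'     re-oxygenation onset (or the steepest-rise window).}
#' }
#' Features whose phase is absent from the schedule are `NULL`, never silently
#' zero. Features (ii) and (iii) are invariant to adding a constant to the
#' whole series; (i) shifts by that constant.
#'
#' @param series Data frame with `time_s` and `log10_ratio` (e.g. from
#'   [mean_log_ratio_trace()] or one well of [correct_and_ratio()]).
#' @param schedule A [phase_schedule()].
#' @param config A [feature_config()].
#' @return A list of class `trace_features`.
#' @export
extract_features <- function(series, schedule, config = feature_config()) {
  stopifnot(inherits(schedule, "phase_schedule"),
            inherits(config, "feature_config"))
  t <- series$time_s; y <- series$log10_ratio
  feats <- list(steady_state_i = NULL, reox_peak_ii = NULL,
                recovery_iii = NULL, reduction_rate = NULL,
                oxidation_rate = NULL)
  norm <- phase_bounds(schedule, config$normoxia)
  hyp <- phase_bounds(schedule, config$hypoxia)
  reox <- phase_bounds(schedule, config$reoxygenation)

  if (!is.null(norm)) {
    w <- t >= norm[2] - config$steady_window_s & t < norm[2] & is.finite(y)
    if (any(w)) feats$steady_state_i <- mean(y[w])
  }
  if (!is.null(reox)) {
    inre <- t >= reox[1] & t < reox[2] & is.finite(y)
    pre <- t < reox[1] & is.finite(y)
    if (any(inre)) {
      peak <- max(y[inre])
      onset_ref <- if (any(pre)) y[pre][which.max(t[pre])] else y[inre][which.min(t[inre])]
      feats$reox_peak_ii <- peak - onset_ref
      wend <- t >= reox[2] - config$recovery_window_s & t < reox[2] & is.finite(y)
      if (any(wend)) feats$recovery_iii <- peak - mean(y[wend])
    }
  }
  if (!is.null(hyp)) {
    feats$reduction_rate <- try_fit(t, y, hyp, config$reduction_window_s,
                                    auto = config$auto_windows, sign = -1)
  }
  if (!is.null(reox)) {
    feats$oxidation_rate <- try_fit(t, y, reox, config$oxidation_window_s,
                                    auto = config$auto_windows, sign = +1)
  }
  structure(feats, class = "trace_features")
}

try_fit <- function(t, y, bounds, width, auto, sign) {
  res <- try({
    if (auto) steepest_slope_window(t, y, bounds[1], bounds[2], width, sign)
    else fit_slope(t, y, c(bounds[1], bounds[1] + width))
  }, silent = TRUE)
  if (inherits(res, "try-error")) NULL else res
}
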