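# Closed-form redox arithmetic for ratiometric roGFP-family biosensors:
# fluorescence ratio <-> degree of oxidation (OxD), OxD <-> redox potential
# (Nernst), potential -> glutathione pool partition, and dynamic-range helpers.

#' Physical constants for Nernst arithmetic
#'
#' Bundles the gas constant, the Faraday constant and an absolute temperature.
#' The temperature defaults to 298.15 K (25 degrees C); titration curves for
#' roGFP-family sensors are conventionally computed at this temperature and at
#' pH 7 without further pH correction.
#'
#' @param temperature_K Absolute temperature in kelvin. Must be positive.
#' @return An object of class `physical_constants` with fields `gas_constant`
#'   (J mol^-1 K^-1), `faraday` (C mol^-1) and `temperature_K`.
#' @examples
#' physical_constants()
#' physical_constants(temperature_K = 295)
#' @export
physical_constants <- function(temperature_K = 298.15) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1,
            is.finite(temperature_K))
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  structure(list(gas_constant = 8.314, faraday = 96485,
                 temperature_K = temperature_K),
            class = "physical_constants")
}

# RT/nF in millivolts for a given electron count
nernst_slope_mV <- function(const, n_electrons = 2) {
  const$gas_constant * const$temperature_K / (n_electrons * const$faraday) * 1000
}

#' Biosensor identity and midpoint potential
#'
#' @param name Sensor name (free text).
#' @param midpoint_mV Consensus midpoint redox potential E0' in millivolts
#'   (signed; e.g. -240 for roGFP2iL, -280 for roGFP2).
#' @param n_electrons Number of electrons transferred (2 for dithiol sensors).
#' @return An object of class `sensor_spec`.
#' @examples
#' sensor_rogfp2il()
#' sensor_spec("roGFP1iE", -236)
#' @export
sensor_spec <- function(name, midpoint_mV, n_electrons = 2L) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(midpoint_mV), length(midpoint_mV) == 1,
            is.finite(midpoint_mV))
  n_electrons <- as.integer(n_electrons)
  if (is.na(n_electrons) || n_electrons < 1) stop("n_electrons must be >= 1")
  structure(list(name = name, midpoint_mV = midpoint_mV,
                 n_electrons = n_electrons),
            class = "sensor_spec")
}

#' @rdname sensor_spec
#' @export
sensor_rogfp2il <- function() sensor_spec("Grx1-roGFP2iL", -240)

#' @rdname sensor_spec
#' @export
sensor_rogfp2 <- function() sensor_spec("roGFP2", -280)

#' In situ calibration of a ratiometric sensor
#'
#' Holds the fluorescence ratios of the fully reduced and fully oxidized
#' sensor (obtained e.g. by DTT and H2O2 immersion) and the 488-channel
#' intensity correction factor `i488_factor` = I488_min / I488_max, where
#' I488_min and I488_max are the 488-excited intensities of the fully
#' oxidized and fully reduced sensor, respectively.
#'
#' @param R_red Ratio of the fully reduced sensor (> 0).
#' @param R_ox Ratio of the fully oxidized sensor (> 0, distinct from `R_red`).
#' @param i488_factor I488_min / I488_max (> 0).
#' @return An object of class `calibration_record`.
#' @examples
#' calibration_record(R_red = 0.5, R_ox = 1.05, i488_factor = 0.7)
#' @export
calibration_record <- function(R_red, R_ox, i488_factor) {
  vals <- c(R_red = R_red, R_ox = R_ox, i488_factor = i488_factor)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("calibration entries must be finite and strictly positive")
  if (R_red == R_ox)
    stop("uncalibrated: R_red and R_ox are identical")
  structure(list(R_red = R_red, R_ox = R_ox, i488_factor = i488_factor),
            class = "calibration_record")
}

#' Degree of sensor oxidation from a fluorescence ratio
#'
#' Converts 405/488 (or 400/482) excitation ratios to the degree of sensor
#' oxidation
#' \deqn{OxD = \frac{R - R_{red}}{\frac{I488_{min}}{I488_{max}}(R_{ox} - R) + (R - R_{red})}}
#' Ratios outside the calibration interval (noisy pixels routinely exceed the
#' in situ limits) are clamped to OxD in \[0, 1\]; the returned vector carries a
#' logical attribute `out_of_range` flagging those entries, and a warning is
#' raised when any is set.
#'
#' @param R Numeric vector of fluorescence ratios.
#' @param cal A [calibration_record()].
#' @param clamp Clamp out-of-range values to \[0, 1\] (default `TRUE`). With
#'   `clamp = FALSE` the raw formula value is returned.
#' @return Numeric vector of OxD values with attribute `out_of_range`.
#' @examples
#' cal <- calibration_record(0.2, 1.0, 0.5)
#' oxd_from_ratio(0.6, cal)  # 2/3
#' @export
oxd_from_ratio <- function(R, cal, clamp = TRUE) {
  stopifnot(inherits(cal, "calibration_record"), is.numeric(R))
  oxd <- (R - cal$R_red) /
    (cal$i488_factor * (cal$R_ox - R) + (R - cal$R_red))
  lo <- min(cal$R_red, cal$R_ox); hi <- max(cal$R_red, cal$R_ox)
  oor <- is.finite(R) & (R < lo | R > hi)
  if (clamp) {
    oxd <- pmin(1, pmax(0, oxd))
    if (any(oor, na.rm = TRUE))
      warning(sprintf("%d ratio value(s) outside calibration limits; OxD clamped to [0,1]",
                      sum(oor, na.rm = TRUE)))
  }
  attr(oxd, "out_of_range") <- oor
  oxd
}

#' Fluorescence ratio from a degree of oxidation
#'
#' Algebraic inverse of [oxd_from_ratio()]; equivalently the ratio predicted by
#' a two-state spectral mixing model whose endmembers imply the calibration.
#'
#' @param oxd Numeric vector of oxidation degrees in \[0, 1\].
#' @param cal A [calibration_record()].
#' @return Numeric vector of ratios.
#' @examples
#' cal <- calibration_record(0.2, 1.0, 0.5)
#' ratio_from_oxd(c(0, 1, 2/3), cal)
#' @export
ratio_from_oxd <- function(oxd, cal) {
  stopifnot(inherits(cal, "calibration_record"), is.numeric(oxd))
  if (any(oxd < 0 | oxd > 1, na.rm = TRUE))
    stop("oxd must lie in [0, 1]")
  i <- cal$i488_factor
  (cal$R_red * (1 - oxd) + i * cal$R_ox * oxd) / ((1 - oxd) + i * oxd)
}

#' Redox potential from a degree of oxidation (Nernst equation)
#'
#' \deqn{E = E_0' - \frac{RT}{nF}\,\ln\frac{1 - OxD}{OxD}}
#'
#' @param oxd Oxidation degree strictly inside (0, 1); values of exactly 0 or 1
#'   correspond to an unbounded potential and raise an error.
#' @param sensor A [sensor_spec()].
#' @param const A [physical_constants()].
#' @return Potential in millivolts (signed), vectorized over `oxd`.
#' @examples
#' potential_from_oxd(0.5, sensor_rogfp2il())    # the midpoint, -240
#' potential_from_oxd(0.465, sensor_rogfp2il())  # about -241.8
#' @export
potential_from_oxd <- function(oxd, sensor, const = physical_constants()) {
  stopifnot(inherits(sensor, "sensor_spec"),
            inherits(const, "physical_constants"), is.numeric(oxd))
  if (any(oxd <= 0 | oxd >= 1, na.rm = TRUE))
    stop("potential unbounded: oxd must lie strictly inside (0, 1)")
  sensor$midpoint_mV -
    nernst_slope_mV(const, sensor$n_electrons) * log((1 - oxd) / oxd)
}

#' Degree of oxidation at a given redox potential
#'
#' Inverse of [potential_from_oxd()]; the sensor titration curve.
#'
#' @param E_mV Potential in millivolts, vectorized.
#' @inheritParams potential_from_oxd
#' @return Oxidation degree in (0, 1).
#' @examples
#' oxd_from_potential(-240, sensor_rogfp2il())  # 0.5
#' @export
oxd_from_potential <- function(E_mV, sensor, const = physical_constants()) {
  stopifnot(inherits(sensor, "sensor_spec"),
            inherits(const, "physical_constants"), is.numeric(E_mV))
  s <- nernst_slope_mV(const, sensor$n_electrons)
  1 / (1 + exp((sensor$midpoint_mV - E_mV) / s))
}

#' Sensor titration curve over a potential grid
#'
#' @param E_grid Numeric vector of potentials in millivolts.
#' @inheritParams potential_from_oxd
#' @return A data frame with columns `E_mV` and `oxd`, monotone in `E_mV`.
#' @examples
#' head(titration_curve(seq(-280, -200, by = 10), sensor_rogfp2il()))
#' @export
titration_curve <- function(E_grid, sensor, const = physical_constants()) {
  data.frame(E_mV = E_grid,
             oxd = oxd_from_potential(E_grid, sensor, const))
}

#' Partition a glutathione pool at a given redox potential
#'
#' For the two-electron GSSG/2GSH couple,
#' \deqn{E = E_0' - \frac{RT}{2F}\ln\frac{[GSH]^2}{[GSSG]}}
#' with concentrations in mol/L (the bracketed quotient carries units of M).
#' Given `E_mV` and total \[GSH\], returns the implied \[GSSG\] and the molar
#' GSH:GSSG ratio. At 2.5 mM GSH and E = -240 mV (the couple midpoint) the
#' ratio is exactly 400:1.
#'
#' @param E_mV Glutathione redox potential in millivolts.
#' @param gsh_molar GSH concentration in mol/L (> 0).
#' @param couple_midpoint_mV Standard potential of the GSSG/2GSH couple at
#'   pH 7; default -240 mV.
#' @param const A [physical_constants()].
#' @return An object of class `glutathione_pool`: list with `gsh_molar`,
#'   `gssg_molar`, `ratio` (GSH:GSSG) and `couple_midpoint_mV`.
#' @examples
#' partition_glutathione(-240, 2.5e-3)  # ratio 400
#' @export
partition_glutathione <- function(E_mV, gsh_molar, couple_midpoint_mV = -240,
                                  const = physical_constants()) {
  stopifnot(inherits(const, "physical_constants"),
            is.numeric(E_mV), is.numeric(gsh_molar))
  if (any(gsh_molar <= 0)) stop("gsh_molar must be > 0")
  s <- nernst_slope_mV(const, 2)
  # [GSH]^2/[GSSG] = exp((E0' - E)/s) in molar units
  mass_action <- exp((couple_midpoint_mV - E_mV) / s)
  gssg <- gsh_molar^2 / mass_action
  structure(list(gsh_molar = gsh_molar, gssg_molar = gssg,
                 ratio = gsh_molar / gssg,
                 couple_midpoint_mV = couple_midpoint_mV),
            class = "glutathione_pool")
}

#' Glutathione redox potential from pool concentrations
#'
#' Inverse of [partition_glutathione()]:
#' \deqn{E = E_0' - \frac{RT}{2F}\ln\frac{[GSH]^2}{[GSSG]}}
#' with concentrations in mol/L.
#'
#' @param gsh_molar,gssg_molar Concentrations in mol/L (> 0), vectorized.
#' @param couple_midpoint_mV Couple standard potential at pH 7 (default -240).
#' @param const A [physical_constants()].
#' @return Potential in millivolts.
#' @export
potential_from_pool <- function(gsh_molar, gssg_molar,
                                couple_midpoint_mV = -240,
                                const = physical_constants()) {
  if (any(gsh_molar <= 0) || any(gssg_molar <= 0))
    stop("concentrations must be > 0")
  s <- nernst_slope_mV(const, 2)
  couple_midpoint_mV - s * log(gsh_molar^2 / gssg_molar)
}

#' Sensor dynamic range and log10-fold helpers
#'
#' `dynamic_range()` returns the dynamic range delta = max(R_ox, R_red) /
#' min(R_ox, R_red) of a calibrated sensor. `fold_from_log10()` converts a
#' difference of log10-transformed ratios into the equivalent fold change
#' (e.g. a log10 change of 0.75 corresponds to a fold change of about 5.6).
#'
#' @param cal A [calibration_record()].
#' @return `dynamic_range()`: delta >= 1.
#' @examples
#' dynamic_range(calibration_record(0.5, 1.05, 0.7))  # 2.1
#' fold_from_log10(0.75)                              # 5.62
#' @export
dynamic_range <- function(cal) {
  stopifnot(inherits(cal, "calibration_record"))
  max(cal$R_ox, cal$R_red) / min(cal$R_ox, cal$R_red)
}

#' @rdname dynamic_range
#' @param delta_log10 Difference of log10-transformed ratios (finite).
#' @export
fold_from_log10 <- function(delta_log10) {
  stopifnot(is.numeric(delta_log10))
  if (any(!is.finite(delta_log10))) stop("delta_log10 must be finite")
  10^delta_log10
}

#' @export
print.glutathione_pool <- function(x, ...) {
  cat(sprintf("Glutathione pool: [GSH] = %.4g M, [GSSG] = %.4g M, GSH:GSSG = %.4g:1\n",
              x$gsh_molar, x$gssg_molar, x$ratio))
  invisible(x)
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("Sensor %s: E0' = %g mV, n = %d electrons\n",
              x$name, x$midpoint_mV, x$n_electrons))
  invisible(x)
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("Calibration: R_red = %g, R_ox = %g, i488_factor = %g (delta = %.3g)\n",
              x$R_red, x$R_ox, x$i488_factor, dynamic_range(x)))
  invisible(x)
}
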