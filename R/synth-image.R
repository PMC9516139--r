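# Synthetic two-channel ER-network images under a two-state spectral mixing
# model, with per-pixel ground-truth oxidation.

#' Fluorescence observation model of a two-state ratiometric sensor
#'
#' Per-channel endmember intensities of the fully reduced and fully oxidized
#' sensor, background levels, autofluorescence level with bleed-through into
#' the 405-excited channel, and a noise model. The defaults imply a
#' calibration R_red = 0.5, R_ox = 1.05 (dynamic range delta = 2.1, matching
#' the 2.0-2.2 observed in situ for roGFP2iL) and i488_factor = 0.7 < 1.
#'
#' @param f405_red,f405_ox,f488_red,f488_ox Endmember intensities (photon
#'   counts at full sensor density), all >= 0.
#' @param background_405,background_488 Channel background levels.
#' @param autofluor_level Amplitude of the autofluorescence field.
#' @param bleed_coefficient Fraction of the autofluorescence channel bleeding
#'   into the 405-excited channel.
#' @param noise One of `"poisson"` (shot noise on photon counts; at the
#'   default counts of ~2000 this gives roughly 2% CV), `"gaussian"`, or
#'   `"none"`.
#' @param gaussian_sd Standard deviation when `noise = "gaussian"`.
#' @param photon_scale Photons per intensity unit for Poisson noise.
#' @return An object of class `spectral_model`.
#' @export
spectral_model <- function(f405_red = 1250, f405_ox = 1837.5,
                           f488_red = 2500, f488_ox = 1750,
                           background_405 = 50, background_488 = 50,
                           autofluor_level = 100, bleed_coefficient = 0.25,
                           noise = c("poisson", "gaussian", "none"),
                           gaussian_sd = 20, photon_scale = 1) {
  noise <- match.arg(noise)
  ends <- c(f405_red, f405_ox, f488_red, f488_ox)
  if (any(!is.finite(ends)) || any(ends < 0))
    stop("invalid spectral model: endmembers must be finite and >= 0")
  if (f488_red == 0 || f488_ox == 0)
    stop("invalid spectral model: 488 endmembers must be > 0")
  if (isTRUE(all.equal(f405_red / f488_red, f405_ox / f488_ox)))
    stop("invalid spectral model: implied R_red and R_ox coincide")
  structure(list(f405_red = f405_red, f405_ox = f405_ox,
                 f488_red = f488_red, f488_ox = f488_ox,
                 background_405 = background_405,
                 background_488 = background_488,
                 autofluor_level = autofluor_level,
                 bleed_coefficient = bleed_coefficient,
                 noise = noise, gaussian_sd = gaussian_sd,
                 photon_scale = photon_scale),
            class = "spectral_model")
}

#' Calibration implied by a spectral model
#'
#' @param spectral A [spectral_model()].
#' @return The [calibration_record()] with R_red = f405_red/f488_red,
#'   R_ox = f405_ox/f488_ox and i488_factor = f488_ox/f488_red.
#' @export
implied_calibration <- function(spectral) {
  stopifnot(inherits(spectral, "spectral_model"))
  calibration_record(R_red = spectral$f405_red / spectral$f488_red,
                     R_ox = spectral$f405_ox / spectral$f488_ox,
                     i488_factor = spectral$f488_ox / spectral$f488_red)
}

apply_noise <- function(x, spectral) {
  switch(spectral$noise,
         none = x,
         gaussian = pmax(0, x + stats::rnorm(length(x), 0, spectral$gaussian_sd)),
         poisson = {
           s <- spectral$photon_scale
           matrix(stats::rpois(length(x), pmax(0, x) * s) / s, nrow(x), ncol(x))
         })
}

# Sensor-density field: random branched tubule polylines dilated to ~2 px,
# an annular nuclear ring, and bright elliptical ER bodies.
er_density_field <- function(shape, n_tubules = 12, n_bodies = 3,
                             nuclear_ring = TRUE) {
  nr <- shape[1]; nc <- shape[2]
  dens <- matrix(0, nr, nc)
  stamp <- function(r, c, val) {
    r <- round(r); c <- round(c)
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    dens[cbind(r[ok], c[ok])] <<- pmax(dens[cbind(r[ok], c[ok])], val)
  }
  walk <- function(r0, c0, theta, len) {
    r <- r0; c <- c0
    for (i in seq_len(len)) {
      theta <- theta + stats::rnorm(1, 0, 0.25)
      r <- r + sin(theta); c <- c + cos(theta)
      if (r < 2 || r > nr - 1 || c < 2 || c > nc - 1) break
      stamp(r, c, 1)
      if (stats::runif(1) < 0.02)  # occasional branch
        walk(r, c, theta + sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1.4),
             max(4, len %/% 2))
    }
  }
  for (i in seq_len(n_tubules))
    walk(stats::runif(1, 2, nr - 1), stats::runif(1, 2, nc - 1),
         stats::runif(1, 0, 2 * pi), round(0.6 * max(nr, nc)))
  if (nuclear_ring) {
    cr <- stats::runif(1, 0.3, 0.7) * nr; cc <- stats::runif(1, 0.3, 0.7) * nc
    rad <- stats::runif(1, 0.1, 0.16) * min(nr, nc)
    ang <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rad * 2))
    stamp(cr + rad * sin(ang), cc + rad * cos(ang), 1)
  }
  # dilate to ~2-3 px tubules with soft edges
  dens <- mean_filter3(dens) * 3
  dens[dens > 1] <- 1
  for (i in seq_len(n_bodies)) {  # ER bodies: bright ellipses
    cr <- stats::runif(1, 0.15, 0.85) * nr; cc <- stats::runif(1, 0.15, 0.85) * nc
    a <- stats::runif(1, 3, 6); b <- stats::runif(1, 1.5, 2.5)
    th <- stats::runif(1, 0, pi)
    rr <- matrix(seq_len(nr), nr, nc); ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    u <- (rr - cr) * cos(th) + (ccm - cc) * sin(th)
    v <- -(rr - cr) * sin(th) + (ccm - cc) * cos(th)
    dens[(u / a)^2 + (v / b)^2 <= 1] <- 1.5
  }
  dens
}

# Smooth autofluorescence field in [0.5, 1.5] * level
autofluor_field <- function(shape, level) {
  f <- matrix(stats::runif(prod(shape)), shape[1], shape[2])
  for (i in 1:6) f <- mean_filter3(f)
  rng <- range(f)
  g <- if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0 + 0.5
  level * (0.5 + g)
}

#' Simulate a two-channel ER-network image with ground truth
#'
#' Builds a sensor-density field emulating a reticulate ER network (branched
#' tubules of ~2 px width, a nuclear ring, bright elongated ER bodies), mixes
#' the reduced/oxidized spectral endmembers per pixel according to a
#' ground-truth oxidation field, and adds background, autofluorescence
#' bleed-through (405 channel) and noise:
#' `I_ch = density * (f_ch_red (1 - OxD) + f_ch_ox OxD) + background (+ bleed) + noise`.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param oxd Ground-truth oxidation: scalar in \[0, 1\] or matrix of `shape`.
#' @param spectral A [spectral_model()].
#' @param seed Integer seed (mandatory; every dataset is reproducible from
#'   seed and parameters).
#' @param calibration_pair Also emit fully reduced / fully oxidized images of
#'   the same specimen (in situ calibration analogue).
#' @param n_tubules,n_bodies Morphology parameters.
#' @return A list with channel images `ch405`, `ch488`, `autofluor`, the
#'   `truth` (list: `oxd` matrix, `density`, `seed`, `params`), and when
#'   requested `calibration` (list of `reduced` and `oxidized` channel pairs).
#' @export
simulate_er_image <- function(shape = c(96, 96), oxd = 0.465,
                              spectral = spectral_model(), seed,
                              calibration_pair = FALSE,
                              n_tubules = 12, n_bodies = 3) {
  stopifnot(inherits(spectral, "spectral_model"))
  if (missing(seed)) stop("seed is mandatory")
  if (length(oxd) == 1) oxd <- matrix(oxd, shape[1], shape[2])
  if (!identical(dim(oxd), as.integer(shape)) &&
      !identical(dim(oxd), shape)) stop("oxd field shape mismatch")
  if (any(oxd < 0 | oxd > 1)) stop("oxd field values must lie in [0, 1]")
  set.seed(seed)
  dens <- er_density_field(shape, n_tubules, n_bodies)
  af <- autofluor_field(shape, spectral$autofluor_level)
  render <- function(o) {
    i405 <- dens * (spectral$f405_red * (1 - o) + spectral$f405_ox * o) +
      spectral$background_405 + spectral$bleed_coefficient * af
    i488 <- dens * (spectral$f488_red * (1 - o) + spectral$f488_ox * o) +
      spectral$background_488
    list(ch405 = channel_image(apply_noise(i405, spectral), "ex405"),
         ch488 = channel_image(apply_noise(i488, spectral), "ex488"))
  }
  main <- render(oxd)
  out <- list(ch405 = main$ch405, ch488 = main$ch488,
              autofluor = channel_image(apply_noise(af, spectral),
                                        "autofluor430_470"),
              truth = list(oxd = oxd, density = dens, seed = seed,
                           params = spectral))
  if (calibration_pair) {
    out$calibration <- list(reduced = render(matrix(0, shape[1], shape[2])),
                            oxidized = render(matrix(1, shape[1], shape[2])))
  }
  out
}

#' Full image-analysis round trip of a simulated image
#'
#' Convenience pipeline used in validation: preprocess both channels (known
#' background and bleed), compute the ratio map with the default mask
#' threshold, summarize the ROI, and convert the mean ratio to OxD using the
#' calibration implied by the spectral model (or measured from a calibration
#' pair).
#'
#' @param sim Output of [simulate_er_image()].
#' @param cal Optional [calibration_record()]; defaults to the implied one.
#' @return List with the `roi_summary()` fields plus `oxd`.
#' @export
analyze_simulated_image <- function(sim, cal = NULL) {
  sp <- sim$truth$params
  if (is.null(cal)) cal <- implied_calibration(sp)
  params <- correction_params(background_405 = sp$background_405,
                              background_488 = sp$background_488,
                              bleed_coefficient = sp$bleed_coefficient)
  p405 <- preprocess_channel(sim$ch405, params, autofluor = sim$autofluor)
  p488 <- preprocess_channel(sim$ch488, params)
  thr <- default_mask_threshold(p488)
  rimg <- ratio_map(p405, p488, thr)
  s <- roi_summary(rimg)
  s$oxd <- as.numeric(oxd_from_ratio(s$mean_ratio, cal))
  s
}

#' Measure a calibration record from simulated calibration-pair images
#'
#' Processes the fully reduced and fully oxidized images through the standard
#' preprocessing and ratio pipeline and reads off R_red, R_ox and
#' i488_factor.
#'
#' @param sim Output of `simulate_er_image(..., calibration_pair = TRUE)`.
#' @return A [calibration_record()].
#' @export
measure_calibration <- function(sim) {
  if (is.null(sim$calibration)) stop("simulation lacks a calibration pair")
  sp <- sim$truth$params
  params <- correction_params(sp$background_405, sp$background_488,
                              sp$bleed_coefficient)
  one <- function(pair) {
    p405 <- preprocess_channel(pair$ch405, params, autofluor = sim$autofluor)
    p488 <- preprocess_channel(pair$ch488, params)
    thr <- default_mask_threshold(p488)
    s <- roi_summary(ratio_map(p405, p488, thr))
    list(ratio = s$mean_ratio,
         i488 = mean(unclass(p488)[unclass(p488) >= thr]))
  }
  red <- one(sim$calibration$reduced)
  ox <- one(sim$calibration$oxidized)
  calibration_record(R_red = red$ratio, R_ox = ox$ratio,
                     i488_factor = ox$i488 / red$i488)
}
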