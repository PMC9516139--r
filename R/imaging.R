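# Pixel-wise ratiometric analysis of two-channel excitation images:
# background subtraction, autofluorescence bleed-through correction, 3x3
# spatial averaging, masking, ROI summaries, pseudocolor rendering and the
# redox-based topology (ReTA) readout.

#' Labeled single-channel image
#'
#' A thin wrapper around a numeric matrix of non-negative intensities
#' (arbitrary units, row/column indexed). Channel labels follow the
#' acquisition: `ex405` and `ex488` are the two sensor excitation channels;
#' `autofluor430_470` is the autofluorescence channel excited at 405 nm and
#' collected at 430-470 nm.
#'
#' @param pixels Numeric matrix; negative values are clipped to 0.
#' @param channel_label One of `"ex405"`, `"ex488"`, `"autofluor430_470"`.
#' @return A `channel_image` (matrix with `channel_label` attribute).
#' @export
channel_image <- function(pixels,
                          channel_label = c("ex405", "ex488", "autofluor430_470")) {
  channel_label <- match.arg(channel_label)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  pixels[pixels < 0] <- 0
  structure(pixels, channel_label = channel_label, class = c("channel_image", "matrix"))
}

channel_label <- function(img) attr(img, "channel_label")

#' Correction parameters for channel preprocessing
#'
#' @param background_405,background_488 Scalar background intensities (>= 0),
#'   typically measured from a sensor-free region such as the vacuole (see
#'   [estimate_background()]).
#' @param bleed_coefficient Dimensionless coefficient k mapping the
#'   autofluorescence-channel intensity into the 405-excited sensor channel
#'   (>= 0; see [estimate_bleed_coefficient()]).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(background_405 = 0, background_488 = 0,
                              bleed_coefficient = 0) {
  vals <- c(background_405, background_488, bleed_coefficient)
  if (!all(is.finite(vals)) || any(vals < 0))
    stop("backgrounds and bleed_coefficient must be finite and >= 0")
  structure(list(background_405 = background_405,
                 background_488 = background_488,
                 bleed_coefficient = bleed_coefficient),
            class = "correction_params")
}

#' Mean background over a region of interest
#'
#' @param img A [channel_image()] or numeric matrix.
#' @param roi Logical matrix of the same shape selecting background pixels.
#' @return Scalar mean intensity.
#' @export
estimate_background <- function(img, roi) {
  if (!identical(dim(img), dim(roi))) stop("roi shape must match image shape")
  if (!any(roi)) stop("empty background ROI")
  mean(img[roi])
}

#' Estimate the autofluorescence bleed coefficient
#'
#' Least-squares regression through the origin of the (background-corrected)
#' 405-excited signal on the autofluorescence channel, intended for
#' sensor-free control images where all 405 nm signal is bleed-through.
#'
#' @param ch405 405-excited channel of a non-sensor control image.
#' @param autofluor Matching autofluorescence channel image.
#' @param background_405 Background to subtract from `ch405` first.
#' @return Scalar bleed coefficient k (clamped at 0).
#' @export
estimate_bleed_coefficient <- function(ch405, autofluor, background_405 = 0) {
  if (!identical(dim(ch405), dim(autofluor)))
    stop("channel shapes differ")
  y <- as.numeric(ch405) - background_405
  x <- as.numeric(autofluor)
  if (sum(x^2) == 0) stop("autofluorescence channel is identically zero")
  max(0, sum(x * y) / sum(x^2))
}

# 3x3 mean filter with shrink-to-valid edge handling: each output pixel is the
# mean of its in-bounds 3x3 neighborhood. Vectorized via shifted zero-padded
# sums divided by in-bounds neighbor counts.
mean_filter3 <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  ones <- matrix(1, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rd <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    cd <- max(1, 1 - dc):min(nc, nc - dc)
    acc[rd, cd] <- acc[rd, cd] + mat[rs, cs]
    cnt[rd, cd] <- cnt[rd, cd] + ones[rs, cs]
  }
  acc / cnt
}

#' Preprocess a sensor channel
#'
#' Applies, in order: subtraction of the scalar channel background; for the
#' `ex405` channel only, subtraction of `k * autofluor` (autofluorescence
#' bleeding into the 405 nm channel); clipping at zero; and 3x3 spatial mean
#' filtering with edge pixels averaged over their in-bounds neighborhood.
#'
#' @param img A [channel_image()] (`ex405` or `ex488`).
#' @param params A [correction_params()].
#' @param autofluor Optional autofluorescence [channel_image()] (same shape);
#'   used only for the `ex405` channel.
#' @return A preprocessed `channel_image` with the same label.
#' @export
preprocess_channel <- function(img, params, autofluor = NULL) {
  stopifnot(inherits(img, "channel_image"), inherits(params, "correction_params"))
  lbl <- channel_label(img)
  bg <- switch(lbl, ex405 = params$background_405,
               ex488 = params$background_488,
               stop("preprocess_channel expects an ex405 or ex488 channel"))
  x <- unclass(img) - bg
  if (lbl == "ex405" && !is.null(autofluor)) {
    if (!identical(dim(autofluor), dim(img)))
      stop(sprintf("shape mismatch: channel %s vs autofluorescence %s",
                   paste(dim(img), collapse = "x"),
                   paste(dim(autofluor), collapse = "x")))
    x <- x - params$bleed_coefficient * unclass(autofluor)
  }
  x[x < 0] <- 0
  channel_image(mean_filter3(x), lbl)
}

#' Robust default mask threshold for the 488 channel
#'
#' Background plus three times a robust estimate of the per-pixel noise. The
#' noise is estimated from the dimmest quartile of pixels (sensor-free
#' background in a typical field of view) as the median absolute deviation;
#' since [preprocess_channel()] has already averaged 3x3 neighborhoods, the
#' observed deviation is scaled back by 3 to recover the pre-smoothing pixel
#' noise. The residual level of those background pixels (positive after
#' clipping at zero) is included in the threshold.
#'
#' @param ch488 Preprocessed 488 channel.
#' @param background Residual background level (0 after preprocessing).
#' @return Scalar intensity threshold.
#' @export
default_mask_threshold <- function(ch488, background = 0) {
  v <- as.numeric(ch488)
  lo <- v[v <= stats::quantile(v, 0.25)]
  med <- stats::median(lo)
  background + med + 3 * 3 * stats::mad(lo, center = med)
}

#' Pixel-wise ratio map
#'
#' Computes the per-pixel ratio I405/I488 wherever the 488-excited intensity
#' reaches `min_intensity_488`; all other pixels are masked out and never
#' evaluated (no division by zero). Both channels are expected to be
#' preprocessed ([preprocess_channel()]) and share their shape.
#'
#' @param ch405,ch488 Preprocessed channel images.
#' @param min_intensity_488 Masking threshold on the 488 channel; see
#'   [default_mask_threshold()].
#' @return An object of class `ratio_image`: list with `ratio` (matrix, `NA`
#'   outside the mask), `mask` (logical matrix) and `provenance`.
#' @export
ratio_map <- function(ch405, ch488, min_intensity_488) {
  if (!identical(dim(ch405), dim(ch488)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(ch405), collapse = "x"),
                 paste(dim(ch488), collapse = "x")))
  mask <- unclass(ch488) >= min_intensity_488 & unclass(ch488) > 0
  ratio <- matrix(NA_real_, nrow(ch405), ncol(ch405))
  if (!any(mask)) {
    warning("no sensor pixels: mask is empty")
  } else {
    ratio[mask] <- unclass(ch405)[mask] / unclass(ch488)[mask]
  }
  structure(list(ratio = ratio, mask = mask,
                 provenance = list(min_intensity_488 = min_intensity_488)),
            class = "ratio_image")
}

#' Summary statistics of a ratio image over a region of interest
#'
#' Reports the plain mean and median ratio, the log10 of the mean ratio
#' (`log10_mean_ratio`) and the per-pixel mean of log10 ratios
#' (`mean_log10_ratio`) -- both log quantities are reported because ratio data
#' are conventionally log10-transformed before plotting.
#'
#' @param rimg A [ratio_map()] result.
#' @param roi Optional logical matrix; defaults to the full sensor mask.
#' @return A list with `mean_ratio`, `median_ratio`, `log10_mean_ratio`,
#'   `mean_log10_ratio` and `n_pixels`.
#' @export
roi_summary <- function(rimg, roi = NULL) {
  stopifnot(inherits(rimg, "ratio_image"))
  sel <- rimg$mask
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(rimg$mask))) stop("roi shape must match image")
    sel <- sel & roi
  }
  if (!any(sel)) stop("empty intersection of ROI and sensor mask")
  r <- rimg$ratio[sel]
  list(mean_ratio = mean(r),
       median_ratio = stats::median(r),
       log10_mean_ratio = log10(mean(r)),
       mean_log10_ratio = mean(log10(r)),
       n_pixels = sum(sel))
}

#' Pseudocolor rendering of a ratio image
#'
#' Hue runs linearly in the ratio from 240 degrees (blue, fully reduced, ratio
#' <= `r_min`) to 0 degrees (red, fully oxidized, ratio >= `r_max`), with the
#' limits set by the in situ calibration. Ratios outside the limits saturate
#' at the end colors (hue never wraps). Masked-out pixels are black.
#'
#' @param rimg A [ratio_map()] result.
#' @param r_min,r_max Calibration limits (R_red, R_ox), `r_min < r_max`.
#' @param brightness Optional matrix (e.g. summed channel intensity) scaling
#'   pixel value; rescaled to its own maximum. Default constant brightness.
#' @return An array `nrow x ncol x 3` of RGB values in \[0, 1\].
#' @export
pseudocolor <- function(rimg, r_min, r_max, brightness = NULL) {
  stopifnot(inherits(rimg, "ratio_image"))
  if (!is.finite(r_min) || !is.finite(r_max) || r_min >= r_max)
    stop("invalid limits: need r_min < r_max")
  frac <- (rimg$ratio - r_min) / (r_max - r_min)
  frac <- pmin(pmax(frac, 0), 1)   # frac first: pmin/pmax keep its dim
  hue_deg <- 240 * (1 - frac)          # 240 (blue) -> 0 (red)
  val <- matrix(1, nrow(frac), ncol(frac))
  if (!is.null(brightness)) {
    if (!identical(dim(brightness), dim(frac))) stop("brightness shape mismatch")
    mx <- max(brightness)
    if (mx > 0) val <- pmin(pmax(brightness / mx, 0), 1)
  }
  ok <- rimg$mask & is.finite(hue_deg)
  out <- array(0, dim = c(nrow(frac), ncol(frac), 3))
  if (any(ok)) {
    cols <- grDevices::hsv(h = hue_deg[ok] / 360, s = 1, v = val[ok])
    rgb <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[ok] <- rgb[ch, ]
      out[, , ch] <- plane
    }
  }
  out
}

#' Redox-based topology assay (ReTA) readout
#'
#' Classifies the orientation of a membrane protein from the oxidation state
#' of N- and C-terminal roGFP2 fusions: a terminus reading reduced
#' (OxD < `reduced_cutoff`) faces the cytosol, one reading oxidized
#' (OxD > `oxidized_cutoff`) faces the ER lumen. N cytosolic with C luminal is
#' a type II membrane protein; the mirror case type I; two termini on the
#' same side are inconclusive.
#'
#' @param oxd_N,oxd_C Summary OxD of the N- and C-terminal fusion.
#' @param reduced_cutoff,oxidized_cutoff Classification cutoffs.
#' @return A list with `topology` (one of `"type II"`, `"type I"`,
#'   `"not membrane-spanning / inconclusive"`, `"ambiguous N-terminus"`,
#'   `"ambiguous C-terminus"`, `"ambiguous"`), and per-terminus face calls.
#' @examples
#' reta_readout(0.05, 0.95)  # type II, as for the ER oxidoreductins
#' @export
reta_readout <- function(oxd_N, oxd_C, reduced_cutoff = 0.25,
                         oxidized_cutoff = 0.75) {
  face <- function(oxd) {
    if (oxd < reduced_cutoff) "cytosolic"
    else if (oxd > oxidized_cutoff) "luminal"
    else "ambiguous"
  }
  fN <- face(oxd_N); fC <- face(oxd_C)
  topology <-
    if (fN == "ambiguous" && fC == "ambiguous") "ambiguous"
    else if (fN == "ambiguous") "ambiguous N-terminus"
    else if (fC == "ambiguous") "ambiguous C-terminus"
    else if (fN == "cytosolic" && fC == "luminal") "type II"
    else if (fN == "luminal" && fC == "cytosolic") "type I"
    else "not membrane-spanning / inconclusive"
  list(topology = topology, n_terminus = fN, c_terminus = fC)
}
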