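# Pixel-wise ratio imaging: preprocessing, masking, summaries, pseudocolor,
# topology readout.

test_that("preprocess_channel applies background, bleed and 3x3 smoothing", {
  p <- correction_params(background_405 = 10, background_488 = 10)
  img <- channel_image(matrix(10, 8, 8), "ex405")
  expect_equal(px(preprocess_channel(img, p)), matrix(0, 8, 8))

  # background + bleed on a constant image: smoothing of a constant is identity
  p2 <- correction_params(background_405 = 2, bleed_coefficient = 0.4)
  img2 <- channel_image(matrix(12, 6, 6), "ex405")
  af <- channel_image(matrix(5, 6, 6), "autofluor430_470")
  expect_equal(px(preprocess_channel(img2, p2, af)), matrix(8, 6, 6))

  # bleed is never applied to the 488 channel
  img3 <- channel_image(matrix(12, 6, 6), "ex488")
  expect_equal(px(preprocess_channel(img3, correction_params(0, 2, 0.4), af)),
               matrix(10, 6, 6))

  # single bright pixel spreads to a 3x3 patch of 1 at an interior position
  m <- matrix(0, 9, 9); m[5, 5] <- 9
  got <- preprocess_channel(channel_image(m, "ex405"), correction_params())
  expect_equal(px(got)[4:6, 4:6], matrix(1, 3, 3))
  expect_equal(sum(got), 9)

  expect_error(preprocess_channel(img2, p2, channel_image(matrix(5, 3, 3),
                                                          "autofluor430_470")),
               "shape mismatch")
})

test_that("3x3 mean filter equals the brute-force double loop on random images", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rexp(256), 16, 16)
    got <- preprocess_channel(channel_image(m, "ex488"), correction_params())
    expect_equal(px(got), brute_mean_filter3(m), tolerance = 1e-12)
  }
})

test_that("ratio_map masks on the 488 channel and never divides by zero", {
  ch405 <- channel_image(matrix(4, 5, 5), "ex405")
  ch488 <- channel_image(matrix(8, 5, 5), "ex488")
  r <- ratio_map(ch405, ch488, min_intensity_488 = 1)
  expect_true(all(r$mask))
  expect_equal(r$ratio, matrix(0.5, 5, 5))

  z <- channel_image(matrix(0, 5, 5), "ex488")
  expect_warning(r0 <- ratio_map(ch405, z, 1), "no sensor pixels")
  expect_false(any(r0$mask))
  expect_true(all(is.na(r0$ratio)))

  expect_error(ratio_map(ch405, channel_image(matrix(1, 4, 5), "ex488"), 1),
               "shape mismatch")
})

test_that("roi_summary reports both log conventions", {
  rimg <- ratio_map(channel_image(matrix(1, 4, 4), "ex405"),
                    channel_image(matrix(1, 4, 4), "ex488"), 0.5)
  s <- roi_summary(rimg)
  expect_equal(s$mean_ratio, 1)
  expect_equal(s$log10_mean_ratio, 0)
  expect_equal(s$n_pixels, 16)

  m405 <- matrix(c(0.5, 2, 0, 0), 2, 2)
  m488 <- matrix(c(1, 1, 0, 0), 2, 2)
  rimg2 <- ratio_map(channel_image(m405, "ex405"),
                     channel_image(m488, "ex488"), 0.5)
  s2 <- roi_summary(rimg2)
  expect_equal(s2$mean_ratio, 1.25)
  expect_equal(s2$mean_log10_ratio, 0)     # mean of log10(0.5), log10(2)
  expect_equal(s2$n_pixels, 2)

  rimg10 <- ratio_map(channel_image(matrix(10, 3, 3), "ex405"),
                      channel_image(matrix(1, 3, 3), "ex488"), 0.5)
  expect_equal(roi_summary(rimg10)$log10_mean_ratio, 1)

  expect_error(roi_summary(rimg2, roi = matrix(FALSE, 2, 2)),
               "empty intersection")
})

test_that("pseudocolor anchors hue at the calibration limits and saturates", {
  mk <- function(v) ratio_map(channel_image(matrix(v, 2, 2), "ex405"),
                              channel_image(matrix(1, 2, 2), "ex488"), 0.5)
  r_min <- 0.5; r_max <- 1.05
  blue <- pseudocolor(mk(r_min), r_min, r_max)
  red <- pseudocolor(mk(r_max), r_min, r_max)
  mid <- pseudocolor(mk((r_min + r_max) / 2), r_min, r_max)
  expect_equal(blue[1, 1, ], c(0, 0, 1))          # hue 240
  expect_equal(red[1, 1, ], c(1, 0, 0))           # hue 0
  expect_equal(mid[1, 1, ], c(0, 1, 0))           # hue 120
  # clipping saturates, never wraps
  expect_equal(pseudocolor(mk(0.1), r_min, r_max)[1, 1, ], c(0, 0, 1))
  expect_equal(pseudocolor(mk(9), r_min, r_max)[1, 1, ], c(1, 0, 0))
  # masked pixels are black
  expect_warning(empty <- ratio_map(channel_image(matrix(1, 2, 2), "ex405"),
                                    channel_image(matrix(0, 2, 2), "ex488"), 1))
  expect_equal(pseudocolor(empty, r_min, r_max), array(0, c(2, 2, 3)))
  expect_error(pseudocolor(mk(1), 1.05, 0.5), "invalid limits")
})

test_that("bleed coefficient estimation recovers a known k on control images", {
  set.seed(3)
  af <- matrix(runif(400, 0, 200), 20, 20)
  k <- 0.37
  ch405 <- k * af + 30
  expect_equal(estimate_bleed_coefficient(ch405, af, background_405 = 30), k,
               tolerance = 1e-9)
  expect_equal(estimate_background(channel_image(matrix(1:16, 4, 4), "ex405"),
                                   matrix(TRUE, 4, 4)), 8.5)
})

test_that("reta_readout classifies membrane topology from terminal OxD values", {
  expect_equal(reta_readout(0.05, 0.95)$topology, "type II")
  expect_equal(reta_readout(0.95, 0.05)$topology, "type I")
  expect_equal(reta_readout(0.5, 0.95)$topology, "ambiguous N-terminus")
  expect_equal(reta_readout(0.95, 0.5)$topology, "ambiguous C-terminus")
  expect_equal(reta_readout(0.1, 0.1)$topology,
               "not membrane-spanning / inconclusive")
  expect_equal(reta_readout(0.1, 0.1)$n_terminus, "cytosolic")
})
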