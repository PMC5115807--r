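test_that("axis profiles are the centroid row and column", {
  rep_ch <- matrix(runif(121), 11, 11)
  mar_ch <- matrix(runif(121), 11, 11)
  img <- two_channel_image(rep_ch, mar_ch, 0.133, centroid = c(6, 6))
  pr <- extract_axis_profiles(img)
  expect_equal(pr$horizontal$reporter_profile, rep_ch[6, ])
  expect_equal(pr$vertical$marker_profile, mar_ch[, 6])
  expect_length(pr$horizontal$marker_profile, 11)

  bad <- two_channel_image(rep_ch, mar_ch, 0.133, centroid = c(20, 6))
  expect_error(extract_axis_profiles(bad), class = "narpump_range_error")
})

test_that("a symmetric ring gives identical horizontal and vertical profiles", {
  img <- gen_soma_image(targeting_mode = "membrane", seed = 1)
  pr <- extract_axis_profiles(img)
  expect_equal(pr$horizontal$marker_profile, pr$vertical$marker_profile)
  # membrane crossings: exactly two interior local maxima on the marker
  m <- pr$horizontal$marker_profile
  peaks <- which(diff(sign(diff(m))) == -2) + 1
  expect_length(peaks, 2)
})

test_that("membrane bounds follow the half-maximum scan rule", {
  expect_identical(membrane_bounds(c(0, 1, 5, 10, 5, 2, 2, 5, 10, 5, 1, 0)),
                   c(3L, 10L))
  prof <- c(10, rep(0, 8), 10)
  expect_identical(membrane_bounds(prof), c(1L, 10L))
  expect_error(membrane_bounds(rep(0, 10)),
               class = "narpump_degenerate_error")
})

test_that("overlapping index behaves at the correlation extremes", {
  seg <- exp(-((1:21) - 11)^2 / 18)  # smooth unimodal
  pair_h <- intensity_profile_pair(seg, seg, "horizontal", bounds = c(1, 21))
  pair_v <- intensity_profile_pair(seg, seg, "vertical", bounds = c(1, 21))
  res <- overlapping_index(list(pair_h, pair_v))
  lag0 <- res$per_lag_coefficients[c("horizontal.+0", "vertical.+0")]
  expect_equal(unname(lag0), c(1, 1))
  expect_true(res$index > 0 && res$index <= 1)

  anti <- intensity_profile_pair(5 - 2 * seg, seg, "horizontal",
                                 bounds = c(1, 21))
  res2 <- overlapping_index(list(anti))
  expect_equal(unname(res2$per_lag_coefficients["horizontal.+0"]), -1)
  expect_lt(res2$index, 0)
})

test_that("index is invariant to affine gain and symmetric under swap", {
  set.seed(42)
  a <- random_profile(25)
  b <- random_profile(25)
  p1 <- intensity_profile_pair(a, b, "horizontal", bounds = c(1, 25))
  p2 <- intensity_profile_pair(a, b, "vertical", bounds = c(1, 25))
  base <- overlapping_index(list(p1, p2))

  scaled <- overlapping_index(list(
    intensity_profile_pair(3 * a + 2, b, "horizontal", bounds = c(1, 25)),
    intensity_profile_pair(3 * a + 2, b, "vertical", bounds = c(1, 25))))
  expect_equal(scaled$index, base$index, tolerance = 1e-12)

  swapped <- overlapping_index(list(
    intensity_profile_pair(b, a, "horizontal", bounds = c(1, 25)),
    intensity_profile_pair(b, a, "vertical", bounds = c(1, 25))))
  expect_equal(swapped$index, base$index, tolerance = 1e-12)
  # lag k coefficient becomes the lag -k coefficient
  expect_equal(unname(swapped$per_lag_coefficients["horizontal.+2"]),
               unname(base$per_lag_coefficients["horizontal.-2"]))
})

test_that("fuzzed indices always lie within [-1, 1]", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(12:40, 1)
    p <- intensity_profile_pair(random_profile(n), random_profile(n),
                                "horizontal", bounds = c(1, n))
    idx <- overlapping_index(list(p))$index
    expect_true(idx >= -1 && idx <= 1)
  }
})

test_that("targeting phenotypes separate as expected", {
  mem <- measure_overlap(gen_soma_image(targeting_mode = "membrane",
                                        noise_sd = 0.02, seed = 13))
  intra <- measure_overlap(gen_soma_image(targeting_mode = "intracellular",
                                          noise_sd = 0.02, seed = 13))
  expect_gt(mem$index, 0.3)
  expect_lt(intra$index, 0.1)
  expect_length(mem$per_lag_coefficients, 14)
})

test_that("degenerate and short segments are refused", {
  flat <- intensity_profile_pair(rep(1, 20), random_profile(20),
                                 "horizontal", bounds = c(1, 20))
  expect_error(overlapping_index(list(flat)),
               class = "narpump_degenerate_error")
  short <- intensity_profile_pair(random_profile(6), random_profile(6),
                                  "horizontal", bounds = c(1, 6))
  expect_error(overlapping_index(list(short)),
               class = "narpump_range_error")
})

test_that("a far-off pixel pitch triggers the lag-span warning", {
  p <- intensity_profile_pair(random_profile(20), random_profile(20),
                              "horizontal", bounds = c(1, 20))
  expect_warning(overlapping_index(list(p), pixel_pitch = 0.3), "0.4 um")
  expect_silent(overlapping_index(list(p), pixel_pitch = 0.4 / 3))
})

test_that("TIFF round trip preserves the overlapping index", {
  img <- gen_soma_image(targeting_mode = "mixed", noise_sd = 0.01, seed = 2)
  path <- tempfile(fileext = ".tif")
  write_two_channel_tiff(img, path)
  back <- read_two_channel_tiff(path, pixel_pitch = img$pixel_pitch)
  back$centroid <- img$centroid
  expect_equal(measure_overlap(back)$index, measure_overlap(img)$index,
               tolerance = 1e-3)  # 16-bit quantization only
  unlink(path)
})
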