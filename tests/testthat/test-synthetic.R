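test_that("all generators are deterministic under a fixed seed", {
  expect_identical(gen_photocurrent_trace(4, 0.25, noise_sd = 0.05, seed = 9),
                   gen_photocurrent_trace(4, 0.25, noise_sd = 0.05, seed = 9))
  expect_identical(gen_dose_response(2.4, 8.3, c(1, 3, 6), noise_cv = 0.05,
                                     n_cells = 3, seed = 9),
                   gen_dose_response(2.4, 8.3, c(1, 3, 6), noise_cv = 0.05,
                                     n_cells = 3, seed = 9))
  expect_identical(gen_iv_series(4e-3, c(-80, -40, 0), 0.05, seed = 9),
                   gen_iv_series(4e-3, c(-80, -40, 0), 0.05, seed = 9))
  expect_identical(gen_soma_image(targeting_mode = "intracellular",
                                  noise_sd = 0.02, seed = 9),
                   gen_soma_image(targeting_mode = "intracellular",
                                  noise_sd = 0.02, seed = 9))
  expect_identical(gen_silencing_experiment(sweep_count = 2,
                                            sample_rate = 2000, seed = 9),
                   gen_silencing_experiment(sweep_count = 2,
                                            sample_rate = 2000, seed = 9))
  expect_identical(gen_ph_trace("KCl", seed = 9),
                   gen_ph_trace("KCl", seed = 9))
})

test_that("photocurrent generator round-trips through feature extraction", {
  tr <- gen_photocurrent_trace(4.0, 0.25, noise_sd = 0)
  f <- extract_features(baseline_subtract(tr))
  expect_equal(f$i_p, 4.0, tolerance = 0.02)
  expect_equal(f$i_ss, 1.0, tolerance = 0.02)
  expect_equal(f$inactivation_ratio, 0.75, tolerance = 0.02)

  flat <- gen_photocurrent_trace(3.0, 1.0, noise_sd = 0)
  expect_equal(extract_features(baseline_subtract(flat))$inactivation_ratio,
               0, tolerance = 0.01)
  expect_error(gen_photocurrent_trace(4, 0.25, tau_act = -1),
               class = "narpump_param_error")
})

test_that("dose-response generator evaluates the saturating models", {
  d <- gen_dose_response(2.4, 8.3, irradiances = 8.3, noise_cv = 0)[[1]]
  expect_equal(d$response, 1.2)  # half-saturation point

  # at the threshold the suppression term vanishes
  ds <- gen_dose_response(2.8, 18.7, irradiances = 10, noise_cv = 0,
                          suppression = c(2.3, 10, 38.1))[[1]]
  expect_equal(ds$response, 2.8 * 10 / (10 + 18.7))

  # above threshold, direct evaluation of the composite formula
  d99 <- gen_dose_response(2.8, 18.7, irradiances = 99, noise_cv = 0,
                           suppression = c(2.3, 10, 38.1))[[1]]
  expect_equal(d99$response,
               2.8 * 99 / (99 + 18.7) - 2.3 * (99 - 10) / ((99 - 10) + 38.1))
  expect_error(gen_dose_response(2.4, 8.3, numeric(0)),
               class = "narpump_param_error")
})

test_that("I-V generator is linear with unit anchor at 0 mV", {
  iv <- gen_iv_series(7.5e-3, c(-80, -40, 0))
  expect_equal(iv$current[iv$voltage == -80], 0.4)
  expect_equal(iv$current[iv$voltage == 0], 1)
  flat <- gen_iv_series(0, c(-80, -40, -20, 0))
  expect_equal(flat$current, rep(1, 4))
  expect_error(gen_iv_series(7.5e-3, c(-80, -40)),
               class = "narpump_param_error")
})

test_that("soma image generator produces the two targeting phenotypes", {
  expect_error(gen_soma_image(image_size = 21, membrane_radius = 3),
               class = "narpump_param_error")
  mem <- gen_soma_image(targeting_mode = "membrane", seed = 5)
  expect_true(measure_overlap(mem)$index > 0)
  intra <- gen_soma_image(targeting_mode = "intracellular", seed = 5)
  expect_lt(measure_overlap(intra)$index, 0.1)
})

test_that("silencing generator honours zone rates and ground truth", {
  ex <- gen_silencing_experiment(sweep_count = 4, silenced_rate = 0,
                                 sample_rate = 2000, seed = 21)
  gt <- unlist(ex$ground_truth)
  in_light <- gt >= ex$light_epoch[1] & gt < ex$light_epoch[2]
  expect_identical(sum(in_light), 0L)

  dark <- gen_silencing_experiment(sweep_count = 30, light_epoch = NULL,
                                   baseline_rate = 8, sample_rate = 1000,
                                   seed = 22)
  zs <- zone_rates(spike_raster(dark$ground_truth, "Dark"), 0:12)
  # without light the rate is uniform across zones in expectation
  expect_true(all(abs(zs$rate - mean(zs$rate)) < 0.35 * mean(zs$rate)))
  expect_error(gen_silencing_experiment(baseline_rate = -1),
               class = "narpump_param_error")
})

test_that("pH generator drifts in the direction set by the ionic condition", {
  expect_gt(ph_slope(gen_ph_trace("NaCl", seed = 1))$slope, 0)
  expect_lt(ph_slope(gen_ph_trace("KCl", seed = 2))$slope, 0)
  s_off <- ph_slope(gen_ph_trace("KCl", cccp = FALSE, seed = 3))
  s_on <- ph_slope(gen_ph_trace("KCl", cccp = TRUE, seed = 4))
  expect_lt(abs(s_on$slope), abs(s_off$slope))
})
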