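grid7 <- c(1, 3, 6, 12, 25, 50, 99)

test_that("fit_mm recovers the printed hyperbolas from noiseless data", {
  for (p in list(c(5.12, 39.3), c(2.4, 8.3))) {
    d <- dose_response(grid7, p[1] * grid7 / (grid7 + p[2]))
    fit <- fit_mm(d)
    expect_equal(fit$imax, p[1], tolerance = 1e-6)
    expect_equal(fit$kd, p[2], tolerance = 1e-6)
    expect_false(fit$boundary)
  }
})

test_that("fit_mm flags saturated (constant) data as a boundary fit", {
  fit <- fit_mm(dose_response(grid7, rep(2.0, 7)))
  expect_true(fit$boundary)
  expect_equal(fit$imax, 2.0, tolerance = 1e-2)
})

test_that("fit_mm kd is invariant to rescaling responses", {
  y <- 2.4 * grid7 / (grid7 + 8.3) * (1 + c(.02, -.01, .03, 0, -.02, .01, 0))
  f1 <- fit_mm(dose_response(grid7, y))
  f2 <- fit_mm(dose_response(grid7, 5 * y))
  expect_equal(f2$kd, f1$kd, tolerance = 1e-6)
  expect_equal(f2$imax, 5 * f1$imax, tolerance = 1e-6)
})

test_that("fit_mm rejects underdetermined data", {
  expect_error(fit_mm(dose_response(c(1, 5), c(0.2, 0.7))),
               class = "narpump_data_error")
})

test_that("composite fit recovers the printed suppressed model exactly", {
  x <- seq(0.5, 99, by = 0.5)
  y <- 2.8 * x / (x + 18.7) - 2.3 * pmax(x - 10, 0) / (pmax(x - 10, 0) + 38.1)
  fit <- fit_suppressed_mm(dose_response(x, y), threshold = 10)
  expect_equal(fit$imax, 2.8, tolerance = 1e-4)
  expect_equal(fit$kd1, 18.7, tolerance = 1e-4)
  expect_equal(fit$supp_amp, 2.3, tolerance = 1e-4)
  expect_equal(fit$kd2, 38.1, tolerance = 1e-4)
})

test_that("composite model nests the plain hyperbola", {
  y <- 2.4 * grid7 / (grid7 + 8.3)
  fit <- fit_suppressed_mm(dose_response(grid7, y), threshold = 10)
  plain <- fit_mm(dose_response(grid7, y))
  expect_lt(fit$supp_amp, 1e-3)
  expect_equal(fit$imax, plain$imax, tolerance = 1e-3)
  expect_equal(fit$kd1, plain$kd, tolerance = 1e-3)
  # continuity: at x = T the suppression term is exactly zero
  expect_equal(suppressed_mm_response(10, 2.8, 18.7, 2.3, 10, 38.1),
               mm_response(10, 2.8, 18.7))
})

test_that("composite fit demands points above the threshold", {
  x <- c(1, 2, 4, 6, 8)
  expect_error(fit_suppressed_mm(dose_response(x, 2 * x / (x + 5)),
                                 threshold = 10),
               class = "narpump_fit_error")
})

test_that("restricted-range fitting filters the grid and recovers kd", {
  d <- dose_response(grid7, 2.1 * grid7 / (grid7 + 6.2))
  fit <- fit_kd_restricted(d, max_irradiance = 12)
  expect_identical(fit$n, 4L)        # {1, 3, 6, 12}
  expect_identical(fit$n_excluded, 3L)
  expect_equal(fit$kd, 6.2, tolerance = 1e-6)
  expect_error(fit_kd_restricted(d, max_irradiance = 0.5),
               class = "narpump_data_error")
})

test_that("per-cell fits summarize as mean and SEM", {
  cells <- gen_dose_response(2.4, 8.3, grid7, noise_cv = 0.05,
                             n_cells = 8, seed = 5)
  fits <- lapply(cells, fit_mm)
  s <- summarize_fits(fits, "kd")
  expect_identical(s$n, 8L)
  expect_equal(s$mean, 8.3, tolerance = 0.2)
  expect_true(s$sem > 0)
})
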