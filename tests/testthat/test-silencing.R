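test_that("spike detection crosses once per spike and honours refractoriness", {
  fs <- 10000
  time <- seq(0, 1, by = 1 / fs)
  v <- rep(-60, length(time))
  spike <- function(v, t0) {          # 2-ms triangular event
    idx <- which(time >= t0 & time < t0 + 0.002)
    ph <- (time[idx] - t0) / 0.001
    v[idx] <- v[idx] + 80 * ifelse(ph <= 1, ph, pmax(2 - ph, 0))
    v
  }
  v <- spike(spike(spike(v, 0.2), 0.5), 0.8)
  tr <- voltage_trace(time, v, injection_epoch = c(0, 1))
  st <- detect_spikes(tr, threshold = -10)
  expect_length(st, 3)
  expect_equal(st, c(0.2, 0.5, 0.8), tolerance = 2e-3)

  flat <- voltage_trace(time, rep(-65, length(time)), c(0, 1))
  expect_length(detect_spikes(flat), 0)

  # two crossings 1 ms apart with a 2-ms refractory count once
  v2 <- rep(-60, length(time))
  v2[time >= 0.300 & time < 0.3005] <- 0
  v2[time >= 0.301 & time < 0.3015] <- 0
  tr2 <- voltage_trace(time, v2, c(0, 1))
  expect_length(detect_spikes(tr2, refractory = 0.002), 1)
  expect_length(detect_spikes(tr2, refractory = 0.0005), 2)

  bad <- voltage_trace(time, c(NA, v[-1]), c(0, 1))
  expect_error(detect_spikes(bad), class = "narpump_data_error")
})

test_that("detection recovers >= 95% of generated ground truth", {
  ex <- gen_silencing_experiment(sweep_count = 10, baseline_rate = 10,
                                 sample_rate = 5000, seed = 31)
  ras <- raster_from_sweeps(ex$sweeps, protocol = "Light")
  hits <- 0; total <- 0; false_pos <- 0
  for (s in seq_along(ex$sweeps)) {
    gt <- ex$ground_truth[[s]]; det <- ras$spike_times[[s]]
    total <- total + length(gt)
    hits <- hits + sum(vapply(gt, function(t) any(abs(det - t) < 0.003),
                              logical(1)))
    false_pos <- false_pos +
      sum(vapply(det, function(t) !any(abs(gt - t) < 0.003), logical(1)))
  }
  expect_gte(hits / total, 0.95)
  expect_equal(false_pos, 0)
})

test_that("zone binning counts and conserves spikes", {
  ras <- spike_raster(list(c(0.5, 1.5, 2.5)), "Dark")
  zs <- zone_rates(ras, 0:3)
  expect_equal(as.numeric(zs$counts), c(1, 1, 1))
  expect_identical(zs$n_outside, 0L)

  empty <- zone_rates(spike_raster(list(numeric(0), numeric(0)), "Dark"), 0:3)
  expect_equal(empty$rate, rep(0, 3))

  # conservation across random rasters
  set.seed(5)
  for (i in 1:20) {
    st <- sort(runif(sample(0:30, 1), 0, 12))
    zs <- zone_rates(spike_raster(list(st), "Dark"), 0:12)
    expect_identical(sum(zs$counts) + zs$n_outside, length(st))
  }

  ex <- gen_silencing_experiment(sweep_count = 6, silenced_rate = 0,
                                 sample_rate = 2000, seed = 32)
  zs <- zone_rates(spike_raster(ex$ground_truth, "Light"), 0:12)
  light_zones <- which(0:11 >= ex$light_epoch[1] & 1:12 <= ex$light_epoch[2])
  expect_equal(zs$rate[light_zones], rep(0, length(light_zones)))
})

test_that("light/dark ratios hit the defining cases", {
  st <- list(c(0.5, 3.2, 6.1, 11.5), c(0.7, 5.5))
  same <- zone_rates(spike_raster(st, "Light"), 0:12)
  same_d <- zone_rates(spike_raster(st, "Dark"), 0:12)
  r <- light_dark_ratios(same, same_d)
  expect_equal(r$ratio, rep(1, 3))

  silenced <- zone_rates(spike_raster(list(c(0.5, 11.5)), "Light"), 0:12)
  r2 <- light_dark_ratios(silenced, same_d)
  expect_equal(r2$ratio[r2$window == "during"], 0)

  nodark <- zone_rates(spike_raster(list(numeric(0)), "Dark"), 0:12)
  r3 <- light_dark_ratios(same, nodark)
  expect_true(all(!r3$defined))
  expect_true(all(is.na(r3$ratio)))

  other <- zone_rates(spike_raster(st, "Dark"), 0:6)
  expect_error(light_dark_ratios(same, other), class = "narpump_data_error")
})

test_that("rebound shows up as an elevated after/dark ratio", {
  light <- gen_silencing_experiment(sweep_count = 40, baseline_rate = 10,
                                    rebound_rate = 20, silenced_rate = 0,
                                    sample_rate = 1000, seed = 33)
  dark <- gen_silencing_experiment(sweep_count = 40, baseline_rate = 10,
                                   light_epoch = NULL,
                                   sample_rate = 1000, seed = 34)
  zl <- zone_rates(spike_raster(light$ground_truth, "Light"), 0:12)
  zd <- zone_rates(spike_raster(dark$ground_truth, "Dark"), 0:12)
  r <- light_dark_ratios(zl, zd)
  after <- r$ratio[r$window == "after"]
  expect_gt(after, 1.4)   # Poisson expectation 2 with thinning losses
  expect_lt(after, 2.6)
  reb <- detect_rebound(zl, light$light_epoch)
  expect_true(reb$rebound)
})

test_that("the late-onset irradiation window variant is available", {
  w <- silencing_windows("late_onset")
  expect_equal(w$during, c(2, 11))
  expect_equal(silencing_windows()$during, c(1, 11))
})
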