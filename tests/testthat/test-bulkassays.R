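# Plate quantification: calibration, rate windows, percent scales, the 4PL
# fit and site-IQ attribution.

test_that("H2O2 calibration slope is exact and validated", {
  cal <- calibrate_h2o2(c(100, 200), c(300, 600))
  expect_equal(cal$slope, 3)
  expect_error(calibrate_h2o2(100, 300), "at least 2")
  expect_warning(calibrate_h2o2(c(100, 200, 300), c(300, 250, 900)),
                 "non-monotone")
  # doubling spikes doubles steps, slope unchanged
  cal2 <- calibrate_h2o2(c(200, 400), c(600, 1200))
  expect_equal(cal2$slope, cal$slope)
})

test_that("calibration slope is recovered within 2% at 1% noise", {
  wells <- data.frame(well = "C1", role = "calibration", condition = "cal",
                      true_h2o2_rate = NA, background_rate = 0,
                      s1qel_concentration = NA)
  tr <- plate_truth(wells, calibration_spikes = c(100, 100, 100),
                    spike_cycles = c(6, 12, 18), calibration_slope = 3,
                    noise_sigma = 0.01 * 300, seed = 5)
  tab <- simulate_plate(tr)
  f <- tab$fluorescence_afu
  steps <- c(mean(f[6:11]) - mean(f[1:5]), mean(f[12:17]) - mean(f[1:5]),
             mean(f[18:25]) - mean(f[1:5]))
  cal <- calibrate_h2o2(c(100, 200, 300), steps)
  expect_equal(cal$slope, 3, tolerance = 0.02)
})

test_that("rate regression uses the inclusive cycle window and exact slopes", {
  cyc <- 1:25
  trace <- data.frame(cycle = cyc, seconds = (cyc - 1) * 80,
                      fluorescence_afu = 500 + 7 * (cyc - 1) * 80 / 60)
  r <- fit_rate(trace)
  expect_equal(r$slope, 7, tolerance = 1e-9)
  expect_equal(r$n_points, 14)  # cycles 5-18 inclusive
  # offset invariance
  trace2 <- trace; trace2$fluorescence_afu <- trace2$fluorescence_afu + 1234
  expect_equal(fit_rate(trace2)$slope, r$slope, tolerance = 1e-12)
  # pure noise: slope within 2 SE of zero
  set.seed(9)
  noise <- data.frame(cycle = cyc, seconds = (cyc - 1) * 80,
                      fluorescence_afu = rnorm(25, 500, 3))
  rn <- fit_rate(noise)
  expect_lt(abs(rn$slope), 2 * rn$se)
  expect_error(fit_rate(trace, c(1, 30)), "outside")
})

test_that("percent-of-vehicle and percent-reduction scales are exact", {
  expect_equal(percent_vehicle(10, c(10, 10)), 100)
  expect_equal(percent_vehicle(2, c(10, 12), sample_background = 2,
                               vehicle_background = 1), 0)
  expect_error(percent_vehicle(5, c(1, 1), vehicle_background = 2), "positive")
  # generator-stored suppression factor 0.5 -> 50%
  veh <- c(20, 21, 19); smp <- 0.5 * mean(veh)
  expect_equal(percent_vehicle(smp, veh), 50, tolerance = 1e-9)

  expect_equal(percent_reduction(c(10, 55, 100), 10, 100)[1:3],
               c(0, 50, 100))
  expect_equal(as.numeric(percent_reduction(120, 10, 100)), 122.2222,
               tolerance = 1e-4)  # unclipped overshoot
  expect_error(percent_reduction(1, 5, 5), "exceed")
})

test_that("noiseless 4PL parameters are recovered to 1e-6 relative", {
  conc <- c(0, 10, 30, 100, 300, 1000, 3000)
  rate <- fourpl_curve(conc, top = 100, bottom = 20, ic50 = 150, hill = 1.2)
  fit <- fit_4pl(conc, rate)
  co <- coef(fit)
  expect_equal(unname(co["top"]), 100, tolerance = 1e-6)
  expect_equal(unname(co["bottom"]), 20, tolerance = 1e-6)
  expect_equal(unname(co["ic50"]), 150, tolerance = 1e-6)
  expect_equal(unname(co["hill"]), 1.2, tolerance = 1e-6)
  # midpoint identity
  expect_equal(unname(predict(fit, data.frame(conc = 150))), 60,
               tolerance = 1e-6)
})

test_that("orientation is normalized: rising curves report bottom <= top", {
  conc <- c(0, 10, 30, 100, 300, 1000, 3000)
  rising <- fourpl_curve(conc, top = 20, bottom = 100, ic50 = 150, hill = 1.2)
  fit <- fit_4pl(conc, rising)
  co <- coef(fit)
  expect_lte(co[["bottom"]], co[["top"]])
  expect_equal(unname(co["ic50"]), 150, tolerance = 1e-4)
})

test_that("IC50 is recovered within 10% from noisy triplicate titrations", {
  truth <- list(top = 100, bottom = 20, ic50 = 150, hill = 1.2)
  conc1 <- c(0, 10, 30, 100, 300, 1000, 3000)
  wells <- data.frame(well = sprintf("S%02d", 1:21),
                      role = "sample", condition = "t",
                      true_h2o2_rate = NA, background_rate = 0,
                      s1qel_concentration = rep(conc1, each = 3))
  tr <- plate_truth(wells, noise_sigma = 0, fourpl = truth, seed = 3)
  tab <- simulate_plate(tr)
  rates <- vapply(split(tab, tab$well), function(w) fit_rate(w)$slope / 3,
                  numeric(1))
  concs <- vapply(split(tab, tab$well), function(w) w$s1qel_concentration[1],
                  numeric(1))
  # Monte-Carlo: the typical (median) recovery error stays within 10%
  set.seed(31)
  errs <- vapply(1:5, function(i) {
    noisy <- rates * (1 + rnorm(length(rates), 0, 0.05))
    abs(coef(fit_4pl(concs, noisy))[["ic50"]] - 150) / 150
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("residual-rate subtraction isolates the site-specific signal", {
  conc <- c(0, 10, 30, 100, 300, 1000, 3000)
  rate <- fourpl_curve(conc, top = 100, bottom = 20, ic50 = 150, hill = 1.2)
  fit <- fit_4pl(conc, rate, subtract_residual = TRUE)
  expect_true(fit$residual_subtracted)
  expect_equal(fit$subtracted_rate, 20, tolerance = 1e-5)
  co <- coef(fit)
  expect_equal(unname(co["bottom"]), 0)
  expect_equal(unname(co["ic50"]), 150, tolerance = 1e-4)
})

test_that("site-IQ attribution floors at zero and checks units", {
  expect_equal(site_iq_rate(100, 40), 60)
  expect_equal(site_iq_rate(40, 40), 0)
  expect_warning(out <- site_iq_rate(30, 40), "floored")
  expect_equal(out, 0)
  expect_error(site_iq_rate(10, 5, units = c("pmol/min", "afu/min")),
               "unit mismatch")
  # generator-stored site share 0.6
  expect_equal(site_iq_rate(100, 40) / 100, 0.6)
})
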