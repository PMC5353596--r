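test_that("ratiometric normalization divides out the reference channel", {
  tr <- sensor_trace(times = 0:5,
                     sensor = c(100, 102, 104, 106, 108, 110),
                     reference = rep(50, 6))
  expect_equal(ratiometric_normalize(tr)[1:3], c(2.00, 2.04, 2.08))

  same <- sensor_trace(0:5, sensor = 3:8, reference = 3:8)
  expect_equal(ratiometric_normalize(same), rep(1, 6))

  expect_error(sensor_trace(0:5, sensor = c(1, 1, 1, 1, 1, 1),
                            reference = c(1, 1, 0, 1, 1, 1)),
               class = "picoresp_data_error")
})

test_that("pure reference drift leaves the analytic drift factor in the ratio", {
  s_drift <- sensor_model(noise_sd = 0, drift_per_min = 0.02)
  s_clean <- sensor_model(noise_sd = 0, drift_per_min = 0)
  tr_d <- simulate_sensor_trace(1, sensor = s_drift, duration = 20, dt = 1,
                                seed = 1)
  tr_c <- simulate_sensor_trace(1, sensor = s_clean, duration = 20, dt = 1,
                                seed = 1)
  observed <- ratiometric_normalize(tr_d)
  drift_free <- ratiometric_normalize(tr_c)
  # Drift applied to the reference only does not cancel: the residual is
  # exactly 1 / (1 + drift * t).
  expect_equal(observed, drift_free / (1 + 0.02 * tr_d$times),
               tolerance = 1e-12)
})

test_that("sliding average matches a brute-force clipped-window mean", {
  expect_equal(sliding_average(rep(4.2, 10), 5), rep(4.2, 10))
  expect_equal(sliding_average(1:5, 5)[3], 3)

  x <- withr::with_seed(8, rnorm(23))
  got <- sliding_average(x, 5)
  oracle <- vapply(seq_along(x), function(i) {
    h <- min(2, i - 1, length(x) - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
  expect_equal(got, oracle)

  expect_error(sliding_average(1:10, 4), class = "picoresp_config_error")
  expect_error(sliding_average(1:3, 5), class = "picoresp_config_error")
})

test_that("Stern-Volmer inversion and two-point calibration are consistent", {
  cal <- calibration_model(ksv = 0.005, i0 = 2)
  expect_equal(as.numeric(calibrate(rep(2, 5), cal)), rep(0, 5))
  expect_equal(as.numeric(calibrate(1, cal)), 200)

  fit <- two_point_calibrate(2, 1, 200)
  expect_equal(fit$i0, 2)
  expect_equal(fit$ksv, 0.005)
  expect_equal(fit$provenance, "two-point")
  # the fitted model passes through both anchors
  expect_equal(as.numeric(calibrate(2, fit)), 0)
  expect_equal(as.numeric(calibrate(1, fit)), 200)

  expect_error(two_point_calibrate(1, 1, 200),
               class = "picoresp_data_error")
  expect_error(two_point_calibrate(2, 1, 0),
               class = "picoresp_config_error")

  expect_warning(out <- calibrate(c(2, 2.2), cal), "clamped")
  expect_equal(as.numeric(out), c(0, 0))
  expect_equal(attr(out, "n_clamped"), 1)

  # forward/inverse round trip against the simulator
  s <- noiseless_setup()
  tr <- simulate_sensor_trace(2, s$geom, s$sensor, duration = 12, dt = 0.5,
                              seed = 1)
  expect_equal(as.numeric(calibrate(ratiometric_normalize(tr), s$cal)),
               attr(tr, "true_concentration"), tolerance = 1e-12)
})

test_that("extract_ocr recovers closed-form slopes and applies units", {
  s <- noiseless_setup()
  tr <- simulate_sensor_trace(1, s$geom, s$sensor, duration = 25, dt = 0.5,
                              seed = 1)
  res <- extract_ocr(tr, s$cal, smooth = FALSE)
  expect_equal(res$ocr_fmol_min, 1, tolerance = 1e-9)
  expect_equal(res$slope_uM_min, -1 / 0.14, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$respirer_class, "respiring")
  expect_true(res$sealed)

  # flat trace at non-zero oxygen: a non-respirer
  flat <- trace_from_concentration(0:9, rep(100, 10))
  res <- extract_ocr(flat, s$cal, smooth = FALSE)
  expect_equal(res$ocr_fmol_min, 0)
  expect_equal(res$respirer_class, "non-respiring")

  # unit contract: slope -1 uM/min in a 140 pL well is 0.14 fmol/min
  lin <- trace_from_concentration(0:19, 200 - 1 * (0:19))
  res <- extract_ocr(lin, s$cal, smooth = FALSE)
  expect_equal(res$slope_uM_min, -1, tolerance = 1e-10)
  expect_equal(res$ocr_fmol_min, 0.14, tolerance = 1e-10)
})

test_that("extraction is ratiometric and matches the closed-form OLS slope", {
  s <- noiseless_setup()
  sm_noisy <- sensor_model(noise_sd = 0.01)
  # OCR chosen so the trace never reaches the depletion floor within 25 min
  tr <- simulate_sensor_trace(0.8, s$geom, sm_noisy, duration = 25, dt = 0.5,
                              seed = 21)

  res <- extract_ocr(tr, s$cal, smooth = FALSE)
  scaled <- tr
  scaled$sensor <- tr$sensor * 37.5
  scaled$reference <- tr$reference * 37.5
  expect_equal(extract_ocr(scaled, s$cal, smooth = FALSE)$ocr_fmol_min,
               res$ocr_fmol_min, tolerance = 1e-12)

  # OLS slope equals sum((t - tbar)(C - Cbar)) / sum((t - tbar)^2)
  conc <- as.numeric(calibrate(ratiometric_normalize(tr), s$cal))
  tt <- tr$times
  manual <- sum((tt - mean(tt)) * (conc - mean(conc))) /
    sum((tt - mean(tt))^2)
  expect_equal(res$slope_uM_min, manual, tolerance = 1e-10)
})

test_that("estimator error grows monotonically with sensor noise", {
  s <- noiseless_setup()
  rmse_at <- function(noise_sd) {
    errs <- vapply(1:30, function(i) {
      sm <- sensor_model(noise_sd = noise_sd)
      tr <- simulate_sensor_trace(2, s$geom, sm, duration = 25, dt = 0.5,
                                  seed = 100 + i)
      extract_ocr(tr, s$cal)$ocr_fmol_min - 2
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  rmse <- vapply(c(0, 0.01, 0.04), rmse_at, numeric(1))
  expect_true(all(diff(rmse) >= 0))
})

test_that("degenerate traces raise extraction errors", {
  s <- noiseless_setup()
  # fast respirer sampled too slowly: < 5 points before the floor
  fast <- simulate_sensor_trace(10, s$geom, s$sensor, duration = 30, dt = 1,
                                seed = 1)
  expect_error(extract_ocr(fast, s$cal), class = "picoresp_data_error")

  # fully depleted from the start
  dead <- trace_from_concentration(0:9, rep(0, 10))
  expect_error(extract_ocr(dead, s$cal, smooth = FALSE),
               class = "picoresp_data_error")
})

test_that("seal QC passes intact wells and catches leaks", {
  flat <- trace_from_concentration(0:19, rep(150, 20))
  expect_true(qc_seal(flat, tolerance = 0.01))

  rising <- sensor_trace(0:10, sensor = 100 * seq(1, 1.10, length.out = 11),
                         reference = rep(100, 11))
  expect_false(qc_seal(rising, tolerance = 0.02))

  # leaky twin under an external nitrogen purge vs its hermetic twin
  s <- noiseless_setup()
  leaky <- simulate_sensor_trace(0, s$geom, s$sensor, duration = 30, dt = 1,
                                 seed = 1, leak_rate = 0.05, external_o2 = 0)
  intact <- simulate_sensor_trace(0, s$geom, s$sensor, duration = 30, dt = 1,
                                  seed = 1)
  expect_false(qc_seal(leaky, tolerance = 0.02))
  expect_true(qc_seal(intact, tolerance = 0.02))
})
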