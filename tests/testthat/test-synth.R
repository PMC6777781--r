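test_that("the click template produces a gated tone with the right support", {
  ck <- make_click(click_template())
  expect_length(ck, 144) # 3 ms at 48 kHz
  expect_equal(spectral_peak(ck, 48000), 3500, tolerance = 200 / 3500)
  expect_lte(max(abs(ck)), 1)
  # duration and band edge cases
  short <- make_click(click_template(duration_ms = 2))
  expect_length(short, 96)
  expect_equal(make_click(click_template(amplitude = 0)), rep(0, 144))
  expect_error(click_template(center_frequency_khz = 30), "Nyquist")
  expect_error(click_template(duration_ms = 0.05), "too short")
})

test_that("echo delay and reflected level follow the propagation laws", {
  prop <- propagation_config()
  expect_equal(echo_delay(2.0, prop) * 1000, 4.0 / 343 * 1000)
  expect_equal(echo_delay(2.0, prop) * 1000, 11.66, tolerance = 1e-3)
  # linearity with slope 2 / c
  d <- seq(0.7, 3.9, by = 0.1)
  expect_equal(diff(echo_delay(d, prop)) / 0.1, rep(2 / 343, length(d) - 1))
  # level anchored at the crossover and falling per doubling
  expect_equal(reflected_level(1.2, prop), 76)
  expect_equal(reflected_level(2.4, prop), 76 - 11)
  expect_equal(reflected_level(0.6, prop), 76 + 11)
})

test_that("same-seed state subtraction isolates the reflection exactly", {
  prop <- propagation_config()
  refl <- synthesize_recording(2.0, "reflecting", prop = prop, seed = 5)
  non <- synthesize_recording(2.0, "nonreflecting", prop = prop, seed = 5)
  resid <- refl$samples - non$samples
  # the residual is a pure scaled, delayed click
  delay_samp <- round(echo_delay(2.0, prop) * 48000)
  expect_true(all(resid[seq_len(delay_samp)] == 0))
  expect_true(all(resid[(delay_samp + 145):length(resid)] == 0))
  gain <- 10^((reflected_level(2.0, prop) - 76) / 20)
  expect_equal(resid[delay_samp + (1:144)],
               gain * make_click(click_template()))
  # non-reflecting recordings carry no reflection energy at all
  quiet <- synthesize_recording(2.0, "nonreflecting", prop = quiet_prop())
  expect_true(all(quiet$samples[(144 + 1):length(quiet$samples)] == 0))
})

test_that("recordings are reproducible and the calibration is batch-constant", {
  a <- synthesize_recording(1.5, "reflecting", seed = 6)
  b <- synthesize_recording(1.5, "reflecting", seed = 6)
  expect_identical(a$samples, b$samples)
  cals <- vapply(c(0.7, 1.5, 3.9), function(d) {
    synthesize_recording(d, "reflecting", seed = 1)$cal_db
  }, numeric(1))
  expect_equal(diff(range(cals)), 0)
  expect_error(synthesize_recording(0.5, "reflecting"), "rail")
  expect_error(synthesize_recording(2, "reflecting", duration = 0.02),
               "too short")
})

test_that("recordings and series survive the WAV + manifest round trip", {
  rec <- synthesize_recording(2.2, "reflecting", seed = 12)
  path <- withr::local_tempfile(fileext = ".wav")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$distance, 2.2)
  expect_equal(back$disk_state, "reflecting")
  expect_equal(back$sample_rate, 48000)
  # analysis of the round-tripped recording matches the in-memory one
  expect_equal(analyze_recording(back)[, -(1:2)],
               analyze_recording(rec)[, -(1:2)], tolerance = 1e-5)
  dir <- withr::local_tempdir()
  recs <- synthesize_series(distances = c(1.0, 2.0), replicates = 2,
                            seed = 3)
  write_measurement_series(recs, dir)
  expect_length(list.files(dir, pattern = "\\.wav$"), 8)
  back_set <- read_measurement_series(dir)
  expect_length(back_set, 8)
  expect_s3_class(analyze_series(back_set), "echo_series")
})
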