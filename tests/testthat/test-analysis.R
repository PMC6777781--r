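test_that("running SPL is flat for a steady tone and linear in gain", {
  fs <- 48000
  t <- (0:(fs / 10 - 1)) / fs
  x <- sin(2 * pi * 1000 * t) # integer cycles per 1-ms window
  tr <- running_spl(x, sample_rate = fs, cal_db = 0)
  expect_lt(diff(range(tr$spl_db)), 0.1)
  # RMS of a unit sinusoid is 1/sqrt(2), i.e. about -3.01 dB
  expect_equal(mean(tr$spl_db), 20 * log10(1 / sqrt(2)), tolerance = 1e-3)
  tr10 <- running_spl(10 * x, sample_rate = fs, cal_db = 0)
  expect_equal(tr10$spl_db, tr$spl_db + 20, tolerance = 1e-9)
  expect_error(running_spl(x[1:10], sample_rate = fs), "window")
  expect_error(running_spl(x), "sample_rate")
})

test_that("maxima extraction finds constructed impulses and their spacing", {
  fs <- 48000
  x <- numeric(fs %/% 20) # 50 ms
  x[round(0.001 * fs)] <- 1 # impulse at 1 ms
  x[round(0.011 * fs)] <- 0.5 # impulse at 11 ms
  m <- extract_maxima(running_spl(x, sample_rate = fs, cal_db = 0))
  expect_equal(m$ici_ms, 10, tolerance = 0.05)
  expect_gte(m$direct_time_ms, 0)
  expect_lt(m$direct_time_ms, 3)
  expect_gte(m$reflected_time_ms, 3)
  expect_lt(m$reflected_time_ms, 30)
  # impulse levels: a lone impulse in a 48-sample window
  expect_equal(m$direct_db, 10 * log10(1 / 48), tolerance = 1e-6)
  expect_equal(m$reflected_db, 10 * log10(0.25 / 48), tolerance = 1e-6)
  expect_error(extract_maxima(running_spl(x[1:150], sample_rate = fs,
                                          cal_db = 0)),
               "reflected window")
})

test_that("a reflecting recording shows the echo bump where geometry says", {
  rec <- synthesize_recording(2.2, "reflecting", seed = 2)
  m <- extract_maxima(running_spl(rec))
  expect_equal(m$ici_ms, 2 * 2.2 / 343 * 1000, tolerance = 0.15)
  expect_equal(m$reflected_time_ms, 12.8, tolerance = 1.2)
  # overall gain does not move the ICI
  rec10 <- rec
  rec10$samples <- rec10$samples * 10
  expect_equal(extract_maxima(running_spl(rec10))$ici_ms, m$ici_ms)
})

test_that("slope fits recover the generator geometry and scaling laws", {
  ser <- analyze_series(quick_series())
  expect_equal(fit_ici_slope(ser), 2 / 343 * 1000, tolerance = 0.005)
  # doubling the sound speed halves the slope; at 686 m/s echoes from
  # distances below about 1.03 m arrive inside the direct window, so the
  # fit is restricted to farther distances
  fast <- quick_series(distances = seq(1.5, 3.9, by = 0.4),
                       prop = propagation_config(sound_speed = 686))
  expect_equal(fit_ici_slope(analyze_series(fast), c(1.5, 3.9)),
               2 / 686 * 1000, tolerance = 0.01)
  expect_error(fit_ici_slope(ser[1:2, ]), "at least 3")
})

test_that("level-decay fits round-trip the generator's anchored law", {
  for (slope in c(11, 6, 0)) {
    prop <- quiet_prop(reflected_decay_per_doubling_db = slope)
    ser <- analyze_series(
      quick_series(distances = seq(0.7, 2.0, by = 0.1), prop = prop))
    expect_equal(fit_level_decay(ser), slope, tolerance = 0.05)
  }
  # with the tail disabled the analyzer recovers R(d) to 0.1 dB everywhere
  prop <- quiet_prop()
  ser <- analyze_series(quick_series(distances = seq(0.7, 3.9, by = 0.1),
                                     prop = prop))
  refl <- ser[ser$disk_state == "reflecting", ]
  expect_lt(max(abs(refl$reflected_max_db -
                      reflected_level(refl$distance_m, prop))), 0.1)
  expect_lt(max(abs(refl$direct_max_db - 76)), 0.1)
})

test_that("combined level is an incoherent power sum", {
  expect_equal(combined_level(76, 76), 76 + 10 * log10(2), tolerance = 1e-9)
  expect_equal(combined_level(76, -Inf), 76)
  expect_equal(combined_level(76, 56), 76.0432, tolerance = 1e-4)
  expect_equal(combined_level(56, 76), combined_level(76, 56))
})

test_that("non-reflecting series are flagged low-confidence, echoes are not", {
  recs <- synthesize_series(distances = c(1.0, 2.0, 3.0),
                            disk_states = c("reflecting", "nonreflecting"),
                            seed = 9)
  ser <- analyze_series(recs)
  refl <- ser[ser$disk_state == "reflecting", ]
  expect_true(all(!refl$low_confidence))
  # the non-reflecting "reflected" maximum is just the room decay level
  non <- ser[ser$disk_state == "nonreflecting", ]
  expect_lt(max(non$reflected_max_db), 50)
  # shrink the reflection below the decay + 3 dB and the flag must raise
  weak <- propagation_config(crossover_distance = 0.05)
  ser2 <- analyze_series(synthesize_series(
    distances = 3.9, disk_states = c("reflecting", "nonreflecting"),
    prop = weak, seed = 9))
  expect_true(ser2$low_confidence[ser2$disk_state == "reflecting"])
})
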