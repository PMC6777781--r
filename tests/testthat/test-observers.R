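test_that("unbiased percent correct follows the equal-variance model", {
  expect_equal(proportion_correct_unbiased(1.0), pnorm(0.5))
  expect_equal(round(100 * proportion_correct_unbiased(1.0)), 69)
  expect_equal(proportion_correct_unbiased(0), 0.5)
  expect_equal(proportion_correct_unbiased(2.0), pnorm(1.0))
  expect_error(proportion_correct_unbiased(-0.1), "non-negative")
  # strictly increasing in d'
  dp <- seq(0, 5, by = 0.1)
  expect_true(all(diff(proportion_correct_unbiased(dp)) > 0))
})

test_that("observer response probabilities match the SDT model", {
  obs <- sdt_observer(3, ref_distance = 0.7, decay_per_m = 1)
  expect_equal(dprime_at(obs, 0.7), 3)
  expect_equal(dprime_at(obs, 2.7), 1)
  expect_equal(dprime_at(obs, 1.7), 2)
  expect_equal(dprime_at(obs, 3.9), 0) # 3 - 3.2, floored at zero
  expect_equal(yes_prob(obs, 2.7, "reflecting"), pnorm(0.5))
  expect_equal(yes_prob(obs, 2.7, "nonreflecting"), pnorm(-0.5))
  # zero sensitivity: yes-rate 0.5 in either state
  flat <- sdt_observer(0)
  expect_equal(yes_prob(flat, 1, "reflecting"), 0.5)
  expect_equal(yes_prob(flat, 1, "nonreflecting"), 0.5)
  # criterion shifts both rates the same way
  biased <- sdt_observer(1, decay_per_m = 0, criterion = 0.3)
  expect_equal(yes_prob(biased, 1, "reflecting"), pnorm(0.5 - 0.3))
  expect_equal(yes_prob(biased, 1, "nonreflecting"), pnorm(-0.5 - 0.3))
  # custom sensitivity profile
  custom <- sdt_observer(2, dprime_fun = function(d) 4 / d)
  expect_equal(dprime_at(custom, 2), 2)
  expect_equal(dprime_crossing(custom, 2), 2, tolerance = 1e-4)
  # crossing outside the search interval is reported as NA
  expect_true(is.na(dprime_crossing(custom, 1)))
})

test_that("empirical rates recover the configured model", {
  set.seed(12)
  n <- 40000
  obs <- sdt_observer(2, ref_distance = 0.7, decay_per_m = 0.5,
                      criterion = 0.2)
  d <- 1.7 # d' = 1.5 here
  hits <- mean(replicate(n, respond(obs, d, "reflecting") == "yes"))
  fas <- mean(replicate(n, respond(obs, d, "nonreflecting") == "yes"))
  h_true <- yes_prob(obs, d, "reflecting")
  f_true <- yes_prob(obs, d, "nonreflecting")
  expect_lt(abs(hits - h_true), 3 * sqrt(h_true * (1 - h_true) / n))
  expect_lt(abs(fas - f_true), 3 * sqrt(f_true * (1 - f_true) / n))
  # d' recovered through the inverse-normal transform
  dhat <- qnorm(hits) - qnorm(fas)
  expect_equal(dhat, dprime_at(obs, d), tolerance = 0.1)
  # random responder yes-rate tracks p_yes regardless of state
  ro <- random_observer(0.3)
  yr <- mean(replicate(n, respond(ro, 2, "reflecting") == "yes"))
  expect_lt(abs(yr - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("the linear d' crossing is analytic and validated", {
  obs <- sdt_observer(3, ref_distance = 0.7, decay_per_m = 1)
  expect_equal(dprime_crossing(obs, 1.0), 2.7)
  expect_true(is.na(dprime_crossing(sdt_observer(3, decay_per_m = 0), 1)))
})

test_that("the staircase drift-zero sits where H - F = 0.5 for c = 0", {
  cfg <- staircase_config()
  obs <- sdt_observer(3, ref_distance = 0.7, decay_per_m = 1)
  d0 <- siam_target_distance(obs, cfg)
  dp_eq <- 2 * qnorm(0.75) # H - F = 0.5 at c = 0
  expect_equal(d0, 0.7 + (3 - dp_eq), tolerance = 1e-4)
  h <- yes_prob(obs, d0, "reflecting")
  f <- yes_prob(obs, d0, "nonreflecting")
  expect_equal(h - f, 0.5, tolerance = 1e-4)
  # degenerate drifts return the bound the walk is pushed towards
  expect_warning(lo <- siam_target_distance(random_observer(0.5), cfg))
  expect_equal(lo, cfg$d_min)
  expect_warning(hi <- siam_target_distance(sdt_observer(50), cfg))
  expect_equal(hi, cfg$d_max)
})
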