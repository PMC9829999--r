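test_that("saccade detector recovers synthetic endpoints", {
  # parameterised over amplitude, including an oblique movement
  for (amp in c(5, 15, 30, 50, 80)) {
    tr <- min_jerk_trace(az = amp, el = 0)
    res <- detect_saccade_endpoint(tr)
    expect_true(res$saccade)
    expect_lt(abs(res$endpoint_az - amp), 0.5,
              label = paste("endpoint error at amplitude", amp))
  }
  tr2 <- min_jerk_trace(az = 30, el = -20)
  res2 <- detect_saccade_endpoint(tr2)
  expect_lt(abs(res2$endpoint_az - 30), 0.5)
  expect_lt(abs(res2$endpoint_el - -20), 0.5)
})

test_that("sub-threshold or absent movements yield no saccade", {
  # constant position
  flat <- head_trace(seq(0, 500, by = 5), rep(3, 101), rep(0, 101))
  expect_false(detect_saccade_endpoint(flat)$saccade)
  # peak velocity ~ 1.875 * amp / dur: amp 3 deg over 300 ms -> 18.75 deg/s
  slow <- min_jerk_trace(az = 3, move_ms = 300)
  expect_false(detect_saccade_endpoint(slow)$saccade)
  # just above threshold is detected
  fast <- min_jerk_trace(az = 4, move_ms = 300)  # peak 25 deg/s
  expect_true(detect_saccade_endpoint(fast)$saccade)
})

test_that("p_EAS counts implant-side responses among heard trials", {
  all_right <- trial_row(runif(10, -80, 80), rep(40, 10))
  expect_equal(peas(all_right), 1)

  half <- trial_row(rep(0, 10), rep(c(30, -30), 5))
  expect_equal(peas(half), 0.5)

  counts <- trial_row(rep(0, 64), c(rep(20, 16), rep(-20, 48)))
  expect_equal(peas(counts), 0.25)

  # zero-azimuth responses contribute half a count
  ties <- trial_row(rep(0, 4), c(0, 0, 50, -50))
  expect_equal(peas(ties), 0.5)

  # unheard trials are excluded; all-unheard is undefined
  mixed <- rbind(trial_row(0, 40), trial_row(0, NA, heard = FALSE))
  expect_equal(peas(mixed), 1)
  expect_true(is.na(peas(trial_row(0, NA, heard = FALSE))))

  # flipping every response maps p to 1 - p
  set.seed(4)
  d <- trial_row(runif(50, -80, 80), runif(50, -80, 80))
  flipped <- d; flipped$response_az <- -flipped$response_az
  expect_equal(peas(flipped), 1 - peas(d))
})

test_that("RMS error matches its definition and invariants", {
  perfect <- trial_row(c(-40, 0, 40), c(-40, 0, 40))
  expect_equal(rms_error(perfect), 0)

  two <- trial_row(c(0, 0), c(30, 40))
  expect_equal(rms_error(two), sqrt((900 + 1600) / 2))
  expect_equal(rms_error(two), 35.36, tolerance = 1e-3)

  # invariant under trial relabeling
  set.seed(9)
  d <- trial_row(runif(30, -80, 80), runif(30, -80, 80))
  expect_equal(rms_error(d[sample(30), ]), rms_error(d))

  # straight-ahead responder converges on the analytic chance level
  set.seed(10)
  big <- trial_row(runif(2e5, -80, 80), rep(0, 2e5))
  expect_equal(rms_error(big), chance_error_straight_ahead(c(-80, 80)),
               tolerance = 0.005)

  # 2-D variant adds the elevation component
  d2 <- trial_row(0, 30, target_el = 0, response_el = 40)
  expect_equal(rms_error(d2, two_dim = TRUE), 50)
})

test_that("chance-level references follow their closed forms", {
  expect_equal(chance_error_straight_ahead(c(-80, 80)), 46.19,
               tolerance = 1e-3)
  expect_equal(round(chance_error_straight_ahead(c(-80, 80))), 46)
  expect_equal(chance_error_straight_ahead(c(-54, 54)),
               sqrt(108^2 / 12), tolerance = 1e-12)
  expect_equal(chance_error_straight_ahead(c(0, 0)), 0)
  # off-centre ranges pick up the midpoint term
  expect_equal(chance_error_straight_ahead(c(20, 60)),
               sqrt(40^2 / 12 + 40^2), tolerance = 1e-12)

  expect_equal(chance_error_random(c(-1, 1)), sqrt(2 * 4 / 12),
               tolerance = 1e-12)
  # halving the range halves the error
  expect_equal(chance_error_random(c(-40, 40)),
               chance_error_random(c(-80, 80)) / 2)
  # Monte-Carlo cross-check of the independent-uniform closed form
  set.seed(11)
  mc <- sqrt(mean((runif(1e6, -80, 80) - runif(1e6, -80, 80))^2))
  expect_equal(chance_error_random(c(-80, 80)), mc, tolerance = 0.5 / 65)
})

test_that("percentile bootstrap interval properties hold", {
  # identical observations -> zero-width interval at the value
  b0 <- bootstrap_ci(rep(5, 20), seed = 1)
  expect_equal(c(b0$lo, b0$hi), c(5, 5))

  # mean of N(0,1), n = 500: interval ~ +/- 1.96 / sqrt(n)
  set.seed(2)
  x <- rnorm(500)
  b <- bootstrap_ci(x, n_boot = 2000, seed = 3)
  expect_lt(b$lo, 0); expect_gt(b$hi, 0)
  expect_equal(b$hi - b$lo, 2 * 1.96 / sqrt(500), tolerance = 0.15)

  # same seed -> identical output; interval contains the plug-in statistic
  b2 <- bootstrap_ci(x, n_boot = 2000, seed = 3)
  expect_identical(b, b2)
  expect_gte(b$estimate, b$lo); expect_lte(b$estimate, b$hi)

  # works with data.frame resampling and an arbitrary statistic
  d <- trial_row(runif(40, -80, 80), runif(40, -80, 80))
  bp <- bootstrap_ci(d, statistic = peas, n_boot = 200, seed = 4)
  expect_true(bp$lo >= 0 && bp$hi <= 1)

  expect_error(bootstrap_ci(numeric(0)), "no observations")
})
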