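test_that("generated audiograms respect construction rules", {
  params <- list(ha_base = 30, ha_corner = 1000, ha_slope = 30,
                 eas_base = 40, eas_corner = 500, eas_slope = 35,
                 electric_mean = 37)
  ags <- generate_audiograms(params, seed = 3)
  # capped everywhere
  for (ag in ags) expect_true(all(ag$thresholds <= 100))
  # ski slope: high-frequency unaided thresholds much worse than low
  expect_gt(ags$ha_unaided$thresholds[11] - ags$ha_unaided$thresholds[1], 30)
  # aiding helps at low frequencies, never harms
  expect_true(all(ags$ha_aided$thresholds <= ags$ha_unaided$thresholds))
  expect_lt(ags$ha_aided$thresholds[3], ags$ha_unaided$thresholds[3])
  # electric aided audiogram roughly flat around its mean
  expect_lt(diff(range(ags$eas_electric$thresholds)), 25)
  # deterministic under a fixed seed
  expect_identical(generate_audiograms(params, seed = 3)$ha_unaided,
                   ags$ha_unaided)
})

test_that("condition mapping composes the correct device states", {
  params <- list(ha_base = 30, ha_corner = 1000, ha_slope = 30,
                 eas_base = 40, eas_corner = 500, eas_slope = 35,
                 electric_mean = 37)
  ags <- generate_audiograms(params, seed = 3)
  ca <- easbias:::condition_audiograms(ags, "A-EA")
  expect_identical(ca$ha, ags$ha_aided)
  # electric-on implanted ear takes the best of electric and acoustic
  best <- combine_eas_thresholds(ags$eas_acoustic_aided, ags$eas_electric)
  expect_equal(ca$eas$thresholds, best$thresholds)
  # A-XA: electric off, acoustic aid on both sides
  ca2 <- easbias:::condition_audiograms(ags, "A-XA")
  expect_identical(ca2$eas, ags$eas_acoustic_aided)
  # X-EX: everything off except the implant; open canals
  ca3 <- easbias:::condition_audiograms(ags, "X-EX")
  expect_identical(ca3$ha, ags$ha_unaided)
})

test_that("trial scheduler emits the designed counts", {
  cfg <- cohort_config(n_listeners = 1, seed = 5)
  listener <- generate_listener("S1", cfg, seed = 5)
  trials <- generate_trials(listener, cfg, seed = 6)
  counts <- table(trials$condition)
  expect_true(all(counts == 64))
  expect_equal(nrow(trials), 64 * 5)
  # bands interleaved evenly: 16 trials per band per condition
  per_band <- table(trials$condition, trials$band)
  expect_true(all(per_band == 16))
  # targets inside the design ranges; responses only on heard trials
  expect_true(all(trials$target_az >= -80 & trials$target_az <= 80))
  expect_true(all(trials$target_el >= -45 & trials$target_el <= 60))
  expect_true(all(is.na(trials$response_az[!trials$heard])))
  expect_true(all(!is.na(trials$response_az[trials$heard])))
})

test_that("simulated response sides follow the logistic model", {
  cfg <- cohort_config(n_listeners = 1, conditions = "A-EA",
                       bands = "MF", n_locations = 2500, n_repeats = 4,
                       seed = 8)
  listener <- generate_listener("S1", cfg, seed = 8)
  # pin the asymmetry to a known value instead of the audiogram-derived one
  asym <- data.frame(participant_id = "S1", condition = "A-EA",
                     band = "MF", delta_h = 25, audibility_eas = 30,
                     audibility_ha = 5, inaudible_both = FALSE,
                     ha_on = TRUE)
  trials <- generate_trials(listener, cfg, asym = asym, seed = 9)
  expect_equal(nrow(trials), 1e4)
  p_hat <- mean(trials$response_az > 0)
  p_true <- peas_predict(25, listener$omega, listener$theta, ha_on = TRUE)
  expect_lt(abs(p_hat - p_true), 0.02)
})

test_that("inaudible cells produce unheard trials", {
  cfg <- cohort_config(n_listeners = 1, conditions = "A-XA", bands = "HF",
                       n_locations = 4, n_repeats = 4, seed = 12)
  listener <- generate_listener("S1", cfg, seed = 12)
  asym <- data.frame(participant_id = "S1", condition = "A-XA",
                     band = "HF", delta_h = 0, audibility_eas = 0,
                     audibility_ha = 0, inaudible_both = TRUE,
                     ha_on = TRUE)
  trials <- generate_trials(listener, cfg, asym = asym, seed = 13)
  expect_true(all(!trials$heard))
  expect_true(all(is.na(trials$response_az)))
  # and such cells are dropped from the model cell table
  expect_equal(nrow(cells_from_trials(trials, asym)), 0)
})

test_that("synthetic head traces round-trip through the saccade detector", {
  trial <- data.frame(response_az = 30, response_el = 0, heard = TRUE)
  tr <- generate_head_trace(trial, seed = 2)
  res <- detect_saccade_endpoint(tr)
  expect_true(res$saccade)
  expect_lt(abs(res$endpoint_az - 30), 0.5)
  expect_lt(abs(res$endpoint_el - 0), 0.5)
  # deterministic under a fixed seed
  tr2 <- generate_head_trace(trial, seed = 2)
  expect_identical(tr, tr2)
  # unheard trials have no trace
  expect_error(generate_head_trace(
    data.frame(response_az = NA, response_el = NA, heard = FALSE)),
    "unheard")
})

test_that("cohort asymmetry spans both signs across conditions", {
  co <- generate_cohort(cohort_config(seed = 3))
  a <- co$asymmetry[!co$asymmetry$inaudible_both, ]
  expect_gt(sum(a$delta_h > 0), 0)
  expect_lt(min(a$delta_h), 0)
  # implant-only conditions lean positive; bilateral-acoustic leans lower
  m_xex <- mean(a$delta_h[a$condition == "X-EX"])
  m_axa <- mean(a$delta_h[a$condition == "A-XA"])
  expect_gt(m_xex, m_axa)
})

test_that("cells_from_trials aggregates counts and joins asymmetry", {
  trials <- data.frame(
    participant_id = "S1", condition = "A-EA", band = "MF",
    target_az = 0, target_el = 0,
    response_az = c(10, -5, 0, 20, NA), response_el = 0,
    heard = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  asym <- data.frame(participant_id = "S1", condition = "A-EA",
                     band = "MF", delta_h = 12)
  cells <- cells_from_trials(trials, asym)
  expect_equal(cells$n, 4)
  expect_equal(cells$k, round(2 + 0.5))
  expect_equal(cells$delta_h, 12)
  expect_true(cells$ha_on)
})

test_that("end-to-end recovery: pipeline posteriors cover the truth", {
  cfg <- cohort_config(seed = 20)
  co <- generate_cohort(cfg)
  cells <- cells_from_trials(co$trials, co$asymmetry)
  fit <- fit_bias_model(cells, chains = 2, warmup = 1000, iter = 2000,
                        seed = 21)
  s <- summary(fit)
  og <- s[s$parameter == "omega_group", ]
  th <- s[s$parameter == "mu_th", ]
  expect_gt(co$group_truth["omega"], og$hdi_low)
  expect_lt(co$group_truth["omega"], og$hdi_high)
  expect_gt(co$group_truth["theta"], th$hdi_low)
  expect_lt(co$group_truth["theta"], th$hdi_high)
})
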