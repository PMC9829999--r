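test_that("logistic model hits its defining points for arbitrary parameters", {
  for (omega in c(5, 43.4, 200)) {
    expect_equal(peas_predict(0, omega), 0.5)
    expect_equal(peas_predict(omega / 2, omega), 0.9, tolerance = 1e-12)
    expect_equal(peas_predict(-omega / 2, omega), 0.1, tolerance = 1e-12)
    for (theta in c(-25, 0, 18.8)) {
      expect_equal(peas_predict(theta, omega, theta, ha_on = TRUE), 0.5)
      # theta is ignored when the hearing aid is off
      expect_equal(peas_predict(0, omega, theta, ha_on = FALSE), 0.5)
    }
  }
  expect_error(peas_predict(0, omega = -1), "positive")
  expect_error(peas_predict(0, omega = 0), "positive")
})

test_that("logistic curve symmetry, width and monotonicity properties", {
  set.seed(21)
  for (rep in 1:20) {
    omega <- runif(1, 5, 150)
    theta <- runif(1, -40, 40)
    dh <- runif(5, -80, 80)
    # point symmetry about (theta_eff, 0.5)
    expect_equal(
      peas_predict(dh, omega, theta, TRUE) +
        peas_predict(2 * theta - dh, omega, theta, TRUE),
      rep(1, 5), tolerance = 1e-12)
    # width definition: rise of 0.8 between theta +/- omega/2
    expect_equal(
      peas_predict(theta + omega / 2, omega, theta, TRUE) -
        peas_predict(theta - omega / 2, omega, theta, TRUE),
      0.8, tolerance = 1e-12)
    # strictly increasing in delta_h
    grid <- seq(-100, 100, length.out = 50)
    expect_true(all(diff(peas_predict(grid, omega, theta, TRUE)) > 0))
  }
  # larger omega flattens the curve
  expect_lt(peas_predict(10, 80), peas_predict(10, 20))
})

test_that("cell log-likelihood matches a direct factorial computation", {
  # independent route: log C(n,k) via lgamma, plus k log p + (n-k) log(1-p)
  n <- 64; k <- 16; p <- 0.25
  direct <- lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    k * log(p) + (n - k) * log(1 - p)
  # choose delta_h so the model probability is exactly 0.25: p = ilogit(x)
  omega <- 40
  dh <- log(p / (1 - p)) * omega / (2 * log(9))
  cell <- list(delta_h = dh, k = k, n = n, ha_on = FALSE)
  expect_equal(cell_log_likelihood(cell, omega), direct, tolerance = 1e-10)

  # k = n with p -> 1 gives log-likelihood -> 0
  sat <- list(delta_h = 1e4, k = 50, n = 50, ha_on = FALSE)
  expect_equal(cell_log_likelihood(sat, omega), 0, tolerance = 1e-6)

  # k/2 successes are most likely at p = 0.5
  half <- list(delta_h = 0, k = 32, n = 64, ha_on = FALSE)
  at_half <- cell_log_likelihood(half, omega)
  for (shift in c(-20, -5, 5, 20)) {
    off <- list(delta_h = shift, k = 32, n = 64, ha_on = FALSE)
    expect_lt(cell_log_likelihood(off, omega), at_half)
  }
})

test_that("HDI is the shortest interval with the requested mass", {
  expect_equal(hdi(rep(3, 500)), c(3, 3))
  set.seed(31)
  z <- rnorm(1e6)
  h <- hdi(z)
  expect_equal(h[1], -1.96, tolerance = 0.02 / 1.96)
  expect_equal(h[2], 1.96, tolerance = 0.02 / 1.96)
  # skewed sample: HDI strictly shorter than the equal-tailed interval
  ln <- exp(rnorm(1e5, 0, 1))
  h_ln <- hdi(ln)
  et <- quantile(ln, c(0.025, 0.975))
  expect_lt(diff(h_ln), diff(unname(et)))
  expect_error(hdi(z, mass = 1.2), "mass")
})

test_that("single-participant MCMC agrees with the dense grid oracle", {
  cells <- make_cells(omega = 40, theta = 15, seed = 42)
  g <- grid_posterior(cells, n_grid = 300)
  fit <- fit_bias_model(cells, chains = 2, warmup = 1000, iter = 2000,
                        seed = 7)
  co <- coef(fit)
  expect_equal(unname(co["omega"]), g$omega_mean,
               tolerance = 0.02)
  expect_equal(unname(co["theta"]), g$theta_mean,
               tolerance = 0.02)
  # and both recover the generative truth to within 10%
  expect_lt(abs(co[["omega"]] / 40 - 1), 0.1)
  expect_lt(abs(co[["theta"]] / 15 - 1), 0.1)
  # convergence diagnostics reported for every parameter
  expect_true(all(is.finite(summary(fit)$rhat)))
  expect_lt(max(summary(fit)$rhat), 1.05)
})

test_that("flat response data push the width posterior to large values", {
  dh <- seq(-60, 60, length.out = 20)
  cells <- data.frame(participant_id = "P1", delta_h = dh,
                      k = 50, n = 100, ha_on = FALSE)
  fit <- fit_bias_model(cells, chains = 2, warmup = 500, iter = 1000,
                        seed = 8)
  # flat curve: fitted width far exceeds the data's delta_h span
  expect_gt(coef(fit)[["omega"]], 120)
})

test_that("MCMC fits are reproducible under a fixed seed", {
  cells <- make_cells(omega = 50, theta = 10, n_cells = 10, n_per = 50)
  f1 <- fit_bias_model(cells, chains = 2, adapt = 200, warmup = 200,
                       iter = 300, seed = 99)
  f2 <- fit_bias_model(cells, chains = 2, adapt = 200, warmup = 200,
                       iter = 300, seed = 99)
  expect_equal(summary(f1)$mean, summary(f2)$mean)
})

test_that("fit object methods are coherent", {
  cells <- make_cells(omega = 40, theta = 15, n_cells = 12, n_per = 100,
                      seed = 5)
  fit <- fit_bias_model(cells, chains = 2, adapt = 300, warmup = 500,
                        iter = 500, seed = 13)
  expect_s3_class(fit, "bias_fit")
  expect_output(print(fit), "omega")
  p <- predict(fit)
  expect_length(p, nrow(cells))
  expect_true(all(p > 0 & p < 1))
  expect_true(all(diff(predict(
    fit, data.frame(delta_h = -50:50, ha_on = FALSE))) > 0))
  r <- residuals(fit)
  expect_length(r, nrow(cells))
  expect_lt(mean(abs(r)), 3)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(cells), 3))
  expect_true(all(sims <= cells$n))
})

test_that("hierarchical fit recovers per-participant parameters", {
  set.seed(77)
  true <- data.frame(id = c("A", "B", "C"),
                     omega = c(30, 45, 60), theta = c(10, 20, 15))
  cells <- do.call(rbind, lapply(1:3, function(i) {
    d <- make_cells(true$omega[i], true$theta[i], n_cells = 20,
                    n_per = 200, seed = 100 + i)
    d$participant_id <- true$id[i]
    d
  }))
  fit <- fit_bias_model(cells, chains = 2, warmup = 1000, iter = 1000,
                        seed = 14)
  s <- summary(fit)
  for (i in 1:3) {
    om <- s$mean[!is.na(s$participant_id) &
                   s$participant_id == true$id[i] &
                   grepl("^omega\\[", s$parameter)]
    th <- s$mean[!is.na(s$participant_id) &
                   s$participant_id == true$id[i] &
                   grepl("^theta\\[", s$parameter)]
    expect_lt(abs(om / true$omega[i] - 1), 0.2)
    expect_lt(abs(th - true$theta[i]), 5)
  }
})
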