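# shared fixture builders

# flat audiogram at a constant threshold
flat_audiogram <- function(threshold, ear = "EAS", state = "A",
                           freqs = c(125, 1000, 8000)) {
  audiogram(freqs, rep(threshold, length(freqs)), ear = ear,
            device_state = state)
}

# band_levels object built directly (bypassing the stimulus stage)
make_bands <- function(fc, levels, stage = "hl",
                       bandwidths = fc * (2^(1 / 6) - 2^(-1 / 6))) {
  structure(list(center_frequencies = fc, levels = levels,
                 bandwidths = bandwidths, grid = "third_octave",
                 stage = stage),
            class = "band_levels")
}

# synthetic observation cells for one participant at known (omega, theta)
make_cells <- function(omega, theta, n_cells = 40, n_per = 200,
                       dh_range = c(-60, 60), seed = 1) {
  set.seed(seed)
  dh <- seq(dh_range[1], dh_range[2], length.out = n_cells)
  ha <- rep(c(TRUE, FALSE), length.out = n_cells)
  p <- peas_predict(dh, omega, theta, ha)
  data.frame(participant_id = "P1", delta_h = dh,
             k = rbinom(n_cells, n_per, p), n = n_per, ha_on = ha)
}

# minimum-jerk head trace to a known endpoint (independent of the
# package's own generator)
min_jerk_trace <- function(az, el = 0, move_ms = 300, dt_ms = 5,
                           pre_ms = 100, post_ms = 300) {
  t <- seq(0, pre_ms + move_ms + post_ms, by = dt_ms)
  tau <- pmin(1, pmax(0, (t - pre_ms) / move_ms))
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  head_trace(t, az * s, el * s)
}

# one-row trial data.frame
trial_row <- function(target_az, response_az, heard = TRUE,
                      target_el = 0, response_el = 0) {
  data.frame(target_az = target_az, target_el = target_el,
             response_az = response_az, response_el = response_el,
             heard = heard)
}
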