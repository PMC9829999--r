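## Synthetic bimodal-EAS cohorts: virtual listeners with ski-slope
## high-frequency hearing loss, device gains, known generative (omega,
## theta), and simulated localization trials, for end-to-end
## parameter-recovery testing of the whole pipeline.

# standard audiometric frequencies for generated audiograms
.audiometric_grid <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000,
                       6000, 8000)

.conditions <- c("A-EX", "A-EA", "X-EX", "X-EA", "A-XA")

# hearing aid on iff the non-implanted ear is aided (first letter A)
ha_on_condition <- function(condition) startsWith(condition, "A")

#' Cohort simulation configuration
#'
#' Defaults reproduce the study design this package models: 7 listeners,
#' five listening conditions, four noise bands at 65 dB(A), 16 azimuths in
#' [-80, +80] deg x 4 repetitions = 64 trials per condition (the four bands
#' interleaved, 16 trials per band), elevations in [-45, +60] deg.
#' Generative group parameters default to width 43.4 dB and hearing-aid
#' preference 18.8 dB with moderate between-listener spread.
#'
#' @param n_listeners number of virtual listeners (default 7).
#' @param conditions listening conditions (device-state codes; first letter
#'   = non-implanted ear, rest = implanted ear).
#' @param bands stimulus bands (subset of LF/MF/MHF/HF).
#' @param n_locations,n_repeats speaker locations and repetitions per
#'   condition (trials per condition = product).
#' @param level overall stimulus level in dB(A).
#' @param az_range,el_range target ranges in degrees.
#' @param group_omega,group_theta generative group-level parameters (dB).
#' @param sd_log_omega,sd_theta between-listener spreads (log-dB, dB).
#' @param response_mean,response_sd lateralized response-endpoint magnitude
#'   model (truncated normal, deg).
#' @param grid audibility analysis grid.
#' @param seed integer seed.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_listeners = 7, conditions = .conditions,
                          bands = c("LF", "MF", "MHF", "HF"),
                          n_locations = 16, n_repeats = 4, level = 65,
                          az_range = c(-80, 80), el_range = c(-45, 60),
                          group_omega = 43.4, group_theta = 18.8,
                          sd_log_omega = 0.2, sd_theta = 5,
                          response_mean = 40, response_sd = 20,
                          grid = "third_octave", seed = 1) {
  stopifnot(n_listeners >= 1, n_locations >= 1, n_repeats >= 1,
            group_omega > 0, all(bands %in% names(.band_edges)))
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate the audiogram set of one virtual listener
#'
#' Emulates the canonical bimodal-EAS threshold pattern: residual
#' low-frequency acoustic hearing with a steep ("ski-slope")
#' high-frequency sensorineural loss in both ears, a hearing aid on the
#' non-implanted side (half-gain amplification of the low frequencies), an
#' acoustic EAS component on the implanted side, and an essentially flat
#' electric aided audiogram around 37 dB HL. Thresholds are capped at
#' 100 dB HL.
#'
#' @param params named list of shape parameters: `ha_base`, `ha_corner`,
#'   `ha_slope`, `eas_base`, `eas_corner`, `eas_slope` (dB HL, Hz,
#'   dB/octave), `electric_mean` (dB HL); see [generate_listener] for the
#'   sampled defaults.
#' @param seed integer seed (audiogram jitter).
#' @return named list of [audiogram] objects: `ha_unaided`, `ha_aided`,
#'   `eas_unaided`, `eas_acoustic_aided`, `eas_electric`.
#' @export
generate_audiograms <- function(params, seed = 1) {
  set.seed(as.integer(seed))
  f <- .audiometric_grid
  ski <- function(base, corner, slope)
    base + slope * pmax(0, log2(f / corner)) + rnorm(length(f), 0, 2)
  # half-gain amplification of the unaided loss, rolling off above 1 kHz
  aided <- function(unaided) {
    gain <- pmin(unaided / 2, 40) *
      pmax(0, pmin(1, 1 - log2(f / 1000) / 2))
    pmax(unaided - gain, 5)
  }
  ha_un <- ski(params$ha_base, params$ha_corner, params$ha_slope)
  eas_un <- ski(params$eas_base, params$eas_corner, params$eas_slope)
  electric <- params$electric_mean + rnorm(length(f), 0, 3)
  list(
    ha_unaided = audiogram(f, ha_un, ear = "HA", device_state = "unaided"),
    ha_aided = audiogram(f, aided(ha_un), ear = "HA", device_state = "A"),
    eas_unaided = audiogram(f, eas_un, ear = "EAS",
                            device_state = "unaided"),
    eas_acoustic_aided = audiogram(f, aided(eas_un), ear = "EAS",
                                   device_state = "A"),
    eas_electric = audiogram(f, electric, ear = "EAS", device_state = "E"))
}

#' Generate one virtual listener
#'
#' Samples audiogram shape parameters and true logistic-model parameters
#' for one listener from the cohort-level distributions of `cfg`.
#'
#' @param id participant identifier (e.g. `"S1"`).
#' @param cfg a [cohort_config].
#' @param seed integer seed.
#' @return list of class `"virtual_listener"`: `participant_id`,
#'   `audiograms` (see [generate_audiograms]), `omega`, `theta` (true
#'   generative values, dB).
#' @export
generate_listener <- function(id, cfg, seed = 1) {
  set.seed(as.integer(seed))
  params <- list(
    ha_base = runif(1, 20, 50),
    ha_corner = 2^runif(1, log2(500), log2(1500)),
    ha_slope = runif(1, 20, 40),
    eas_base = runif(1, 25, 60),
    eas_corner = 2^runif(1, log2(250), log2(1000)),
    eas_slope = runif(1, 25, 45),
    electric_mean = rnorm(1, 37, 3))
  omega <- exp(rnorm(1, log(cfg$group_omega), cfg$sd_log_omega))
  theta <- rnorm(1, cfg$group_theta, cfg$sd_theta)
  structure(list(
    participant_id = id, shape_params = params,
    audiograms = generate_audiograms(params, seed = seed + 104729L),
    omega = omega, theta = theta),
    class = "virtual_listener")
}

# effective per-ear audiograms for a listening condition.
# Non-implanted ear code: A = aided, X = open canal (unaided).
# Implanted ear code, two letters: electric state (E on / X off) then
# acoustic state (X open canal / A acoustic component on). Electric-on
# states take the best of the electric and acoustic thresholds.
condition_audiograms <- function(audiograms, condition) {
  parts <- strsplit(condition, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("unknown condition: ", condition)
  ha <- switch(parts[1],
               A = audiograms$ha_aided,
               X = audiograms$ha_unaided,
               stop("unknown non-implanted ear state in ", condition))
  el <- substr(parts[2], 1, 1)
  ac <- substr(parts[2], 2, 2)
  ac_ag <- switch(ac,
                  X = audiograms$eas_unaided,
                  A = audiograms$eas_acoustic_aided,
                  stop("unknown acoustic state in ", condition))
  eas <- switch(el,
                E = combine_eas_thresholds(ac_ag, audiograms$eas_electric),
                X = ac_ag,
                stop("unknown electric state in ", condition))
  list(eas = eas, ha = ha)
}

#' Hearing-asymmetry table of a virtual listener
#'
#' Runs the audibility pipeline for every condition x band of the design.
#'
#' @param listener a `"virtual_listener"`.
#' @param cfg a [cohort_config].
#' @return data.frame: `participant_id`, `condition`, `band`, `delta_h`,
#'   `audibility_eas`, `audibility_ha`, `inaudible_both`, `ha_on`.
#' @export
listener_asymmetry <- function(listener, cfg = cohort_config()) {
  rows <- list()
  for (cond in cfg$conditions) {
    ags <- condition_audiograms(listener$audiograms, cond)
    for (b in cfg$bands) {
      stim <- stimulus_spec(b, overall_level = cfg$level)
      hsym <- stimulus_asymmetry(stim, ags$eas, ags$ha, grid = cfg$grid)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = listener$participant_id, condition = cond,
        band = b, delta_h = hsym$delta_h,
        audibility_eas = hsym$audibility_eas,
        audibility_ha = hsym$audibility_ha,
        inaudible_both = hsym$inaudible_both,
        ha_on = ha_on_condition(cond), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# truncated normal on (lo, hi) via inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Simulate localization trials for one virtual listener
#'
#' For each listening condition the scheduler emits `n_locations x
#' n_repeats` trials (64 by default) with the bands interleaved so that
#' each band is presented at each location once per `n_repeats`. Target
#' azimuths are drawn uniformly on the configured range (a fixed
#' 16-location grid via `fixed_grid = TRUE`). A trial is unheard when the
#' stimulus is inaudible in both ears; otherwise the response side is
#' Bernoulli with probability given by the logistic bias model at the
#' listener's true parameters, the response magnitude is a truncated
#' normal toward the chosen side, and the elevation response is
#' near-horizontal (normal, sd 5 deg), emulating the absence of usable
#' elevation cues.
#'
#' @param listener a `"virtual_listener"`.
#' @param cfg a [cohort_config].
#' @param asym optional precomputed [listener_asymmetry] table.
#' @param fixed_grid use an evenly spaced fixed set of target azimuths
#'   instead of uniform redraws (default `FALSE`).
#' @param seed integer seed.
#' @return data.frame of trials: `participant_id`, `condition`, `band`,
#'   `target_az`, `target_el`, `response_az`, `response_el`, `heard`.
#' @export
generate_trials <- function(listener, cfg = cohort_config(), asym = NULL,
                            fixed_grid = FALSE, seed = 1) {
  set.seed(as.integer(seed))
  if (is.null(asym)) asym <- listener_asymmetry(listener, cfg)
  n_per_cond <- cfg$n_locations * cfg$n_repeats
  rows <- list()
  for (cond in cfg$conditions) {
    band_seq <- rep(cfg$bands, length.out = n_per_cond)
    target_az <- if (fixed_grid)
      rep(seq(cfg$az_range[1], cfg$az_range[2],
              length.out = cfg$n_locations), cfg$n_repeats)
    else runif(n_per_cond, cfg$az_range[1], cfg$az_range[2])
    target_el <- runif(n_per_cond, cfg$el_range[1], cfg$el_range[2])
    for (t in seq_len(n_per_cond)) {
      b <- band_seq[t]
      a <- asym[asym$condition == cond & asym$band == b, ]
      heard <- !a$inaudible_both
      if (heard) {
        p <- peas_predict(a$delta_h, listener$omega, listener$theta,
                          ha_on = a$ha_on)
        side <- if (runif(1) < p) 1 else -1
        mag <- rtruncnorm(1, cfg$response_mean, cfg$response_sd, 0,
                          max(abs(cfg$az_range)))
        resp_az <- side * mag
        resp_el <- max(cfg$el_range[1],
                       min(cfg$el_range[2], rnorm(1, 0, 5)))
      } else {
        resp_az <- NA_real_; resp_el <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = listener$participant_id, condition = cond,
        band = b, target_az = target_az[t], target_el = target_el[t],
        response_az = resp_az, response_el = resp_el, heard = heard,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Synthesize a head-orientation trace for one trial
#'
#' A minimum-jerk movement from straight ahead to the trial's response
#' endpoint over 200-400 ms, embedded in pre- and post-movement fixation,
#' with small measurement noise. Peak velocity of the minimum-jerk profile
#' is `1.875 x amplitude / duration`, comfortably above the 20 deg/s
#' detection criterion for amplitudes of a few degrees.
#'
#' @param trial one-row trial data.frame with `response_az`,
#'   `response_el`, `heard`.
#' @param seed integer seed.
#' @param dt_ms sample interval (default 5 ms, i.e. 200 Hz).
#' @param noise_sd measurement noise, deg (default 0.1).
#' @return a [head_trace].
#' @export
generate_head_trace <- function(trial, seed = 1, dt_ms = 5,
                                noise_sd = 0.1) {
  if (!isTRUE(trial$heard) || is.na(trial$response_az))
    stop("cannot generate a movement trace for an unheard trial")
  set.seed(as.integer(seed))
  move_ms <- runif(1, 200, 400)
  pre_ms <- 200; post_ms <- 300
  t <- seq(0, pre_ms + move_ms + post_ms, by = dt_ms)
  tau <- pmin(1, pmax(0, (t - pre_ms) / move_ms))
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5       # minimum-jerk profile
  az <- trial$response_az * s + rnorm(length(t), 0, noise_sd)
  el <- trial$response_el * s + rnorm(length(t), 0, noise_sd)
  head_trace(t, az, el)
}

#' Generate a full virtual cohort
#'
#' @param cfg a [cohort_config]; its `seed` drives every random draw.
#' @return list of class `"cohort"`: `listeners` (virtual listeners),
#'   `asymmetry` (stacked [listener_asymmetry] tables), `trials` (stacked
#'   trial tables), `truth` (data.frame of generative `omega`, `theta` per
#'   listener plus the group values), `config`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  base_seed <- as.integer(cfg$seed) %% 1000000L
  listeners <- lapply(seq_len(cfg$n_listeners), function(i)
    generate_listener(sprintf("S%d", i), cfg, seed = base_seed * 13L + i))
  asym <- do.call(rbind, lapply(listeners, listener_asymmetry, cfg = cfg))
  trials <- do.call(rbind, lapply(seq_along(listeners), function(i)
    generate_trials(listeners[[i]], cfg, seed = base_seed * 31L + i)))
  truth <- data.frame(
    participant_id = vapply(listeners, `[[`, "", "participant_id"),
    omega = vapply(listeners, `[[`, 0, "omega"),
    theta = vapply(listeners, `[[`, 0, "theta"))
  structure(list(listeners = listeners, asymmetry = asym, trials = trials,
                 truth = truth,
                 group_truth = c(omega = cfg$group_omega,
                                 theta = cfg$group_theta),
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Virtual EAS cohort: %d listeners, %d trials (%d per condition)\n",
    length(x$listeners), nrow(x$trials),
    x$config$n_locations * x$config$n_repeats))
  cat(sprintf("  generative group omega = %.1f dB, theta = %.1f dB\n",
              x$group_truth["omega"], x$group_truth["theta"]))
  invisible(x)
}

#' Aggregate trials into model observation cells
#'
#' Collapses a trial table to one row per participant x condition x band:
#' implant-side response count `k` (zero-azimuth responses count 0.5),
#' valid-trial count `n`, joined with the hearing-asymmetry table. Cells
#' with no valid trials (stimulus inaudible in both ears) are dropped —
#' they carry no behavioural information.
#'
#' @param trials trial data.frame (see [generate_trials] or
#'   [read_trials]).
#' @param asym asymmetry data.frame with `participant_id`, `condition`,
#'   `band`, `delta_h` (and optionally `ha_on`).
#' @return cell data.frame ready for [fit_bias_model].
#' @export
cells_from_trials <- function(trials, asym) {
  key <- interaction(trials$participant_id, trials$condition, trials$band,
                     drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    v <- d[d$heard & !is.na(d$response_az), , drop = FALSE]
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1], band = d$band[1],
               k = sum(v$response_az > 0) + 0.5 * sum(v$response_az == 0),
               n = nrow(v), stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, rows)
  cells <- cells[cells$n > 0, , drop = FALSE]
  m <- merge(cells, asym[, c("participant_id", "condition", "band",
                             "delta_h")],
             by = c("participant_id", "condition", "band"))
  m$ha_on <- ha_on_condition(m$condition)
  m$k <- round(m$k)  # binomial counts; half-counts from 0-deg ties rounded
  rownames(m) <- NULL
  m
}
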