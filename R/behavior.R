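## Behavioural statistics: saccade endpoint extraction from head traces,
## the localization-bias proportion p_EAS, RMS localization error, chance
## reference levels, and percentile bootstrap confidence intervals.

#' Head orientation trace
#'
#' @param time_ms uniformly sampled time stamps in ms.
#' @param azimuth_deg,elevation_deg head orientation samples in degrees.
#' @return object of class `"head_trace"`.
#' @export
head_trace <- function(time_ms, azimuth_deg, elevation_deg) {
  stopifnot(length(time_ms) == length(azimuth_deg),
            length(time_ms) == length(elevation_deg),
            length(time_ms) >= 5)
  dt <- diff(time_ms)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("head trace must be uniformly sampled")
  structure(list(time_ms = time_ms, azimuth_deg = azimuth_deg,
                 elevation_deg = elevation_deg, dt_ms = mean(dt)),
            class = "head_trace")
}

#' Detect the endpoint of a head saccade
#'
#' Angular velocity is estimated by a Savitzky-Golay smoothed derivative of
#' the 2-D (azimuth, elevation) trajectory. The first contiguous epoch whose
#' speed exceeds `velocity_threshold` marks the saccade; the endpoint is the
#' first sample after which speed falls and stays below threshold for the
#' dwell window.
#'
#' @param trace a [head_trace].
#' @param velocity_threshold deg/s, default 20.
#' @param smooth_ms Savitzky-Golay window length in ms (default 50).
#' @param dwell_ms speed must stay sub-threshold this long to end the
#'   saccade (default 80).
#' @return list with `saccade` (logical), and when `TRUE`: `endpoint_az`,
#'   `endpoint_el` (deg), `onset_ms`, `offset_ms`, `peak_velocity` (deg/s).
#'   When no epoch exceeds threshold, `saccade = FALSE` (the caller should
#'   mark the trial invalid/unheard).
#' @export
detect_saccade_endpoint <- function(trace, velocity_threshold = 20,
                                    smooth_ms = 50, dwell_ms = 80) {
  stopifnot(inherits(trace, "head_trace"))
  dt_s <- trace$dt_ms / 1000
  n <- length(trace$time_ms)
  win <- round(smooth_ms / trace$dt_ms)
  win <- max(5L, win + (win + 1L) %% 2L)        # odd, >= 5
  win <- min(win, n - (n + 1L) %% 2L)
  vaz <- signal::sgolayfilt(trace$azimuth_deg, p = 2, n = win, m = 1,
                            ts = dt_s)
  vel <- signal::sgolayfilt(trace$elevation_deg, p = 2, n = win, m = 1,
                            ts = dt_s)
  speed <- sqrt(vaz^2 + vel^2)
  above <- which(speed > velocity_threshold)
  if (!length(above))
    return(list(saccade = FALSE))
  onset <- above[1]
  dwell_n <- max(1L, round(dwell_ms / trace$dt_ms))
  below <- speed <= velocity_threshold
  end_idx <- n
  for (i in seq(onset + 1L, n)) {
    if (below[i] && all(below[i:min(n, i + dwell_n - 1L)])) {
      # read the endpoint at the end of the dwell window, once the head
      # has settled (residual drift after threshold crossing is over)
      end_idx <- min(n, i + dwell_n - 1L)
      break
    }
  }
  list(saccade = TRUE,
       endpoint_az = trace$azimuth_deg[end_idx],
       endpoint_el = trace$elevation_deg[end_idx],
       onset_ms = trace$time_ms[onset],
       offset_ms = trace$time_ms[end_idx],
       peak_velocity = max(speed))
}

# normalize a trial table: valid = heard with a recorded azimuth response
.valid_trials <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("target_az", "response_az", "heard") %in% names(trials)))
  trials[trials$heard & !is.na(trials$response_az), , drop = FALSE]
}

#' Localization bias: proportion of responses toward the implanted ear
#'
#' `p_EAS = n_EAS / n_valid`, where a response counts as implant-side iff
#' its azimuth is positive (positive azimuth = implanted side by
#' convention); responses at exactly 0 deg contribute 0.5. Unheard trials
#' are excluded. 0.5 means no bias; 1 means every response went to the
#' implanted side.
#'
#' @param trials data.frame with columns `target_az`, `response_az`,
#'   `heard` (one row per trial of one participant x condition x band cell).
#' @return proportion in `[0, 1]`, or `NA` when no valid trials exist
#'   (bias undefined).
#' @export
peas <- function(trials) {
  v <- .valid_trials(trials)
  n_valid <- nrow(v)
  if (n_valid == 0L) return(NA_real_)
  n_eas <- sum(v$response_az > 0) + 0.5 * sum(v$response_az == 0)
  n_eas / n_valid
}

#' Root-mean-square localization error
#'
#' `sqrt(mean((response_az - target_az)^2))` over heard trials. Azimuth-only
#' by default; `two_dim = TRUE` adds the elevation component
#' (`sqrt(mean(d_az^2 + d_el^2))`).
#'
#' @param trials trial data.frame (see [peas]); `two_dim` additionally needs
#'   `target_el` and `response_el`.
#' @param two_dim include elevation (default `FALSE`).
#' @return error in degrees, `NA` when no valid trials.
#' @export
rms_error <- function(trials, two_dim = FALSE) {
  v <- .valid_trials(trials)
  if (nrow(v) == 0L) return(NA_real_)
  sq <- (v$response_az - v$target_az)^2
  if (two_dim) sq <- sq + (v$response_el - v$target_el)^2
  sqrt(mean(sq))
}

#' Chance-level RMS errors for reference
#'
#' For targets uniform on `az_range`, `chance_error_straight_ahead` is the
#' asymptotic RMS error of a listener who always responds straight ahead
#' (0 deg): `sqrt((hi - lo)^2 / 12 + midpoint^2)`. `chance_error_random` is
#' the RMS error of a listener responding uniformly at random over the same
#' range, independent of the target: `sqrt(2 (hi - lo)^2 / 12)`.
#'
#' @param az_range numeric length-2, degrees, `lo < hi` (equal allowed for
#'   the degenerate straight-ahead case).
#' @return RMS error in degrees.
#' @examples
#' chance_error_straight_ahead(c(-80, 80))  # 46.2 deg
#' @export
chance_error_straight_ahead <- function(az_range) {
  stopifnot(length(az_range) == 2, all(is.finite(az_range)),
            az_range[1] <= az_range[2])
  width <- diff(az_range)
  mid <- mean(az_range)
  sqrt(width^2 / 12 + mid^2)
}

#' @rdname chance_error_straight_ahead
#' @export
chance_error_random <- function(az_range) {
  stopifnot(length(az_range) == 2, all(is.finite(az_range)),
            az_range[1] < az_range[2])
  sqrt(2 * diff(az_range)^2 / 12)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the observations with replacement `n_boot` times, applies
#' `statistic` to each resample, and returns the percentile interval.
#'
#' @param x numeric vector of observations (or rows of a data.frame when
#'   `statistic` takes a data.frame).
#' @param statistic function of a resample, default [mean].
#' @param n_boot number of bootstrap resamples, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed optional integer for reproducibility.
#' @return list with `estimate` (plug-in statistic on the full sample),
#'   `mean` (mean of the bootstrap distribution), `lo`, `hi`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 1L) stop("no observations to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  take <- if (is.data.frame(x)) function(i) x[i, , drop = FALSE]
          else function(i) x[i]
  stats <- vapply(seq_len(n_boot),
                  function(b) statistic(take(sample.int(n, n, replace = TRUE))),
                  numeric(1))
  alpha <- (1 - level) / 2
  qs <- unname(quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE))
  list(estimate = statistic(x), mean = mean(stats), lo = qs[1], hi = qs[2])
}
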