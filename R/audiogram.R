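#' Cap audiometric thresholds at the no-response ceiling
#'
#' Thresholds worse than the audiometer limit are assigned the limit value;
#' "no response at limit" sentinels (`NA`) are likewise assigned the limit.
#' Standard clinical practice for profound losses.
#'
#' @param raw_thresholds numeric vector of thresholds in dB HL; `NA` marks
#'   "no response at the audiometer limit".
#' @param cap ceiling in dB HL (default 100).
#' @return numeric vector, every element `<= cap`.
#' @examples
#' cap_thresholds(c(20, 60, 120))  # 20 60 100
#' @export
cap_thresholds <- function(raw_thresholds, cap = 100) {
  if (!is.numeric(raw_thresholds) && !all(is.na(raw_thresholds)))
    stop("thresholds must be numeric")
  x <- as.numeric(raw_thresholds)
  if (any(is.nan(x)))
    stop("NaN thresholds are not allowed (use NA for 'no response at limit')")
  x[is.na(x)] <- cap
  pmin(x, cap)
}

#' Construct an audiogram
#'
#' A per-ear, per-device-state hearing threshold curve. Thresholds are capped
#' at `cap` dB HL on construction.
#'
#' @param frequencies Hz, strictly increasing, at least 2 points.
#' @param thresholds dB HL, same length; `NA` = no response at limit.
#' @param ear `"EAS"` (implanted side) or `"HA"` (hearing-aid side).
#' @param device_state one of `"unaided"`, `"A"` (acoustic aid), `"E"`
#'   (electric only), `"EA"` (electro-acoustic).
#' @param cap threshold ceiling in dB HL.
#' @return object of class `"audiogram"`.
#' @export
audiogram <- function(frequencies, thresholds, ear = c("EAS", "HA"),
                      device_state = c("unaided", "A", "E", "EA"),
                      cap = 100) {
  ear <- match.arg(ear)
  device_state <- match.arg(device_state)
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 2L)
    stop("an audiogram needs at least 2 frequency points")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be positive and finite")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (length(thresholds) != length(frequencies))
    stop("thresholds and frequencies must have equal length")
  thresholds <- cap_thresholds(thresholds, cap = cap)
  structure(
    list(ear = ear, device_state = device_state,
         frequencies = frequencies, thresholds = thresholds, cap = cap),
    class = "audiogram")
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf("Audiogram: %s ear, state %s, %d frequencies (%g-%g Hz)\n",
              x$ear, x$device_state, length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  print(data.frame(frequency_hz = x$frequencies, threshold_dbhl = x$thresholds),
        row.names = FALSE)
  invisible(x)
}

# Interpolate an audiogram onto arbitrary frequencies: linear in log-frequency,
# last measured value held beyond the measured range.
interp_audiogram <- function(ag, freqs) {
  stopifnot(inherits(ag, "audiogram"))
  approx(x = log(ag$frequencies), y = ag$thresholds, xout = log(freqs),
         rule = 2)$y
}

#' Combine electric and acoustic thresholds of an implanted ear
#'
#' The effective aided audiogram of an ear receiving both electric and
#' acoustic stimulation is the better (lower) of the two single-modality
#' thresholds at each frequency. Inputs are first resampled onto the union of
#' their frequency grids by log-frequency interpolation.
#'
#' @param acoustic,electric [audiogram] objects for the same ear.
#' @return an [audiogram] with `device_state = "EA"`.
#' @export
combine_eas_thresholds <- function(acoustic, electric) {
  stopifnot(inherits(acoustic, "audiogram"), inherits(electric, "audiogram"))
  if (acoustic$ear != electric$ear)
    stop("acoustic and electric audiograms are for different ears")
  grid <- sort(unique(c(acoustic$frequencies, electric$frequencies)))
  thr <- pmin(interp_audiogram(acoustic, grid), interp_audiogram(electric, grid))
  audiogram(grid, thr, ear = acoustic$ear, device_state = "EA",
            cap = max(acoustic$cap, electric$cap))
}

#' Read audiograms from a long-format CSV
#'
#' Expected columns: `participant_id`, `ear` (EAS/HA), `device_state`
#' (unaided/A/E/EA), `frequency_hz`, `threshold_dbhl`.
#'
#' @param path CSV file path.
#' @param cap threshold ceiling in dB HL.
#' @return nested list: `x[[participant]][[ear]][[device_state]]` is an
#'   [audiogram].
#' @export
read_audiograms <- function(path, cap = 100) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "ear", "device_state", "frequency_hz",
            "threshold_dbhl")
  if (!all(need %in% names(d)))
    stop("audiogram CSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (pid in unique(d$participant_id)) {
    dp <- d[d$participant_id == pid, ]
    out[[as.character(pid)]] <- list()
    for (ear in unique(dp$ear)) {
      de <- dp[dp$ear == ear, ]
      states <- list()
      for (st in unique(de$device_state)) {
        ds <- de[de$device_state == st, ]
        ds <- ds[order(ds$frequency_hz), ]
        states[[st]] <- audiogram(ds$frequency_hz, ds$threshold_dbhl,
                                  ear = ear, device_state = st, cap = cap)
      }
      out[[as.character(pid)]][[ear]] <- states
    }
  }
  out
}

# Long data.frame from the nested audiogram list (inverse of read_audiograms).
audiograms_to_df <- function(x) {
  rows <- list()
  for (pid in names(x)) for (ear in names(x[[pid]]))
    for (st in names(x[[pid]][[ear]])) {
      ag <- x[[pid]][[ear]][[st]]
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, ear = ear, device_state = st,
        frequency_hz = ag$frequencies, threshold_dbhl = ag$thresholds,
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
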