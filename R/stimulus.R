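## Stimulus band-level analysis: third-octave (or finer) band SPLs of the
## bandpass noise bursts, gammatone-bandwidth correction, and SPL <-> HL
## conversion against an embedded free-field reference-threshold table.

# The four noise bands, edges in Hz. All presented at the same overall
# A-weighted level.
.band_edges <- list(
  LF  = c(100, 400),
  MF  = c(500, 1500),
  HF  = c(3000, 20000),
  MHF = c(500, 20000)
)

#' Stimulus specification
#'
#' A bandpass-filtered white-noise burst described by its band edges and
#' overall A-weighted level. The four standard bands are `"LF"` (100-400 Hz),
#' `"MF"` (500-1500 Hz), `"HF"` (3000-20000 Hz) and `"MHF"` (500-20000 Hz).
#'
#' @param band_label one of `"LF"`, `"MF"`, `"HF"`, `"MHF"`, or `"custom"`.
#' @param f_low,f_high passband edges in Hz; filled in automatically for the
#'   four standard labels.
#' @param overall_level overall level in dB(A), default 65.
#' @param duration burst duration in ms.
#' @return object of class `"stimulus_spec"`.
#' @export
stimulus_spec <- function(band_label = c("LF", "MF", "HF", "MHF", "custom"),
                          f_low = NULL, f_high = NULL,
                          overall_level = 65, duration = 150) {
  band_label <- match.arg(band_label)
  if (band_label != "custom") {
    edges <- .band_edges[[band_label]]
    if (!is.null(f_low) && !isTRUE(all.equal(c(f_low, f_high), edges)))
      stop("band edges do not match the standard '", band_label, "' band")
    f_low <- edges[1]; f_high <- edges[2]
  }
  if (is.null(f_low) || is.null(f_high) || f_low >= f_high)
    stop("need f_low < f_high")
  if (!is.finite(overall_level)) stop("overall_level must be finite")
  structure(list(band_label = band_label, f_low = f_low, f_high = f_high,
                 overall_level = overall_level, duration = duration),
            class = "stimulus_spec")
}

# Analysis band grid. Exact base-2 third-octave centers 125-8000 Hz
# (19 bands); the "fine" grid subdivides each into 10 (1/30-octave).
# Spectral energy above the top band edge is folded into the top band,
# because neither hearing-level references nor audiograms are defined
# above 8 kHz.
band_grid <- function(grid = c("third_octave", "fine"), fold_to = 20000) {
  grid <- match.arg(grid)
  per_oct <- if (grid == "third_octave") 3 else 30
  k <- seq(-3 * per_oct, 3 * per_oct)  # 125 Hz .. 8 kHz
  fc <- 1000 * 2^(k / per_oct)
  half <- 2^(1 / (2 * per_oct))
  lo <- fc / half
  hi <- fc * half
  hi_fold <- hi
  hi_fold[length(hi_fold)] <- max(hi[length(hi)], fold_to)
  data.frame(fc = fc, lo = lo, hi = hi, hi_fold = hi_fold,
             bw = hi - lo)
}

# IEC 61672 A-weighting in dB at frequency f (Hz).
a_weight <- function(f) {
  f2 <- f^2
  ra <- (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  20 * log10(ra) + 2.00
}

#' Third-octave band levels of a bandpass noise stimulus
#'
#' Distributes the power of a flat-spectral-density bandpass noise over the
#' analysis band grid so that the A-weighted power sum of the returned bands
#' equals the stimulus' overall dB(A) level. Bands wholly outside the
#' passband are absent; energy above the top analysis band (8 kHz) is folded
#' into the top band.
#'
#' @param stim a [stimulus_spec].
#' @param grid `"third_octave"` (default) or `"fine"` (1/30-octave).
#' @return object of class `"band_levels"` with fields `center_frequencies`,
#'   `levels` (dB SPL), `bandwidths`, `stage = "spl"`.
#' @export
stimulus_band_levels <- function(stim, grid = c("third_octave", "fine")) {
  stopifnot(inherits(stim, "stimulus_spec"))
  grid <- match.arg(grid)
  g <- band_grid(grid)
  # overlap of each (folded) analysis band with the passband, in Hz
  w <- pmax(0, pmin(g$hi_fold, stim$f_high) - pmax(g$lo, stim$f_low))
  keep <- w > 0
  if (!any(keep)) stop("stimulus passband does not intersect the analysis grid")
  g <- g[keep, ]; w <- w[keep]
  # unit spectral density band levels, then calibrate the A-weighted sum
  l0 <- 10 * log10(w)
  la <- l0 + a_weight(g$fc)
  offset <- stim$overall_level - 10 * log10(sum(10^(la / 10)))
  structure(list(center_frequencies = g$fc,
                 levels = l0 + offset,
                 bandwidths = g$bw,
                 grid = grid,
                 stage = "spl"),
            class = "band_levels")
}

#' @export
print.band_levels <- function(x, ...) {
  cat(sprintf("Band levels (%s grid, stage %s): %d bands\n",
              x$grid, x$stage, length(x$levels)))
  print(data.frame(fc_hz = round(x$center_frequencies, 1),
                   level_db = round(x$levels, 2)), row.names = FALSE)
  invisible(x)
}

#' Equivalent rectangular bandwidth of the auditory filter
#'
#' `ERB(f) = 24.7 (4.37 f / 1000 + 1)` Hz, the standard gammatone
#' auditory-filter bandwidth model.
#'
#' @param f frequency in Hz.
#' @return bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

# design bandwidth of a third-octave band at center f
third_octave_bandwidth <- function(f) f * (2^(1 / 6) - 2^(-1 / 6))

#' Gammatone-bandwidth correction of noise band levels
#'
#' Adjusts each analysis band level by `10 log10(ERB(f) / BW(f))`, where
#' `ERB` is the auditory-filter bandwidth ([erb_bandwidth]) and `BW` the
#' analysis band's design bandwidth. This converts the level of a noise band
#' into the level effectively passed by a gammatone auditory filter centred
#' on the band, compensating for the mismatch between the noise bandwidth
#' and the auditory filter bandwidth.
#'
#' @param bands a `"band_levels"` object at the `"spl"` stage.
#' @param erb_fun auditory-filter bandwidth model (Hz as a function of Hz);
#'   configurable, default [erb_bandwidth].
#' @return a `"band_levels"` object at stage `"spl_gt"`.
#' @export
gammatone_correction <- function(bands, erb_fun = erb_bandwidth) {
  stopifnot(inherits(bands, "band_levels"))
  if (bands$stage != "spl")
    stop("gammatone correction applies to raw SPL band levels")
  fc <- bands$center_frequencies
  corr <- 10 * log10(erb_fun(fc) / bands$bandwidths)
  bands$levels <- bands$levels + corr
  bands$stage <- "spl_gt"
  bands
}

# Embedded free-field reference thresholds (RETSPL-style minimum audible
# field values), loaded once per session.
.retspl_env <- new.env(parent = emptyenv())
retspl_table <- function() {
  if (is.null(.retspl_env$tab)) {
    path <- system.file("extdata", "retspl_freefield.csv", package = "easbias")
    .retspl_env$tab <- read.csv(path)
  }
  .retspl_env$tab
}

#' Free-field reference threshold (0 dB HL in dB SPL) at given frequencies
#'
#' Interpolated linearly in log-frequency between the tabulated audiometric
#' frequencies (125-8000 Hz); frequencies outside the table are clamped to
#' the nearest tabulated value with a warning.
#'
#' @param f frequency in Hz.
#' @return reference threshold in dB SPL.
#' @export
retspl <- function(f) {
  tab <- retspl_table()
  if (any(f < min(tab$frequency_hz) | f > max(tab$frequency_hz)))
    warning("frequency outside the reference-threshold table (",
            min(tab$frequency_hz), "-", max(tab$frequency_hz),
            " Hz); clamping to the nearest tabulated value")
  approx(log(tab$frequency_hz), tab$retspl_dbspl, xout = log(f), rule = 2)$y
}

#' Convert band levels from dB SPL to dB HL
#'
#' `HL(f) = SPL(f) - RETSPL(f)` using the embedded free-field reference
#' table ([retspl]).
#'
#' @param bands a `"band_levels"` object at stage `"spl"` or `"spl_gt"`.
#' @return a `"band_levels"` object at stage `"hl"`.
#' @seealso [hl_to_spl] for the inverse.
#' @export
spl_to_hl <- function(bands) {
  stopifnot(inherits(bands, "band_levels"))
  if (bands$stage == "hl") stop("band levels are already in dB HL")
  bands$levels <- bands$levels - retspl(bands$center_frequencies)
  bands$stage <- "hl"
  bands
}

#' @rdname spl_to_hl
#' @export
hl_to_spl <- function(bands) {
  stopifnot(inherits(bands, "band_levels"))
  if (bands$stage != "hl") stop("band levels are not in dB HL")
  bands$levels <- bands$levels + retspl(bands$center_frequencies)
  bands$stage <- "spl_gt"
  bands
}

# Full SPL->HL stage for one stimulus: band levels, gammatone correction,
# HL conversion.
stimulus_levels_hl <- function(stim, grid = "third_octave",
                               erb_fun = erb_bandwidth) {
  spl_to_hl(gammatone_correction(stimulus_band_levels(stim, grid = grid),
                                 erb_fun = erb_fun))
}
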