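---
title: "Methods: audibility, hearing asymmetry and the logistic bias model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: audibility, hearing asymmetry and the logistic bias model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(easbias)
```

## Scope and assumptions

`easbias` models one specific phenomenon: bimodal EAS listeners whose two
ears hear a stimulus unequally respond predominantly toward the
better-hearing side. The package's quantitative claim is that the
proportion of implant-side responses, `p_EAS`, is a logistic function of
the interaural audibility difference `ΔH`, and that the lateralization is
additionally offset toward the hearing-aid ear when that aid is switched
on. Everything else — audiogram handling, stimulus band analysis,
behavioural statistics, cohort simulation — exists to compute the two
quantities this law relates.

Key assumptions, stated up front:

* Audibility (sensation level re: threshold) is an adequate proxy for the
  effective interaural level cue. Loudness growth, compression/AGC in the
  devices, and electric current-level maps are *not* modelled; electric
  hearing enters only through its aided audiogram.
* Responses within a participant × condition × band cell are exchangeable
  Bernoulli draws; the cell-level count is binomial. This matches data
  that are strongly side-dominated with no graded stimulus–response
  relation within a cell.
* Elevation carries no usable information for these listeners (no
  spectral pinna cues through the devices); it is simulated as
  near-horizontal noise and excluded from the error statistic by default.

## The audibility pipeline

For each stimulus (bandpass white noise, defined by band edges and an
overall level in dB(A); the four standard bands are LF 100–400 Hz, MF
500–1500 Hz, HF 3000–20000 Hz, MHF 500–20000 Hz, all at 65 dB(A)):

1. **Band levels.** The noise has flat spectral density inside its
   passband. Power is distributed over exact base-2 third-octave bands
   with centres 125 Hz–8 kHz, and the total is calibrated so the
   A-weighted (IEC 61672) power sum of the emitted bands equals the
   overall dB(A) level. Spectral energy above the 8-kHz band edge is
   folded into the 8-kHz band: hearing-level references and audiograms
   are undefined above 8 kHz, and in this population aided audibility is
   effectively confined below it.
2. **Gammatone-bandwidth correction.** Each band level is adjusted by
   `10·log10(ERB(f)/BW(f))`, with `ERB(f) = 24.7(4.37 f/1000 + 1)` Hz
   (the standard gammatone auditory-filter bandwidth) and `BW` the
   analysis band's design bandwidth. This expresses each noise band as
   the level effectively delivered to an auditory filter, compensating
   for the mismatch between noise bandwidth and filter bandwidth. The
   bandwidth model is configurable (`erb_fun`).
3. **dB HL conversion.** `HL = SPL − RETSPL(f)` with an embedded
   free-field reference-threshold table (minimum-audible-field style
   values, 125–8000 Hz at the standard audiometric frequencies),
   interpolated linearly in log-frequency; out-of-range frequencies clamp
   to the nearest tabulated value with a warning. Free-field references
   are used because the stimuli are loudspeaker presentations, not
   headphone ones.
4. **Sensation levels and overall audibility.** Thresholds are
   interpolated onto the band grid (linear in log-frequency, last value
   held outside the measured range), subtracted, and negative differences
   clamped at zero. The overall audibility is the power sum
   `10·log10(Σ wᵢ·10^(SLᵢ/10))` over audible bands, with `wᵢ` the band's
   bandwidth relative to the third-octave bandwidth at its centre.
   On the default third-octave grid `wᵢ = 1` and the formula is the plain
   power sum; the weight exists so that the `grid = "fine"` option
   (1/30-octave bands) computes a brute-force integral of the *same*
   quantity instead of inflating the sum tenfold with the band count. The
   two grids agree within 1 dB for all four standard bands across
   realistic audiogram shapes, which is the package's internal
   consistency check for the discretization.
5. **Asymmetry.** `ΔH = overall audibility (EAS ear) − overall audibility
   (HA ear)`; positive favours the implanted ear. When no band is audible
   in an ear the overall audibility is 0 dB and an explicit `inaudible`
   flag is set; when both ears are inaudible the trial generator emits
   "unheard" trials and the model excludes the cell.

An alternative summary — the arithmetic mean sensation level across bands
(`summation_rule = "mean"`) — is provided because the field uses both
conventions for "averaging audibility across frequency" and printed
per-listener values cannot disambiguate which was used without the raw
thresholds. Power summation is the default: it is the physically motivated
choice for combining acoustic band powers, and all shipped defaults and
tests use it.

## Behavioural statistics

* **Saccade endpoints.** Angular velocity is a Savitzky–Golay smoothed
  derivative (50-ms window, order 2) of the 2-D head trajectory. The first
  epoch exceeding 20 deg/s marks the saccade; the endpoint is read at the
  end of an 80-ms sub-threshold dwell window, once residual drift has
  settled. Traces with no super-threshold epoch yield "no saccade" and the
  trial is treated as invalid. The detector recovers minimum-jerk
  endpoints within 0.5 deg over 5–80 deg amplitudes. (Interactive manual
  adjustment of endpoints is out of scope.)
* **p_EAS.** Implant-side responses (azimuth > 0) over valid trials;
  exactly-zero azimuths count half, a symmetric tie-break that cannot bias
  either side. Unheard trials are excluded; a cell with no valid trials
  has undefined bias (`NA`), not a number.
* **E_RMS.** Azimuth-only by default (elevation was uninformative); a 2-D
  variant is available behind `two_dim = TRUE`. Chance references for
  targets uniform on `[lo, hi]`: a straight-ahead responder gives
  `sqrt((hi−lo)²/12 + midpoint²)` (46.2 deg for ±80 deg) and an
  independent uniform responder `sqrt(2(hi−lo)²/12)` (65.3 deg for
  ±80 deg). The uniform-responder value differs from the 73 deg sometimes
  quoted for this paradigm; the closed form above is exact for the stated
  response model (and is verified by Monte Carlo), so the quoted figure
  must rest on a different — unstated — response strategy, possibly
  including elevation error or edge-biased guessing. We keep the exact
  closed form.
* **Bootstrap.** Percentile intervals over 1000 resamples by default.
  Cell-level statistics resample trials; group means resample
  participants. Percentile intervals at very small n undercover slightly
  (a known property, not a defect of the implementation); the package's
  coverage check uses n = 100 Gaussian observations, where the method is
  within its nominal band.

## The model and its fit

With slope written as `2 ln 9 / ω`, the curve rises from 0.1 to 0.9 over
exactly `ω` dB — that is the width's definition, and it holds for every
`(ω, θ)` by construction (`p(θ_eff ± ω/2) = 0.9/0.1`). `θ` applies in all
hearing-aid-on conditions and is shared across conditions within a
participant; making it condition-specific would double the parameter count
without per-trial data to support it.

**Hierarchy and priors.** `log ωᵢ ~ Normal(μ_ω, σ_ω)` and
`θᵢ ~ Normal(μ_θ, σ_θ)` across participants, with weakly informative
hyperpriors on the dB scales the data live on: `μ_ω ~ Normal(log 40, 1)`,
`σ_ω ~ Half-Normal(1)`, `μ_θ ~ Normal(0, 30 dB)`,
`σ_θ ~ Half-Normal(20 dB)`. The log scale enforces `ω > 0`. The group
width is reported as `exp(μ_ω)` (the population median width).

**Sampling.** JAGS, 4 chains × 2000 kept draws after 500 adaptation and
2000 burn-in steps by default, deterministically seeded per chain.
Convergence is monitored by split-half potential scale reduction computed
in the package; split-Rhat > 1.05 raises a warning rather than failing
silently. The contract is the posterior, not the sampler: the
single-participant model is verified against an independent dense grid
posterior (500 × 500 over `(log ω, θ)`, pure R numerical integration), and
posterior means agree to well under 2%.

**Observation model.** Binomial on cell counts. Fitting trial-level
Bernoulli outcomes instead would give the same likelihood up to a
constant; cells are the natural unit because `ΔH` is constant within a
cell. Cells inaudible in both ears are excluded — there is no behavioural
response to model.

## The synthetic cohort

The generator's defaults are the study design the analysis assumes: 7
listeners, five listening conditions (A-EX, A-EA, X-EX, X-EA, A-XA; first
letter = non-implanted ear, remaining letters = electric then acoustic
state of the implanted ear), four bands interleaved within 16 locations ×
4 repetitions = 64 trials per condition, targets uniform in ±80 deg
azimuth and −45…+60 deg elevation at 65 dB(A). Generative group
parameters default to ω = 43.4 dB and θ = 18.8 dB — group-level estimates
reported for a real cohort of this kind — with between-listener spreads
σ_log ω = 0.2 and σ_θ = 5 dB chosen as moderate individual variation of
the sort audiology cohorts show; audiogram shapes are ski-slope losses
(low-frequency thresholds 20–60 dB HL, corners 250–1500 Hz, slopes 20–45
dB/octave), a flat electric aided audiogram around 37 dB HL, and half-gain
amplification rolling off above 1 kHz.

What it emulates: frequency-dependent, condition-dependent `ΔH` of both
signs (implant-only conditions lean positive, bilateral-acoustic leans
negative relative to them); unheard cells when a band is inaudible in both
ears; side-dominated responses with lateralized endpoints (truncated
Gaussian magnitude, mean 40 deg, sd 20 deg — an invented stand-in, since
endpoint scatter for lateralized responses is not characterized in the
literature this models; it is config-exposed); near-horizontal elevation
responses; minimum-jerk head movements for the saccade detector.

What it does not emulate: real audiogram correlation structure across
frequencies, device compression, reaction times, attention lapses, or any
graded stimulus–response relation within a cell. Passing recovery tests
therefore demonstrates that *if* behaviour follows the logistic law, the
pipeline estimates it correctly — not that real listeners obey the law.

## Problem sizes and numerical choices

* Recovery check: 20 replicate cohorts at the full default design, fitted
  with 3 chains × 3000 kept draws after 2000 burn-in — enough that Monte
  Carlo error in HDI endpoints is small against the intervals themselves.
  Group 95%-HDIs cover the generative ω and θ in ≥ 18/20 replicates and
  posterior means land within a few percent on average.
* Grid oracle: 500 × 500 grid, prior ± 4 sd in each dimension; binomial
  probabilities clamped to `[1e-12, 1 − 1e-12]` before log.
* Bootstrap coverage: 1000 replicates × 1000 resamples, n = 100.
* Audibility: thresholds capped at 100 dB HL (sentinel `NA` = no response
  at limit, also capped); audiogram interpolation linear in
  (log f, dB HL) with flat extrapolation; degenerate inputs (empty
  passband, single-frequency audiograms, identical ear labels) are
  rejected with explicit errors.

## Known limitations

* `ΔH` treats audibility as the only interaural variable; interaural time
  cues and loudness recruitment are outside the model.
* The RETSPL table stops at 8 kHz; stimuli extending to 20 kHz are folded
  into the top band, which slightly overstates 8-kHz-band audibility for
  listeners with measurable hearing there (rare in this population).
* θ is shared across hearing-aid-on conditions; condition-specific
  preferences are not identifiable at 16 trials per cell.
* The endpoint-scatter model and audiogram-shape distributions are
  plausible inventions; conclusions about real cohorts require real
  per-trial data through `read_trials()`/`read_audiograms()`.
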