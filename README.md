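# easbias

Quantifying how binaural hearing asymmetry biases horizontal sound
localization in bimodal users of electro-acoustic stimulation (EAS)
cochlear implants.

## The problem

A bimodal EAS listener has a cochlear implant plus acoustic amplification in
one ear and a hearing aid (or just an open ear canal) in the other. Because
the two ears differ in residual hearing and in which devices are switched
on, a given sound can be far more audible in one ear than in the other —
and the imbalance depends strongly on the sound's frequency band. Listeners
in this situation tend to lateralize: they point at whichever side hears
the sound better, rather than at the sound's actual location.

This package implements that analysis chain end to end, for researchers in
auditory psychophysics and CI rehabilitation:

1. **Audibility** — from per-ear audiograms and a stimulus specification,
   compute third-octave band levels (calibrated in dB(A)), apply a
   gammatone-bandwidth correction, convert to dB HL with an embedded
   free-field reference-threshold table, subtract thresholds, clamp
   negative sensation levels at zero, and power-sum across bands into an
   overall audibility per ear. The **hearing asymmetry**
   `ΔH = audibility(implanted ear) − audibility(hearing-aid ear)` (dB).
2. **Behaviour** — extract head-saccade endpoints from orientation traces
   (20 deg/s velocity criterion), and compute the localization-bias
   proportion `p_EAS` (fraction of responses toward the implanted side),
   the RMS localization error `E_RMS`, chance-level references, and
   percentile-bootstrap confidence intervals.
3. **The model** — a logistic law linking bias to asymmetry,

   `p_EAS(ΔH) = (1 + exp(−(2 ln 9 / ω)(ΔH − θ)))⁻¹`

   with width `ω` (dB): the ΔH range over which `p_EAS` rises from 0.1 to
   0.9, and hearing-aid preference `θ` (dB): the ΔH at which responses are
   balanced, applied only when the hearing aid is on. Per-listener and
   group-level parameters are fitted simultaneously by hierarchical
   Bayesian MCMC (JAGS), summarized by posterior means, 95%
   highest-density intervals and split-Rhat diagnostics.
4. **Synthetic cohorts** — virtual listeners with ski-slope audiograms,
   device gains and known true (ω, θ), so the whole pipeline is testable
   by parameter recovery without access to per-trial participant data.

## Worked example

```r
library(easbias)

co <- generate_cohort(cohort_config(seed = 42))
#> Virtual EAS cohort: 7 listeners, 2240 trials (64 per condition)
#>   generative group omega = 43.4 dB, theta = 18.8 dB

head(subset(co$asymmetry, participant_id == "S1"))
#>  condition band delta_h audibility_eas audibility_ha
#>       A-EA   HF   26.59           26.6           0.0
#>       A-EA   LF   -6.52           36.0          42.5
#>       A-EA   MF  -11.34           26.6          37.9
#>       A-EA  MHF    2.02           27.3          25.3
```

High-frequency noise is audible only through the implant (`ΔH = +27` dB);
low- and mid-frequency noise favours the hearing-aid ear (`ΔH < 0`): the
asymmetry is frequency-dependent. Fitting the bias model to the simulated
responses:

```r
cells <- cells_from_trials(co$trials, co$asymmetry)
fit <- fit_bias_model(cells, chains = 2, warmup = 1000, iter = 2000, seed = 1)
print(fit)
#> Logistic hearing-asymmetry bias model (hierarchical)
#>   133 cells, 7 participant(s); 2 chains x 2000 iterations
#>   group theta (dB)   19.9  [14.4, 25.3] 95%-HDI
#>   group omega (dB)   47.0  [37.2, 58.3] 95%-HDI
#>   sd log-omega        0.3  [0.0, 0.5] 95%-HDI
#>   sd theta (dB)       5.8  [1.6, 10.7] 95%-HDI
#>   max split-Rhat: 1.007
```

The group posteriors recover the generative values (ω = 43.4 dB,
θ = 18.8 dB) within their 95%-HDIs. A width of ~45 dB means an asymmetry
of roughly ±22 dB is enough to push the bias to 0.9 or 0.1; a preference
of ~19 dB means that with the hearing aid on, audibility must favour the
implant by ~19 dB before responses are evenly split. The simulated mean
`E_RMS` of ~63 deg sits between the straight-ahead (46 deg) and
random-response (65 deg) chance references — side-dominated guessing, as
expected when binaural cues are this degraded:

```r
m <- run_metrics(co$trials, n_boot = 200, seed = 1)
mean(m$erms, na.rm = TRUE)        #> 63.5 deg
chance_error_straight_ahead(c(-80, 80))  #> 46.2 deg
```

A file-level pipeline (`run_simulate()`, `run_audibility()`,
`run_metrics()`, `run_fit()`) offers the same stages over long-format CSV
with JSON run manifests, and `inst/scripts/easbias.R` wraps them as shell
subcommands.

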