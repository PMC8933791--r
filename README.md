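# pscana — spontaneous postsynaptic current analysis

`pscana` analyses spontaneous excitatory and inhibitory postsynaptic
currents (sEPSC/sIPSC) in whole-cell voltage-clamp recordings, for
electrophysiologists who want the standard mini-analysis chain as scripted,
reproducible code rather than point-and-click software:

* **Event detection** at a threshold of 5× the RMS baseline noise, with a
  robust (MAD-of-differences) noise estimator and explicit, logged artifact
  rules in place of manual curation.
* **Event metrics**: amplitude, inter-event interval, 10–90% rise time,
  per-event charge (area under the waveform), and per-cell charge transfer
  per second = event frequency × mean charge per event.
* **Non-stationary noise analysis (NSNA)** — the core model.  Isolated
  events (>200 ms from any neighbour) are aligned at their 50%-rise point
  and the across-event variance–mean relation is fitted with the parabola

  σ² = i·I − I²/N + b

  (i unitary current, N channels open at peak, b background variance),
  yielding an `nsna_fit` model object with `print`, `summary`, `coef`,
  `vcov`, `predict`, `plot`, `residuals` and `simulate` methods.
* **Cohort comparison**: two-sample Kolmogorov–Smirnov tests on pooled
  event distributions, Mann–Whitney tests on per-cell quantities,
  median/IQR/5–95% summaries, optional amplitude cut-off.
* **A channel-level simulator** (Poisson event trains of binomially gating
  channels over a biexponential open-probability waveform plus Gaussian
  noise) — the model under which the NSNA equation is exact — so the whole
  pipeline is validated by parameter recovery.

## Worked example

Simulate a recording with 200 isolated events from 93 channels of 1 pA
unitary current (2 pA baseline noise), then run detection and NSNA blind:

```r
library(pscana)
set.seed(1)
onsets <- 0.3 + (0:199) * 0.4 + runif(200, -0.05, 0.05)
sim <- simulate_trace(sim_config(duration_s = max(onsets) + 0.4,
                                 event_rate_hz = 0, onset_times_s = onsets,
                                 seed = 42))
catalog <- detect_events(sim$trace)
catalog
#> Event catalog: 200 detected, 200 accepted (rms 2.08 pA, threshold 10.4 pA, inward)

fit <- nsna(sim$trace, catalog)
summary(fit)
#> Non-stationary noise analysis: sigma^2 = i*I - I^2/N + b
#>
#> Coefficients:
#>                         Estimate Std. Error
#> unitary_current_pa        1.0047     0.0083
#> n_channels               93.0451     1.2645
#> background_variance_pa2   3.9743     0.0161
#>
#> Channels open at peak: 74.41
#> Parabola peak: I = 46.74 pA, variance = 27.46 pA^2
#> R^2 = 0.9997 on 10 points (200 events); residual SD 0.974 pA^2
```

The detector found all 200 events at the 5×RMS threshold (10.4 pA, RMS
estimated at 2.08 pA against a true 2 pA); the fit recovers the injected
unitary current (1.005 vs 1 pA), channel count (93.0 vs 93) and background
variance (3.97 vs 4 pA²) to within their standard errors.  About 74
channels are open at the peak of the mean event (N × p_peak = 93 × 0.8).

A full two-cohort analysis — simulate control and treated groups, detect,
measure, fit, compare, and write TSV/JSON reports with a manifest — is one
call:

```r
res <- run_pipeline(demo_pipeline_config(), out_dir = "demo_out", seed = 1)
res$comparison
```

See the vignette (`vignettes/psc-noise-analysis.Rmd`) for the model, the
conventions chosen where the field's practice is underspecified, and known
limitations.

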