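---
title: "Spontaneous postsynaptic current analysis and non-stationary noise analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spontaneous postsynaptic current analysis and non-stationary noise analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Whole-cell voltage-clamp recordings from neurons show spontaneous
postsynaptic currents (PSCs): transient inward or outward deflections caused
by stochastic neurotransmitter release.  Two families of questions are asked
of such recordings:

* **Event-level**: how often do events occur (frequency, or equivalently the
  inter-event interval, IEI), how big are they (amplitude), how fast
  (10–90% rise time), and how much charge does each transfer?  The net drive
  a cell receives is summarised as *charge transfer per second* — the mean
  number of events per second times the mean charge per event.
* **Channel-level**: what unitary current *i* and how many channels *N*
  underlie the events?  Non-stationary noise analysis (NSNA) answers this
  from the relation between the across-event variance and the mean current
  of an ensemble of aligned events,

  $$\sigma^2(I) \;=\; iI \;-\; \frac{I^2}{N} \;+\; b,$$

  where $I$ is the mean current at a time bin, $\sigma^2$ the across-event
  variance at that bin, and $b$ the background (event-independent) variance.
  The relation is exact when the current at each instant is the sum of $N$
  independent two-state channels of amplitude $i$, each open with
  probability $p(t)$: the mean is $Nip(t)$ and the variance
  $Ni^2p(t)(1-p(t)) = iI - I^2/N$.

`pscana` implements the full chain — detection, event metrics, NSNA, and
nonparametric cohort comparison — together with a channel-level simulator,
so that every stage can be validated by *parameter recovery*: simulate with
known $(i, N, b)$, rates and amplitudes, run the pipeline blind, and check
what comes back.

## The generative model behind the simulator

`simulate_trace()` draws Poisson-timed events (or takes explicit onsets).
Each event's open-probability waveform is a difference of exponentials
normalised to `peak_open_prob`:

$$p(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r},\qquad
  t^* = \frac{\tau_r\tau_d}{\tau_d-\tau_r}\,\ln\frac{\tau_d}{\tau_r}.$$

At every sample the number of open channels is a Binomial($N$, $p(t)$) draw,
independent across samples, multiplied by $i$; Gaussian baseline noise of SD
`baseline_rms_pa` is added, the polarity sign applied (inward events
negative), and an optional zero-phase 4th-order Butterworth low-pass can be
applied.  This is deliberately the *simplest* model under which the NSNA
parabola is exact:

* **No Markov dwell times.**  Channel gating is independent per time bin.
  Real receptors have correlated open/shut sojourns; that is out of scope,
  and its absence means passing tests here do not validate NSNA against
  gating correlation.
* **Linear superposition** of overlapping events; the 200 ms isolation rule
  downstream removes overlaps from NSNA anyway.
* **White Gaussian baseline noise.**  Real recordings have 1/f and line
  components.
* **The low-pass filter is off by default.**  Filtering correlates adjacent
  samples, which shrinks per-bin binomial variance and breaks the exactness
  of the parabola — with it on, recovered $i$ is biased low by design of the
  physics, not by a defect of the fit.  The filter exists for realism of the
  trace files, not for the NSNA validation path.  (A Bessel response is the
  bench convention; the package uses a Butterworth design applied forwards
  and backwards, which has the same role here — band-limiting the noise —
  with exactly linear phase.)

Default conditions mirror a typical spontaneous-EPSC experiment: 120 s
records digitised at 20 kHz, held at −60 mV, $N = 93$, $i = 1$ pA,
$p_{peak} = 0.8$, baseline RMS 2 pA, $\tau_r = 0.5$ ms, $\tau_d = 5$ ms.
The two-cohort generator defaults place ~76 expected events over 10 control
cells and ~278 over 12 treated cells (rates 0.063 and 0.193 Hz), with the
treated amplitude scaled by 0.8 — the kind of contrast (higher frequency,
smaller amplitude) seen after early-life febrile seizures.  The rise and
decay constants and $p_{peak}$ are field conventions, not measured values;
nothing downstream depends on them beyond their plausibility.

## Detection

Events are detected where the polarity-corrected, baseline-subtracted
current exceeds `threshold_multiple` (default 5) times the RMS baseline
noise — the operating point used by standard mini-analysis software.
Decisions the convention leaves open, and how this package fixes them:

* **RMS noise estimation.**  A whole-trace RMS is biased upward by the very
  events being detected.  The default estimator first-differences the
  signal (cancelling slow drift and most of each event), takes
  $1.4826\,\mathrm{MAD}$, and divides by $\sqrt 2$.  The naive SD is kept as
  `method = "sd"` for comparison.
* **Detection geometry on a smoothed copy.**  On an unfiltered trace,
  binomial channel noise makes the raw signal re-cross the threshold many
  times during one decay.  Runs are therefore found on a 0.5 ms boxcar
  smoothing of the signal, with hysteresis: a run starts above the
  threshold and ends only when the signal falls below *half* the threshold.
  All waveform measurements (alignment, variance, charge integrand) use raw
  samples.
* **Onset** is the last sample at or below baseline + 10% of the amplitude,
  found by backward scan from the threshold crossing — this feeds the
  50%-rise alignment cleanly.
* **Overlap**: a second threshold crossing separated by at least
  `min_event_separation_ms` and a sufficient valley is a new event; such
  events count for frequency and amplitude but are excluded from NSNA by
  the isolation rule.
* **Manual curation is replaced by explicit rules** (`apply_artifact_rules()`):
  too-fast rises (< 2 samples), no decay below 50% amplitude within 100 ms,
  flat-topped saturation, pre-event baseline drifting more than 3 RMS from
  the global baseline.  Every exclusion is a flag in the catalog, so the
  "manual check" is auditable and reproducible.
* **Threshold semantics**: the baseline-subtracted peak amplitude is
  thresholded (not the raw excursion), and polarity `auto` infers the event
  sign from trace skewness rather than hard-coding "inward".

## Event metrics

* 10–90% rise time uses linear sub-sample interpolation at both level
  crossings; for a mono-exponential rise it equals $\tau\ln 9$.
* Charge is the trapezoidal integral of |baseline-subtracted current| from
  onset to the decay endpoint — the first return of the smoothed current to
  within one RMS of baseline, capped at 200 ms.  The smoothed endpoint
  matters: raw noise dips below baseline would truncate the tail several
  percent early.  1 pA·s = 1 pC.
* IEIs are defined between consecutive *accepted* onsets within one cell,
  never across cells; the first event has none.
* `charge_transfer_pc_per_s = frequency_hz * mean_charge_per_event_pc` holds
  exactly, by construction, on every cell.

## NSNA: isolation, alignment, fit

Only accepted events more than 200 ms (onset-to-onset, both sides) from any
other event *or artifact* enter the ensemble.  Onset-to-onset is a choice —
edge-to-edge would be slightly stricter; with 5 ms decay constants the
difference is immaterial.

Rows are aligned at the 50%-of-amplitude rising crossing.  The alignment
shift is rounded to a whole number of samples by default
(`shift = "nearest"`).  This is a deliberate departure from resampling each
row at fractional offsets: linear interpolation between two samples turns
independent per-bin noise of variance $v$ into $((1-f)^2+f^2)\,v$ — a one
third loss on average over fractions $f$ — which propagates into the fit as
$i$ biased low by the same factor.  Nearest-sample alignment leaves at most
half a sample of residual misalignment, whose variance contribution (slope²
× jitter²) on the decay phase is orders of magnitude below the channel
noise.  `shift = "interpolate"` remains available for averaged-waveform
work.  Cells whose ensembles align imprecisely (median absolute re-measured
50%-crossing residual ≥ 0.5 samples) are excluded, mirroring the practice of
analysing only precisely aligned cells.

The variance–mean curve is built per time bin from the *decay phase* only
(peak of the ensemble mean onward): rise-phase asynchrony inflates variance.
Points are aggregated into 10 equal-width mean-current bins by default
(stabilises the variance-of-variance; `nbins = NULL` keeps raw bins).  The
fit is linear in $(i, -1/N, b)$, weighted by (points × events)/predicted²
and iterated twice — the natural weighting since a sample variance has
sampling variance $\propto \sigma^4/(M-1)$.  Constraints and edge cases:

* $b$ is fitted freely but clamped at 0 (refit with $b = 0$) if negative;
  `fix_b` pins it to a measured pre-event baseline variance instead.
* Curvature indistinguishable from zero (the $N \to \infty$ regime) yields
  a *censored* `n_channels = Inf` with a diagnostic flag, never a spurious
  finite value.
* Degenerate inputs (all $I \approx 0$, fewer than 5 points, span below
  half the peak current) abort with explicit errors.
* Whether to fit per cell and average, or pool events across cells, is left
  to the caller; `nsna()` is per-cell, which matches per-cell distributions
  of $N$ and $i$ entering Mann–Whitney comparisons.

The fit returns an `nsna_fit` object with `print`, `summary` (delta-method
standard errors), `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`
and `simulate` methods.  For a noiseless parabola the fit reproduces
$(i, N, b)$ to better than six significant digits, and the fitted maximum
sits at $I = iN/2$ with height $i^2N/4 + b$.

## Cohort statistics

Event-level variables (amplitude, IEI, rise time) are pooled across the
cells of a cohort and compared with a two-sample Kolmogorov–Smirnov test;
per-cell variables (charge transfer per second, $N$, $i$) with a
Mann–Whitney test; distributions are summarised as median, IQR and 5–95%
interval (quantile type 7 throughout).  Pooling events across cells
reproduces the common event-count-based cumulative-probability comparison
and with it the pseudoreplication that practice entails: events from the
same cell are not independent, so KS p-values on pooled events are
anti-conservative with respect to cell-level inference.  That is a property
of the reproduced analysis, not of the implementation; per-cell medians can
always be compared via the Mann–Whitney path instead.  P-values are exact
for small tie-free samples (KS: product of sizes < 10⁴; MW: enumeration
below 50 per group) and asymptotic with tie corrections otherwise.  Tests
are two-sided at α = 0.05 with no multiplicity correction.  An optional
upper amplitude cut-off (e.g. 100 pA for IPSC work) filters pooled
amplitudes — and only amplitudes — before testing.

## A worked run

```{r}
library(pscana)
set.seed(1)
onsets <- 0.3 + (0:199) * 0.4 + runif(200, -0.05, 0.05)
sim <- simulate_trace(sim_config(duration_s = max(onsets) + 0.4,
                                 event_rate_hz = 0, onset_times_s = onsets,
                                 seed = 42))
catalog <- detect_events(sim$trace)
catalog
fit <- nsna(sim$trace, catalog)
summary(fit)
```

With the defaults above, the recovered unitary current and channel count
land within a few percent of the injected $i = 1$ pA and $N = 93$.

## Validation scale and known limitations

The test suite validates, among others: binomial mean/variance laws of the
simulator; Poisson event counts (χ² at α = .01 over 1000 replicates);
detection sensitivity and precision ≥ 0.95 with ≤ 0.05 false events/s on
noise (50 + 50 traces of 120 s); NSNA recovery of $i$ within ±10% and $N$
within ±15% in ≥ 90% of 100 ensembles of 250 isolated events; exactness of
KS and MW p-values against exhaustive enumeration for all size combinations
up to 5 + 5; and ≥ 90% power / ≤ 10% type-I error of the two-cohort pipeline
over 100 Monte-Carlo runs of 10 + 12 cells × 120 s.  The cohort Monte-Carlo
is simulated at 5 kHz: the quantities under test (event times, amplitudes,
test decisions) do not depend on the digitisation rate, and this keeps the
suite's runtime proportionate; single-trace checks use the full 20 kHz.

Limitations worth restating: no Markov gating, no series-resistance or
space-clamp artifacts, no temperature effects, no template-matching or
deconvolution detection, no per-event decay-constant fitting, and no
hierarchical (cell-within-animal) modelling — pooled-event KS inherits the
pseudoreplication discussed above.
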