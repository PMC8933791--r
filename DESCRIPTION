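Package: pscana
Title: Spontaneous Postsynaptic Current Analysis and Non-Stationary Noise Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of spontaneous excitatory and inhibitory postsynaptic
    currents (sEPSC/sIPSC) from whole-cell voltage-clamp recordings: threshold
    event detection at a multiple of the root-mean-square baseline noise,
    per-event kinetics (amplitude, inter-event interval, 10-90% rise time,
    charge transfer), ensemble non-stationary noise analysis by fitting the
    variance-mean parabola sigma^2 = i*I - I^2/N + b to estimate unitary
    current and channel count, and nonparametric cohort comparison
    (Kolmogorov-Smirnov on pooled event distributions, Mann-Whitney on
    per-cell quantities).  Includes a channel-level simulator of voltage-clamp
    traces (Poisson event trains of binomially gating unitary channels over a
    biexponential open-probability waveform plus Gaussian baseline noise) so
    every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
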