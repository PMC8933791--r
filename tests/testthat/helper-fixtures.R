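# Shared fixtures and independent oracles for the test suite.

# Build a psc_events catalog by hand (for operations that consume catalogs
# independently of the detector).
make_catalog <- function(onset_index, peak_index = onset_index + 1L,
                         baseline_pa = 0, amplitude_pa = 1,
                         fs = 20000, rms = 0, polarity = "outward",
                         accepted = TRUE, duration_s = NULL) {
  k <- length(onset_index)
  df <- data.frame(
    onset_index = as.integer(onset_index),
    peak_index = as.integer(peak_index),
    onset_s = (onset_index - 1) / fs,
    peak_s = (peak_index - 1) / fs,
    baseline_pa = rep_len(baseline_pa, k),
    amplitude_pa = rep_len(amplitude_pa, k),
    flag = ifelse(rep_len(accepted, k), "accepted", "artifact:test"),
    accepted = rep_len(accepted, k),
    stringsAsFactors = FALSE)
  structure(df, class = c("psc_events", "data.frame"),
            rms_noise_pa = rms, threshold_pa = 5 * rms,
            global_baseline_pa = 0, polarity = polarity,
            sampling_rate_hz = fs,
            duration_s = duration_s %||% (max(peak_index) / fs + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-permutation oracle for the two-sample KS p-value (tie-free).
ks_perm_p <- function(a, b) {
  n1 <- length(a); pool <- c(a, b)
  D_of <- function(x, y) {
    v <- sort(unique(c(x, y)))
    max(abs(stats::ecdf(x)(v) - stats::ecdf(y)(v)))
  }
  d_obs <- D_of(a, b)
  idx <- utils::combn(length(pool), n1)
  ds <- apply(idx, 2, function(ii) D_of(pool[ii], pool[-ii]))
  mean(ds >= d_obs - 1e-12)
}

# Exhaustive-permutation oracle for the two-sided Mann-Whitney p-value
# (symmetric |U - n1 n2 / 2| rejection region; tie-free).
mw_perm_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); pool <- c(a, b)
  r <- rank(pool)
  U_of <- function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2
  u_obs <- U_of(seq_len(n1))
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, U_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Trace carrying a given positive-going waveform at given onset samples.
waveform_trace <- function(waveform, onset_index, n, fs = 20000,
                           noise_sd = 0, polarity = "outward", seed = NULL) {
  x <- numeric(n)
  for (j in onset_index) {
    L <- min(length(waveform), n - j + 1L)
    x[j:(j + L - 1L)] <- x[j:(j + L - 1L)] + waveform[seq_len(L)]
  }
  if (polarity == "inward") x <- -x
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(n, 0, noise_sd)
  }
  psc_trace(x, sampling_rate_hz = fs)
}

# A jittered regular grid of guaranteed-isolated onsets (>200 ms apart).
isolated_onsets <- function(k, spacing_s = 0.4, jitter_s = 0.05) {
  0.3 + (seq_len(k) - 1) * spacing_s + runif(k, -jitter_s, jitter_s)
}

# Ensemble fixture: trace with k isolated binomial-channel events plus the
# config used (defaults mirror the sEPSC-like study conditions).
isolated_event_sim <- function(k = 250, seed = 1, ...) {
  set.seed(seed)
  onsets <- isolated_onsets(k)
  cfg <- sim_config(duration_s = max(onsets) + 0.4, event_rate_hz = 0,
                    onset_times_s = onsets, seed = seed + 1000L, ...)
  simulate_trace(cfg)
}

# Build an aligned binomial ensemble matrix directly (rows = events), for
# NSNA tests that do not need the detection stage.
binomial_ensemble <- function(n_events, n_channels, unitary_pa, p_waveform,
                              noise_sd = 0) {
  m <- matrix(rbinom(n_events * length(p_waveform), n_channels,
                     rep(p_waveform, each = n_events)) * unitary_pa,
              nrow = n_events)
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  structure(m, class = c("psc_ensemble", class(m)),
            align_col = 1L, dt_ms = 0.05, quality = rep(0, n_events),
            baseline_var_pa2 = noise_sd^2)
}
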