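#' Simulation configuration for synthetic voltage-clamp recordings
#'
#' Defines the generative model for a synthetic spontaneous-PSC recording:
#' synaptic events occur as a Poisson process in time; each event's current
#' arises from `n_channels` independent unitary channels of amplitude
#' `unitary_current_pa` that gate open with a biexponential open-probability
#' waveform peaking at `peak_open_prob`; Gaussian baseline noise is
#' superimposed and an optional low-pass filter applied.  This is the model
#' under which the non-stationary noise relation
#' \eqn{\sigma^2 = iI - I^2/N + b} is exact, which makes parameter recovery a
#' meaningful end-to-end check of the analysis pipeline.
#'
#' Defaults mirror typical spontaneous-EPSC recording conditions: 120 s
#' recordings digitised at 20 kHz at a holding potential of -60 mV, with
#' N = 93 channels of i = 1 pA unitary current and 2 pA RMS baseline noise.
#'
#' @param duration_s Recording length in seconds.
#' @param sampling_rate_hz Digitisation rate in Hz.
#' @param event_rate_hz Mean Poisson rate of synaptic events (events/s).
#' @param n_channels Integer N >= 1, channels per synapse.
#' @param unitary_current_pa Unitary current magnitude i > 0 (pA).
#' @param peak_open_prob Peak open probability in (0, 1].
#' @param tau_rise_ms,tau_decay_ms Rise and decay time constants of the
#'   open-probability waveform (ms); `tau_decay_ms > tau_rise_ms`.
#' @param baseline_rms_pa Gaussian baseline noise RMS (pA, >= 0).
#' @param polarity `"inward"` (events deflect negative, the convention at
#'   -60 mV) or `"outward"`.
#' @param lowpass_cutoff_hz Optional low-pass corner frequency in
#'   \[1000, 5000\] Hz (4th-order Butterworth applied zero-phase), or `NULL`
#'   for no filtering.  The default is `NULL` because filtering correlates
#'   adjacent samples and so perturbs the per-bin binomial variance the NSNA
#'   model assumes.
#' @param seed Integer RNG seed or `NULL`.
#' @param onset_times_s Optional explicit event onset times (s); overrides
#'   the Poisson process (used e.g. to lay out guaranteed-isolated events).
#' @param cell_id,cohort,recording_type,holding_potential_mv Metadata copied
#'   into the simulated trace.
#' @return A list of class `psc_sim_config`.
#' @seealso [simulate_trace()], [simulate_cohort()]
#' @export
sim_config <- function(duration_s = 120, sampling_rate_hz = 20000,
                       event_rate_hz = 0.2, n_channels = 93,
                       unitary_current_pa = 1, peak_open_prob = 0.8,
                       tau_rise_ms = 0.5, tau_decay_ms = 5,
                       baseline_rms_pa = 2,
                       polarity = c("inward", "outward"),
                       lowpass_cutoff_hz = NULL, seed = NULL,
                       onset_times_s = NULL,
                       cell_id = "cell01", cohort = "NT",
                       recording_type = "sEPSC",
                       holding_potential_mv = -60) {
  polarity <- match.arg(polarity)
  cfg <- list(duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
              event_rate_hz = event_rate_hz, n_channels = n_channels,
              unitary_current_pa = unitary_current_pa,
              peak_open_prob = peak_open_prob,
              tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
              baseline_rms_pa = baseline_rms_pa, polarity = polarity,
              lowpass_cutoff_hz = lowpass_cutoff_hz, seed = seed,
              onset_times_s = onset_times_s,
              cell_id = cell_id, cohort = cohort,
              recording_type = recording_type,
              holding_potential_mv = holding_potential_mv)
  validate_sim_config(cfg)
  structure(cfg, class = "psc_sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (duration_s <= 0) stop("duration_s must be positive")
    if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
    if (event_rate_hz < 0) stop("event_rate_hz must be >= 0")
    if (n_channels < 1 || n_channels != round(n_channels))
      stop("n_channels must be an integer >= 1")
    if (unitary_current_pa <= 0) stop("unitary_current_pa must be > 0")
    if (peak_open_prob <= 0 || peak_open_prob > 1)
      stop("peak_open_prob must be in (0, 1]")
    if (tau_rise_ms <= 0) stop("tau_rise_ms must be > 0")
    if (tau_decay_ms <= tau_rise_ms)
      stop("tau_decay_ms must exceed tau_rise_ms")
    if (baseline_rms_pa < 0) stop("baseline_rms_pa must be >= 0")
    if (!is.null(lowpass_cutoff_hz) &&
        (lowpass_cutoff_hz < 1000 || lowpass_cutoff_hz > 5000))
      stop("lowpass_cutoff_hz must lie in [1000, 5000]")
    if (!is.null(onset_times_s)) {
      if (is.unsorted(onset_times_s, strictly = TRUE))
        stop("onset_times_s must be strictly increasing")
      if (any(onset_times_s < 0) || any(onset_times_s > duration_s))
        stop("onset_times_s must lie within [0, duration_s]")
    }
  })
  invisible(cfg)
}

#' Biexponential channel open-probability waveform
#'
#' The open probability follows a difference of exponentials,
#' \eqn{p(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}}, normalised analytically
#' so its maximum equals `peak_open_prob`.  The maximum occurs at
#' \eqn{t^* = \tau_r\tau_d/(\tau_d-\tau_r)\,\log(\tau_d/\tau_r)}.
#'
#' @param tau_rise_ms,tau_decay_ms Time constants (ms), decay > rise > 0.
#' @param peak_open_prob Peak open probability in (0, 1].
#' @param dt_ms Sample interval (ms).
#' @param horizon_ms Waveform length (ms); default `tau_rise_ms +
#'   10 * tau_decay_ms`, by which point p(t) has decayed below 1e-4 of peak.
#' @return Numeric vector p(t) on the grid `seq(0, horizon_ms, by = dt_ms)`,
#'   with p(0) = 0 and all values in \[0, peak_open_prob\].
#' @examples
#' p <- open_prob_waveform(0.5, 5, 1, dt_ms = 0.05)
#' max(p)            # ~1 (up to grid discretisation)
#' @export
open_prob_waveform <- function(tau_rise_ms, tau_decay_ms, peak_open_prob,
                               dt_ms, horizon_ms = NULL) {
  if (tau_rise_ms <= 0 || tau_decay_ms <= tau_rise_ms)
    stop("require tau_decay_ms > tau_rise_ms > 0")
  if (peak_open_prob <= 0 || peak_open_prob > 1)
    stop("peak_open_prob must be in (0, 1]")
  if (dt_ms <= 0) stop("dt_ms must be > 0")
  horizon_ms <- horizon_ms %||% (tau_rise_ms + 10 * tau_decay_ms)
  t <- seq(0, horizon_ms, by = dt_ms)
  raw <- exp(-t / tau_decay_ms) - exp(-t / tau_rise_ms)
  t_star <- tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
  peak_raw <- exp(-t_star / tau_decay_ms) - exp(-t_star / tau_rise_ms)
  p <- peak_open_prob * raw / peak_raw
  pmin(pmax(p, 0), 1)
}

#' Sample a single event's channel current
#'
#' At each time bin the number of open channels is drawn as
#' Binomial(`n_channels`, p(t)), independently across bins, and multiplied by
#' the unitary current.  Hence the per-bin mean is \eqn{N i p(t)} and the
#' variance \eqn{N i^2 p(t)(1-p(t))} — the generative inverse of the NSNA
#' variance-mean relation.
#'
#' @param p_waveform Open-probability waveform (see [open_prob_waveform()]).
#' @param n_channels Integer N >= 1.
#' @param unitary_current_pa Unitary current i > 0 (pA).
#' @param seed Optional RNG seed (the caller's RNG state is preserved).
#' @return Numeric vector of event current (pA, positive).
#' @export
sample_event_current <- function(p_waveform, n_channels, unitary_current_pa,
                                 seed = NULL) {
  if (!length(p_waveform)) stop("empty open-probability waveform")
  if (n_channels < 1 || n_channels != round(n_channels))
    stop("n_channels must be an integer >= 1")
  if (unitary_current_pa <= 0) stop("unitary_current_pa must be > 0")
  with_seed(seed,
            unitary_current_pa * rbinom(length(p_waveform),
                                        size = n_channels, prob = p_waveform))
}

#' Simulate a whole-cell voltage-clamp recording
#'
#' Composes Poisson-timed (or explicitly placed) synaptic events, each drawn
#' from the binomial channel model, with Gaussian baseline noise and an
#' optional zero-phase low-pass filter.  Overlapping events superpose
#' linearly.  Identical configs (including seed) reproduce the trace
#' bit-for-bit.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{trace}{a [psc_trace()] (pA, physical sign)}
#'     \item{events}{ground-truth event train: data frame with `onset_s`
#'       (grid-aligned), `n_channels`, `unitary_pa`, `tau_rise_ms`,
#'       `tau_decay_ms`, `p_peak`}
#'   }
#' @examples
#' sim <- simulate_trace(sim_config(duration_s = 2, event_rate_hz = 1, seed = 1))
#' sim$trace
#' nrow(sim$events)
#' @export
simulate_trace <- function(config) {
  validate_sim_config(config)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  dt_ms <- 1000 / fs
  with_seed(config$seed, {
    if (is.null(config$onset_times_s)) {
      k <- rpois(1, config$event_rate_hz * config$duration_s)
      onsets <- sort(runif(k, 0, config$duration_s))
    } else {
      onsets <- config$onset_times_s
    }
    idx0 <- pmin(round(onsets * fs) + 1L, n)
    keep <- !duplicated(idx0)
    idx0 <- idx0[keep]
    p <- open_prob_waveform(config$tau_rise_ms, config$tau_decay_ms,
                            config$peak_open_prob, dt_ms)
    ev_component <- numeric(n)
    for (j in idx0) {
      L <- min(length(p), n - j + 1L)
      ev_component[j:(j + L - 1L)] <- ev_component[j:(j + L - 1L)] +
        config$unitary_current_pa * rbinom(L, config$n_channels, p[seq_len(L)])
    }
    sgn <- if (config$polarity == "inward") -1 else 1
    cur <- sgn * ev_component
    if (config$baseline_rms_pa > 0)
      cur <- cur + rnorm(n, 0, config$baseline_rms_pa)
    if (!is.null(config$lowpass_cutoff_hz)) {
      bf <- signal::butter(4, config$lowpass_cutoff_hz / (fs / 2), "low")
      cur <- signal::filtfilt(bf, cur)
    }
    trace <- psc_trace(
      cur, sampling_rate_hz = fs,
      metadata = list(cell_id = config$cell_id, cohort = config$cohort,
                      recording_type = config$recording_type,
                      holding_potential_mv = config$holding_potential_mv,
                      filter = if (is.null(config$lowpass_cutoff_hz)) "none"
                               else sprintf("butterworth4 %g Hz zero-phase",
                                            config$lowpass_cutoff_hz)))
    events <- data.frame(
      onset_s = (idx0 - 1L) / fs,
      n_channels = rep(config$n_channels, length(idx0)),
      unitary_pa = rep(config$unitary_current_pa, length(idx0)),
      tau_rise_ms = rep(config$tau_rise_ms, length(idx0)),
      tau_decay_ms = rep(config$tau_decay_ms, length(idx0)),
      p_peak = rep(config$peak_open_prob, length(idx0)))
    list(trace = trace, events = events)
  })
}

#' Simulate two cohorts of cells
#'
#' Generates `cells_per_group` recordings per cohort from two configurations,
#' deriving one reproducible child seed per cell from `seed`.  The default
#' contrast mirrors a febrile-seizure-type comparison: the treated (HT)
#' cohort has a ~3x higher event rate and 0.8x event amplitude than the
#' normothermic (NT) control, with pooled expected event counts of about 76
#' (NT, 10 cells) and 278 (HT, 12 cells) over 120 s recordings.
#'
#' @param nt_config,ht_config [sim_config()]s for the two cohorts (per-cell
#'   seeds and cell ids are overwritten).
#' @param cells_per_group Integer vector of length 2: cells in each cohort.
#' @param seed Master seed for the cohort.
#' @return List with elements `nt` and `ht`, each a list of
#'   [simulate_trace()] results.
#' @export
simulate_cohort <- function(nt_config = sim_config(event_rate_hz = 76 / (10 * 120),
                                                   cohort = "NT"),
                            ht_config = sim_config(event_rate_hz = 278 / (12 * 120),
                                                   unitary_current_pa = 0.8,
                                                   cohort = "HT"),
                            cells_per_group = c(10, 12), seed = 1) {
  stopifnot(length(cells_per_group) == 2, all(cells_per_group >= 1))
  seeds <- derive_seeds(seed, sum(cells_per_group))
  gen <- function(cfg, n_cells, seeds, prefix) {
    lapply(seq_len(n_cells), function(k) {
      cfg$seed <- seeds[k]
      cfg$cell_id <- sprintf("%s_cell%02d", prefix, k)
      simulate_trace(cfg)
    })
  }
  list(nt = gen(nt_config, cells_per_group[1],
                seeds[seq_len(cells_per_group[1])], nt_config$cohort),
       ht = gen(ht_config, cells_per_group[2],
                seeds[cells_per_group[1] + seq_len(cells_per_group[2])],
                ht_config$cohort))
}
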