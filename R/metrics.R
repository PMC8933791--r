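#' 10-90% rise time of detected events
#'
#' Time between the first crossings of 10% and 90% of the event amplitude on
#' the rising phase (onset to peak), with linear sub-sample interpolation at
#' both crossings.  For a mono-exponential rise with time constant
#' \eqn{\tau} this equals \eqn{\tau \log 9}.
#'
#' @param trace A [psc_trace()].
#' @param catalog A `psc_events` catalog; only accepted events are measured.
#' @return Numeric vector (ms), one value per accepted event.
#' @export
rise_time_10_90 <- function(trace, catalog) {
  ev <- catalog[catalog$accepted, , drop = FALSE]
  if (!nrow(ev)) return(numeric(0))
  s <- rectify_trace(trace, attr(catalog, "polarity"))$s
  fs <- trace$sampling_rate_hz
  vapply(seq_len(nrow(ev)), function(k) {
    on <- ev$onset_index[k]; pk <- ev$peak_index[k]
    base <- ev$baseline_pa[k]; amp <- ev$amplitude_pa[k]
    seg <- s[on:pk]
    t10 <- crossing_time(seg, base + 0.1 * amp)
    t90 <- crossing_time(seg, base + 0.9 * amp)
    if (is.na(t10) || is.na(t90))
      stop("event does not cross its 10%/90% levels on the rising phase")
    max(t90 - t10, 0) / fs * 1000
  }, numeric(1))
}

# First upward crossing of `level` in `y`, as a fractional 0-based index;
# linear interpolation between the bracketing samples.
crossing_time <- function(y, level) {
  k <- which(y >= level)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  if (k == 1L) return(0)
  frac <- (level - y[k - 1L]) / (y[k] - y[k - 1L])
  (k - 2L) + frac
}

#' Per-event charge transfer
#'
#' Trapezoidal integral of the magnitude of the baseline-subtracted current
#' from the event onset to the decay endpoint: the first sample after the
#' peak at which a lightly smoothed copy of the current (boxcar of
#' `smooth_ms`) returns to within one RMS of the local baseline, capped at
#' `max_window_ms` after the peak.  The endpoint is found on the smoothed
#' copy because sample-level noise dips would otherwise truncate the decay
#' tail early; the integral itself uses the raw samples.  1 pA x 1 s = 1 pC,
#' so integrating pA against seconds yields picocoulombs directly.
#'
#' @param trace A [psc_trace()].
#' @param catalog A `psc_events` catalog; only accepted events are measured.
#' @param max_window_ms Cap on the integration window after the peak (ms).
#' @param smooth_ms Boxcar window for endpoint detection (ms).
#' @return Data frame with `charge_pc` and logical `truncated` (window cut
#'   short by the trace end), one row per accepted event.
#' @export
event_charge <- function(trace, catalog, max_window_ms = 200,
                         smooth_ms = 0.5) {
  ev <- catalog[catalog$accepted, , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(charge_pc = numeric(0), truncated = logical(0)))
  s <- rectify_trace(trace, attr(catalog, "polarity"))$s
  sm <- boxcar_smooth(s, round(smooth_ms / 1000 * trace$sampling_rate_hz))
  fs <- trace$sampling_rate_hz
  rms <- attr(catalog, "rms_noise_pa") %||% 0
  cap <- round(max_window_ms / 1000 * fs)
  n <- length(s)
  out <- lapply(seq_len(nrow(ev)), function(k) {
    on <- ev$onset_index[k]; pk <- ev$peak_index[k]
    base <- ev$baseline_pa[k]
    wend_max <- pk + cap
    truncated <- wend_max > n
    wend <- min(wend_max, n)
    post <- sm[pk:wend]
    ret <- which(post <= base + rms)
    end <- if (length(ret)) pk + ret[1] - 1L else wend
    y <- abs(s[on:end] - base)
    q <- sum((y[-1] + y[-length(y)]) / 2) / fs  # pA * s = pC
    data.frame(charge_pc = q, truncated = truncated && !length(ret))
  })
  do.call(rbind, out)
}

#' Inter-event intervals of accepted events
#'
#' Intervals between consecutive accepted event onsets within one recording.
#' The first event contributes no interval; fewer than two accepted events
#' yield an empty vector.
#'
#' @param catalog A `psc_events` catalog.
#' @return Numeric vector of intervals (ms), length `n_accepted - 1`.
#' @export
inter_event_intervals <- function(catalog) {
  on <- catalog$onset_s[catalog$accepted]
  if (length(on) < 2) return(numeric(0))
  diff(on) * 1000
}

#' Per-event metrics table
#'
#' Combines amplitude, inter-event interval, 10-90% rise time, and charge
#' for every accepted event of a catalog.
#'
#' @inheritParams event_charge
#' @return Data frame with one row per accepted event: `onset_s`,
#'   `amplitude_pa`, `iei_ms` (NA for the first event), `rise_10_90_ms`,
#'   `charge_pc`, `charge_truncated`.
#' @export
event_metrics <- function(trace, catalog, max_window_ms = 200) {
  ev <- catalog[catalog$accepted, , drop = FALSE]
  ch <- event_charge(trace, catalog, max_window_ms)
  iei <- if (nrow(ev)) c(NA_real_, inter_event_intervals(catalog))
         else numeric(0)
  data.frame(
    onset_s = ev$onset_s,
    amplitude_pa = ev$amplitude_pa,
    iei_ms = iei,
    rise_10_90_ms = rise_time_10_90(trace, catalog),
    charge_pc = ch$charge_pc,
    charge_truncated = ch$truncated)
}

#' Per-cell summary: frequency and charge transfer per second
#'
#' The charge transfer per second is the product of the mean number of events
#' per second and the mean charge transfer per event; the identity
#' `charge_transfer_pc_per_s == frequency_hz * mean_charge_per_event_pc`
#' holds exactly by construction.  An empty table yields zero frequency and
#' zero charge transfer.
#'
#' @param metrics An [event_metrics()] table.
#' @param duration_s Recording duration (s, > 0).
#' @param cell_id,cohort Labels copied into the summary row.
#' @return One-row data frame (`cell_id`, `cohort`, `n_events`,
#'   `duration_s`, `frequency_hz`, `mean_amplitude_pa`,
#'   `mean_charge_per_event_pc`, `charge_transfer_pc_per_s`).
#' @export
summarize_cell <- function(metrics, duration_s, cell_id = NA_character_,
                           cohort = NA_character_) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  n <- nrow(metrics)
  freq <- n / duration_s
  mean_q <- if (n) mean(metrics$charge_pc) else 0
  data.frame(cell_id = cell_id, cohort = cohort, n_events = n,
             duration_s = duration_s, frequency_hz = freq,
             mean_amplitude_pa = if (n) mean(metrics$amplitude_pa) else 0,
             mean_charge_per_event_pc = mean_q,
             charge_transfer_pc_per_s = freq * mean_q,
             stringsAsFactors = FALSE)
}
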