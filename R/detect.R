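#' Detection configuration
#'
#' Parameters for threshold event detection and the automated artifact rules
#' that stand in for manual curation.
#'
#' @param threshold_multiple Detection threshold as a multiple of the RMS
#'   baseline noise (default 5, the conventional operating point for
#'   spontaneous-PSC detection).
#' @param min_event_separation_ms Minimum separation between accepted peaks
#'   (ms); closer supra-threshold maxima are merged into one event.
#' @param baseline_window_ms Pre-onset window used for the local baseline
#'   (median) of each event (ms).
#' @param onset_fraction Fraction of the event amplitude defining the onset:
#'   the onset is the last pre-crossing sample at or below
#'   `baseline + onset_fraction * amplitude` (default 0.1).
#' @param smooth_ms Boxcar smoothing window (ms) applied to the working
#'   signal for detection geometry (threshold runs, peaks, onsets); set to 0
#'   to detect on the raw samples.  Smoothing suppresses the threshold
#'   re-crossing chatter that channel noise produces on unfiltered traces;
#'   event waveform measurements downstream always use the raw samples.
#' @param polarity `"auto"` infers the event sign from the skewness of the
#'   trace; `"inward"`/`"outward"` force it.
#' @param rms_method Noise estimator passed to [estimate_rms_noise()].
#' @param artifact_too_fast_samples Events whose onset-to-peak time is below
#'   this many samples are flagged `artifact:too_fast` (default 2).
#' @param artifact_decay_window_ms Window after the peak within which the
#'   current must return below 50% of the amplitude, else
#'   `artifact:no_decay` (default 100; the rule is skipped when the window
#'   is truncated by a following event or the trace end).
#' @param artifact_drift_multiple Events whose local baseline deviates from
#'   the global baseline by more than this multiple of the RMS noise are
#'   flagged `artifact:baseline_drift` (default 3).
#' @return A list of class `psc_detect_config`.
#' @export
detect_config <- function(threshold_multiple = 5,
                          min_event_separation_ms = 2,
                          baseline_window_ms = 5,
                          onset_fraction = 0.1,
                          smooth_ms = 0.5,
                          polarity = c("auto", "inward", "outward"),
                          rms_method = c("robust", "sd"),
                          artifact_too_fast_samples = 2,
                          artifact_decay_window_ms = 100,
                          artifact_drift_multiple = 3) {
  polarity <- match.arg(polarity)
  rms_method <- match.arg(rms_method)
  if (threshold_multiple <= 0) stop("threshold_multiple must be > 0")
  if (min_event_separation_ms <= 0 || baseline_window_ms <= 0)
    stop("window parameters must be positive")
  if (onset_fraction <= 0 || onset_fraction >= 1)
    stop("onset_fraction must be in (0, 1)")
  structure(list(threshold_multiple = threshold_multiple,
                 min_event_separation_ms = min_event_separation_ms,
                 baseline_window_ms = baseline_window_ms,
                 onset_fraction = onset_fraction, smooth_ms = smooth_ms,
                 polarity = polarity, rms_method = rms_method,
                 artifact_too_fast_samples = artifact_too_fast_samples,
                 artifact_decay_window_ms = artifact_decay_window_ms,
                 artifact_drift_multiple = artifact_drift_multiple),
            class = "psc_detect_config")
}

#' Estimate the RMS baseline noise of a trace
#'
#' The default `"robust"` estimator first-differences the signal (which
#' cancels slow baseline components and most of each event waveform), takes
#' 1.4826 times the median absolute deviation of the differences, and divides
#' by \eqn{\sqrt{2}} to undo the variance doubling of differencing.  On
#' Gaussian noise it is consistent for the noise SD, and it is barely
#' perturbed by sparse synaptic events.  `"sd"` is the naive whole-trace
#' standard deviation, biased upwards by events.
#'
#' @param trace A [psc_trace()] or numeric vector.
#' @param method `"robust"` (default) or `"sd"`.
#' @param n_max Maximum number of samples used (strided subsample); `Inf`
#'   uses the full trace.
#' @return Noise RMS in pA (>= 0; an all-constant trace returns 0).
#' @examples
#' estimate_rms_noise(rnorm(1e5, sd = 2))
#' @export
estimate_rms_noise <- function(trace, method = c("robust", "sd"),
                               n_max = Inf) {
  method <- match.arg(method)
  x <- if (inherits(trace, "psc_trace")) trace$current_pa else as.numeric(trace)
  n <- length(x)
  if (n < 2) return(0)
  if (is.finite(n_max) && n > n_max) {
    stride <- ceiling(n / n_max)
    x <- x[seq(1L, n, by = stride)]
  }
  if (method == "sd") return(sd(x))
  d <- diff(x)
  1.4826 * median(abs(d - median(d))) / sqrt(2)
}

# Polarity-corrected working signal: events deflect positive.
rectify_trace <- function(trace, polarity) {
  x <- trace$current_pa
  if (polarity == "auto") {
    mu <- mean(x)
    polarity <- if (mean((x - mu)^3) < 0) "inward" else "outward"
  }
  list(s = if (polarity == "inward") -x else x, polarity = polarity)
}

# Centred boxcar moving average (window forced odd); edges keep raw values.
boxcar_smooth <- function(x, width) {
  n <- length(x)
  if (width < 2 || n < width) return(x)
  width <- width + (1L - width %% 2L)
  h <- width %/% 2L
  cs <- cumsum(x)
  out <- x
  out[(h + 1L):(n - h)] <- (cs[(2L * h + 1L):n] -
                              c(0, cs[seq_len(n - 2L * h - 1L)])) / width
  out
}

# Local maxima indices of a short vector (strict on the left, >= on the right
# so plateaus report their first sample).
local_maxima <- function(y) {
  n <- length(y)
  if (n == 1L) return(1L)
  up <- c(TRUE, diff(y) > 0)
  down <- c(diff(y) <= 0, TRUE)
  cand <- which(up & down)
  if (!length(cand)) cand <- which.max(y)
  cand
}

#' Detect spontaneous synaptic events by threshold crossing
#'
#' Events are detected where the polarity-corrected, baseline-subtracted
#' current exceeds `threshold_multiple` times the RMS baseline noise.  Each
#' contiguous supra-threshold run yields one event per sufficiently prominent
#' local maximum (so overlapping events riding on a decay are split); the
#' event onset is found by backward scan as the last sample at or below
#' baseline + `onset_fraction` x amplitude; the local baseline is the median
#' of the `baseline_window_ms` window before the threshold crossing.
#' Detection is deterministic, and [apply_artifact_rules()] is applied before
#' returning unless `apply_artifacts = FALSE`.
#'
#' @param trace A [psc_trace()].
#' @param config A [detect_config()].
#' @param apply_artifacts Run the artifact rules on the catalog (default
#'   `TRUE`).
#' @return A `psc_events` data frame with one row per detected event
#'   (columns `onset_index`, `peak_index`, `onset_s`, `peak_s`,
#'   `baseline_pa`, `amplitude_pa`, `flag`, `accepted`) and attributes
#'   `rms_noise_pa`, `threshold_pa`, `polarity`, `sampling_rate_hz`,
#'   `duration_s`.  Baselines and amplitudes are reported on the
#'   polarity-corrected scale, i.e. amplitudes are magnitudes.
#' @export
detect_events <- function(trace, config = detect_config(),
                          apply_artifacts = TRUE) {
  stopifnot(inherits(trace, "psc_trace"))
  fs <- trace$sampling_rate_hz
  bw <- max(1L, round(config$baseline_window_ms / 1000 * fs))
  if (length(trace) <= bw)
    stop("trace shorter than the baseline window")
  rt <- rectify_trace(trace, config$polarity)
  s <- rt$s
  n <- length(s)
  rms <- estimate_rms_noise(s, method = config$rms_method, n_max = 1e5)
  med <- {
    stride <- max(1L, ceiling(n / 2e5))
    median(s[seq(1L, n, by = stride)])
  }
  thr_height <- config$threshold_multiple * rms
  thr <- med + thr_height
  min_sep <- max(1L, round(config$min_event_separation_ms / 1000 * fs))

  # boxcar-smoothed working copy for detection geometry
  sd_ <- boxcar_smooth(s, round(config$smooth_ms / 1000 * fs))

  # hysteresis: an event run starts when the smoothed signal exceeds the
  # threshold and extends until it falls back below half the threshold
  # height, so channel-noise chatter during a decay does not re-trigger
  lo <- sd_ > med + thr_height / 2
  hi <- sd_ > thr
  dd <- diff(c(FALSE, lo, FALSE))
  starts <- which(dd == 1L)
  ends <- which(dd == -1L) - 1L
  has_hi <- vapply(seq_along(starts),
                   function(r) any(hi[starts[r]:ends[r]]), logical(1))
  starts <- starts[has_hi]; ends <- ends[has_hi]

  rows <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    st <- starts[r]; en <- ends[r]
    seg <- sd_[st:en]
    pk_rel <- local_maxima(seg)
    # keep prominent peaks: greedy by height, requiring separation and a
    # valley at least one threshold-height below the smaller peak
    ord <- pk_rel[order(seg[pk_rel], decreasing = TRUE)]
    kept <- integer(0)
    for (c0 in ord) {
      ok <- TRUE
      for (a in kept) {
        if (abs(c0 - a) < min_sep) { ok <- FALSE; break }
        rng <- if (c0 < a) c0:a else a:c0
        valley <- min(seg[rng])
        if (valley > min(seg[c0], seg[a]) - thr_height) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, c0)
    }
    kept <- sort(kept)
    ev <- vector("list", length(kept))
    for (q in seq_along(kept)) {
      peak <- st + kept[q] - 1L
      if (q == 1L) {
        cross <- st
        b0 <- max(1L, cross - bw)
        base <- if (cross > 1L) median(sd_[b0:(cross - 1L)]) else med
      } else {
        # secondary event on a decay: reference point is the valley before it
        valley_rel <- which.min(seg[kept[q - 1L]:kept[q]]) + kept[q - 1L] - 1L
        cross <- st + valley_rel - 1L
        base <- sd_[cross]
      }
      amp <- sd_[peak] - base
      lev <- base + config$onset_fraction * amp
      onset <- cross
      while (onset > 1L && sd_[onset] > lev && (cross - onset) < 10 * bw)
        onset <- onset - 1L
      ev[[q]] <- c(onset, peak, base, amp)
    }
    rows[[r]] <- do.call(rbind, ev)
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), ncol = 4)
  catalog <- data.frame(
    onset_index = as.integer(m[, 1]),
    peak_index = as.integer(m[, 2]),
    onset_s = trace$t0_s + (m[, 1] - 1) / fs,
    peak_s = trace$t0_s + (m[, 2] - 1) / fs,
    baseline_pa = m[, 3],
    amplitude_pa = m[, 4],
    flag = rep("accepted", nrow(m)),
    accepted = rep(TRUE, nrow(m)),
    stringsAsFactors = FALSE)
  # enforce the amplitude threshold (secondary peaks measured from their valley)
  if (nrow(catalog)) {
    keep <- catalog$amplitude_pa >= thr_height
    catalog <- catalog[keep, , drop = FALSE]
    rownames(catalog) <- NULL
  }
  catalog <- structure(catalog,
                       class = c("psc_events", "data.frame"),
                       rms_noise_pa = rms, threshold_pa = thr_height,
                       global_baseline_pa = med,
                       polarity = rt$polarity, sampling_rate_hz = fs,
                       duration_s = trace_duration(trace))
  if (apply_artifacts) catalog <- apply_artifact_rules(catalog, trace, config)
  catalog
}

#' Flag detection artifacts
#'
#' Applies explicit, reproducible artifact rules in place of manual event
#' curation: spike-like rises faster than `artifact_too_fast_samples`
#' samples (`artifact:too_fast`); events that do not fall back below 50% of
#' their amplitude within `artifact_decay_window_ms` (`artifact:no_decay`;
#' skipped when the window is cut short by the trace end); flat-topped
#' saturating peaks (`artifact:saturation`); and events whose local baseline
#' drifts more than `artifact_drift_multiple` x RMS from the global baseline
#' (`artifact:baseline_drift`).  Idempotent: re-applying the rules does not
#' change flags.
#'
#' @param catalog A `psc_events` data frame from [detect_events()].
#' @param trace The trace the catalog was detected on.
#' @param config The [detect_config()] used.
#' @return The catalog with `flag`/`accepted` updated.
#' @export
apply_artifact_rules <- function(catalog, trace, config = detect_config()) {
  if (!nrow(catalog)) return(catalog)
  rt <- rectify_trace(trace, attr(catalog, "polarity") %||% config$polarity)
  s <- rt$s
  n <- length(s)
  fs <- attr(catalog, "sampling_rate_hz")
  rms <- attr(catalog, "rms_noise_pa")
  med <- attr(catalog, "global_baseline_pa") %||% median(s)
  decay_w <- round(config$artifact_decay_window_ms / 1000 * fs)
  flags <- catalog$flag
  for (k in seq_len(nrow(catalog))) {
    if (startsWith(flags[k], "artifact")) next
    peak <- catalog$peak_index[k]
    onset <- catalog$onset_index[k]
    base <- catalog$baseline_pa[k]
    amp <- catalog$amplitude_pa[k]
    if ((peak - onset) < config$artifact_too_fast_samples) {
      flags[k] <- "artifact:too_fast"; next
    }
    if (peak > 1L && peak < n &&
        s[peak] == s[peak - 1L] && s[peak] == s[peak + 1L]) {
      flags[k] <- "artifact:saturation"; next
    }
    if (abs(base - med) > config$artifact_drift_multiple * rms) {
      flags[k] <- "artifact:baseline_drift"; next
    }
    wend <- min(peak + decay_w, n)
    if ((wend - peak) >= decay_w) {  # skipped when cut short by the trace end
      if (min(s[peak:wend]) > base + 0.5 * amp)
        flags[k] <- "artifact:no_decay"
    }
  }
  catalog$flag <- flags
  catalog$accepted <- flags == "accepted"
  catalog
}

#' @export
print.psc_events <- function(x, ...) {
  cat(sprintf("Event catalog: %d detected, %d accepted (rms %.3g pA, threshold %.3g pA, %s)\n",
              nrow(x), sum(x$accepted), attr(x, "rms_noise_pa"),
              attr(x, "threshold_pa"), attr(x, "polarity")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
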