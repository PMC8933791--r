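#' Construct a voltage-clamp current trace
#'
#' A `psc_trace` holds one cell's membrane current recording: a uniformly
#' sampled numeric vector in picoamperes (physical sign: inward currents
#' negative) plus recording metadata.
#'
#' @param current_pa Numeric vector of membrane current samples (pA).
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample in seconds.
#' @param metadata Named list of recording metadata.  Conventional entries:
#'   `cell_id`, `cohort`, `recording_type` ("sEPSC"/"sIPSC"),
#'   `holding_potential_mv`, `filter`.
#' @return An object of class `psc_trace`.
#' @examples
#' tr <- psc_trace(rnorm(2000), sampling_rate_hz = 20000)
#' tr
#' @export
psc_trace <- function(current_pa, sampling_rate_hz, t0_s = 0,
                      metadata = list()) {
  current_pa <- as.numeric(current_pa)
  if (!all(is.finite(current_pa)))
    stop("trace samples must be finite")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  structure(
    list(current_pa = current_pa,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         t0_s = as.numeric(t0_s),
         metadata = metadata),
    class = "psc_trace"
  )
}

#' @export
print.psc_trace <- function(x, ...) {
  dur <- length(x$current_pa) / x$sampling_rate_hz
  md <- x$metadata
  cat(sprintf("Voltage-clamp current trace: %d samples, %.6g s at %g kHz\n",
              length(x$current_pa), dur, x$sampling_rate_hz / 1000))
  if (length(md)) {
    lab <- vapply(md, function(v) paste(format(v), collapse = " "), "")
    cat("  ", paste(names(md), lab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  current range [%.3g, %.3g] pA\n",
              min(x$current_pa), max(x$current_pa)))
  invisible(x)
}

#' @export
length.psc_trace <- function(x) length(x$current_pa)

# Time axis in seconds.
trace_times <- function(trace) {
  trace$t0_s + (seq_along(trace$current_pa) - 1L) / trace$sampling_rate_hz
}

trace_duration <- function(trace) {
  length(trace$current_pa) / trace$sampling_rate_hz
}

#' Read and write traces as two-column CSV
#'
#' The text interchange format is a CSV with header `time_s,current_pA`,
#' preceded by `# key: value` comment lines carrying the sampling rate and
#' metadata.  `write_trace()` serialises samples at full double precision so
#' a round trip preserves them bit-exactly; `read_trace()` checks that the
#' time column is uniformly spaced (relative jitter below 1 ppm) and infers
#' the sampling rate from it.
#'
#' @param path File path.
#' @param trace A [psc_trace()].
#' @return `read_trace()` returns a `psc_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  all_lines <- readLines(path)
  hdr <- grep("^#", all_lines, value = TRUE)
  body <- grep("^#", all_lines, invert = TRUE)
  first <- all_lines[body[1]]
  if (!grepl("time_s", first) || !grepl("current_pA", first))
    stop("unrecognised trace CSV: expected header 'time_s,current_pA'")
  df <- read.table(text = all_lines[body], header = TRUE, sep = ",")
  if (!is.numeric(df$current_pA) || anyNA(df$current_pA))
    stop("non-numeric current samples in ", path)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  n <- nrow(df)
  if (n >= 2) {
    dt <- diff(df$time_s)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt))
      stop("irregular time spacing in ", path,
           ": trace samples must be uniform")
    rate <- 1 / mean(dt)
  } else {
    rate <- as.numeric(meta$sampling_rate_hz %||% NA)
    if (is.na(rate)) stop("missing sampling rate for single-sample trace")
  }
  if (!is.null(meta$sampling_rate_hz)) {
    rate_meta <- as.numeric(meta$sampling_rate_hz)
    if (is.finite(rate_meta) && abs(rate_meta - rate) < 1e-3 * rate_meta)
      rate <- rate_meta
  }
  meta$sampling_rate_hz <- NULL
  t0 <- if (n) df$time_s[1] else 0
  for (k in c("holding_potential_mv")) {
    if (!is.null(meta[[k]])) meta[[k]] <- as.numeric(meta[[k]])
  }
  psc_trace(df$current_pA, sampling_rate_hz = rate, t0_s = t0, metadata = meta)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "psc_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.17g", trace$sampling_rate_hz), con)
  for (k in names(trace$metadata)) {
    writeLines(sprintf("# %s: %s", k,
                       paste(format(trace$metadata[[k]]), collapse = " ")), con)
  }
  writeLines("time_s,current_pA", con)
  tt <- trace_times(trace)
  writeLines(sprintf("%.17g,%.17g", tt, trace$current_pa), con)
  invisible(path)
}

#' Read and write event catalogs as TSV
#'
#' Columns: `onset_s`, `peak_s`, `baseline_pa`, `amplitude_pa`, `flag`.
#' The RMS noise and detection threshold are carried as `# key: value`
#' header comments.
#'
#' @param catalog A `psc_events` data frame from [detect_events()].
#' @param path File path.
#' @return `read_events()` returns a `psc_events` data frame;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("rms_noise_pa", "threshold_pa", "sampling_rate_hz")) {
    v <- attr(catalog, k)
    if (!is.null(v)) writeLines(sprintf("# %s: %.17g", k, v), con)
  }
  pol <- attr(catalog, "polarity")
  if (!is.null(pol)) writeLines(paste0("# polarity: ", pol), con)
  df <- as.data.frame(catalog)[, c("onset_s", "peak_s", "baseline_pa",
                                   "amplitude_pa", "flag")]
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(sprintf("%.17g\t%.17g\t%.17g\t%.17g\t%s",
                       df$onset_s, df$peak_s, df$baseline_pa,
                       df$amplitude_pa, df$flag), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  all_lines <- readLines(path)
  hdr <- grep("^#", all_lines, value = TRUE)
  df <- read.table(text = grep("^#", all_lines, invert = TRUE, value = TRUE),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  rate <- as.numeric(meta$sampling_rate_hz %||% NA)
  if (is.finite(rate)) {
    df$onset_index <- as.integer(round(df$onset_s * rate)) + 1L
    df$peak_index <- as.integer(round(df$peak_s * rate)) + 1L
  }
  df$accepted <- df$flag == "accepted"
  structure(df,
            class = c("psc_events", "data.frame"),
            rms_noise_pa = as.numeric(meta$rms_noise_pa %||% NA),
            threshold_pa = as.numeric(meta$threshold_pa %||% NA),
            sampling_rate_hz = rate,
            polarity = meta$polarity %||% NA_character_)
}
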