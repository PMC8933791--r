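#' Select isolated events for noise analysis
#'
#' Keeps accepted events whose onset is more than `isolation_ms` from the
#' onset of any other detected event or artifact on either side, so that
#' ensemble statistics are not contaminated by overlapping currents.
#'
#' @param catalog A `psc_events` catalog with artifact flags resolved.
#' @param isolation_ms Minimum onset-to-onset distance (ms, default 200).
#' @return The catalog subset (attributes preserved, order preserved).
#' @export
select_isolated_events <- function(catalog, isolation_ms = 200) {
  if (!nrow(catalog)) return(catalog)
  on <- catalog$onset_s
  gap_prev <- c(Inf, diff(on)) * 1000
  gap_next <- c(diff(on), Inf) * 1000
  keep <- catalog$accepted & gap_prev > isolation_ms & gap_next > isolation_ms
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("rms_noise_pa", "threshold_pa", "global_baseline_pa",
              "polarity", "sampling_rate_hz", "duration_s"))
    attr(out, a) <- attr(catalog, a)
  class(out) <- class(catalog)
  out
}

#' Align event waveforms at their 50%-rise point
#'
#' Extracts a fixed window around each isolated event, shifted so that the
#' interpolated 50%-of-amplitude crossing on the rising phase sits at the
#' alignment column.  Rows are baseline-subtracted (local pre-event
#' baseline) and polarity-corrected to positive.  Events whose window would
#' run off the trace are dropped.
#'
#' Two shift modes are offered.  `"nearest"` (default) shifts by a whole
#' number of samples, leaving a residual misalignment of at most half a
#' sample; it is the right mode for noise analysis because resampling a row
#' between samples (`"interpolate"`) averages adjacent bins and thereby
#' shrinks the across-event variance of any bin-independent noise component
#' by \eqn{(1-f)^2 + f^2} (a one-third loss on average), which would bias
#' the fitted unitary current downward.  `"interpolate"` places the 50%
#' crossing exactly on the alignment column by linear sub-sample
#' interpolation and is appropriate when the object of interest is the
#' averaged event waveform rather than its variance.
#'
#' @param trace A [psc_trace()].
#' @param catalog Catalog of isolated accepted events (see
#'   [select_isolated_events()]).
#' @param pre_ms,post_ms Window extent before/after the alignment point (ms).
#' @param min_events Minimum number of alignable events required (default 2).
#' @param shift `"nearest"` (default) or `"interpolate"`; see Details.
#' @return A matrix of class `psc_ensemble` (rows = events, columns = time
#'   bins) with attributes `align_col`, `dt_ms`, `quality` (per-row absolute
#'   residual of the re-measured 50% crossing, in samples), and
#'   `baseline_var_pa2` (mean pre-event baseline variance across rows).
#' @export
align_events <- function(trace, catalog, pre_ms = 5, post_ms = 50,
                         min_events = 2,
                         shift = c("nearest", "interpolate")) {
  shift <- match.arg(shift)
  ev <- catalog[catalog$accepted, , drop = FALSE]
  s <- rectify_trace(trace, attr(catalog, "polarity"))$s
  fs <- trace$sampling_rate_hz
  dt_ms <- 1000 / fs
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  L <- pre + post + 1L
  align_col <- pre + 1L
  n <- length(s)
  rows <- list(); quality <- numeric(0); bvar <- numeric(0)
  for (k in seq_len(nrow(ev))) {
    on <- ev$onset_index[k]; pk <- ev$peak_index[k]
    base <- ev$baseline_pa[k]; amp <- ev$amplitude_pa[k]
    c50 <- crossing_time(s[on:pk], base + 0.5 * amp)
    if (is.na(c50)) next
    pos50 <- on + c50                       # fractional 1-based sample index
    if (shift == "nearest") {
      ctr <- round(pos50)
      idx <- ctr + (seq_len(L) - align_col)
      if (idx[1] < 1L || idx[L] > n) next   # truncated by trace boundary
      row <- s[idx] - base
    } else {
      grid <- pos50 + (seq_len(L) - align_col)
      i0 <- floor(grid)
      if (i0[1] < 1L || (i0[L] + 1L) > n) next
      frac <- grid - i0
      row <- (1 - frac) * s[i0] + frac * s[i0 + 1L] - base
    }
    rows[[length(rows) + 1L]] <- row
    # re-measure the 50% crossing on the shifted row as a quality score
    r50 <- crossing_time(row[seq_len(align_col + max(1L, pk - on))],
                         0.5 * amp)
    quality <- c(quality, abs((r50 + 1) - align_col))
    bw <- max(2L, round(5 / 1000 * fs))
    b0 <- max(1L, on - bw)
    bvar <- c(bvar, var(s[b0:(on - 1L)]))
  }
  if (length(rows) < min_events)
    stop(sprintf("only %d alignable events; %d required",
                 length(rows), min_events))
  m <- do.call(rbind, rows)
  structure(m, class = c("psc_ensemble", class(m)),
            align_col = align_col, dt_ms = dt_ms,
            quality = quality,
            baseline_var_pa2 = mean(bvar, na.rm = TRUE))
}

#' Ensemble variance-mean curve
#'
#' Per time bin of an aligned ensemble, computes the magnitude of the mean
#' current and the unbiased across-event variance, restricted (by default)
#' to the decay phase — from the bin of peak ensemble mean onward — because
#' rise-phase alignment jitter inflates the variance.  Optionally aggregates
#' the per-bin points into equal-width mean-current bins, which stabilises
#' the variance estimates.
#'
#' @param alignment A `psc_ensemble` from [align_events()].
#' @param nbins Number of equal-width mean-current bins (default 10);
#'   `NULL` keeps one point per time bin.
#' @param decay_only Restrict to the decay phase (default `TRUE`).
#' @return Data frame of class `psc_vm_curve` with columns `I_pa`,
#'   `var_pa2`, `n_events`, `n_bins` (time bins aggregated per point) and
#'   attributes `I_peak_pa` and `baseline_var_pa2`.
#' @export
ensemble_variance_mean <- function(alignment, nbins = 10, decay_only = TRUE) {
  m <- unclass(alignment)
  if (nrow(m) < 2) stop("need at least 2 aligned events")
  M <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - M * mu^2) / (M - 1)
  v <- pmax(v, 0)
  pk <- which.max(mu)
  cols <- if (decay_only) pk:ncol(m) else seq_len(ncol(m))
  I <- abs(mu[cols]); vv <- v[cols]
  I_peak <- max(abs(mu))
  if (!is.null(nbins) && length(I) > nbins) {
    br <- seq(min(I), max(I), length.out = nbins + 1L)
    bin <- findInterval(I, br, rightmost.closed = TRUE, all.inside = TRUE)
    I_b <- tapply(I, bin, mean)
    v_b <- tapply(vv, bin, mean)
    n_b <- tapply(I, bin, length)
    curve <- data.frame(I_pa = as.numeric(I_b), var_pa2 = as.numeric(v_b),
                        n_events = M, n_bins = as.integer(n_b))
  } else {
    curve <- data.frame(I_pa = I, var_pa2 = vv, n_events = M, n_bins = 1L)
  }
  curve <- curve[order(curve$I_pa), , drop = FALSE]
  rownames(curve) <- NULL
  structure(curve, class = c("psc_vm_curve", "data.frame"),
            I_peak_pa = I_peak,
            baseline_var_pa2 = attr(alignment, "baseline_var_pa2"))
}

#' Fit the non-stationary noise variance-mean parabola
#'
#' Fits \eqn{\sigma^2 = iI - I^2/N + b} by (iteratively re-weighted) least
#' squares.  The model is linear in \eqn{(i, -1/N, b)}, so the fit is a
#' weighted linear regression of variance on \eqn{(I, I^2)}; weights default
#' to (time bins x events) / predicted-variance squared, iterated twice, the
#' natural weighting for the chi-square-distributed sample variances.
#' Constraints: \eqn{i > 0} is required (else the fit aborts), \eqn{b} is
#' bounded below by 0 (refit with \eqn{b = 0} when the free intercept goes
#' negative), and a non-negative curvature (a variance-mean relation with no
#' parabolic rollover, the \eqn{N \to \infty} regime) yields a censored
#' `n_channels = Inf` with a diagnostic flag rather than a spurious finite
#' estimate.
#'
#' @param curve A `psc_vm_curve` from [ensemble_variance_mean()], or any data
#'   frame with columns `I_pa` and `var_pa2` (optionally `n_events`,
#'   `n_bins`).
#' @param weighting `"iterative"` (default), `"points"` (weight by the
#'   number of aggregated points only), or `"none"` (ordinary least
#'   squares).
#' @param fix_b Fix the background variance to this value (e.g. the measured
#'   pre-event baseline variance) instead of fitting it freely; `NULL`
#'   (default) fits b.
#' @param min_points Minimum number of curve points (default 5).
#' @param min_span Minimum current range as a fraction of the peak mean
#'   current (default 0.5).
#' @return An object of class `nsna_fit`; see [coef.nsna_fit()],
#'   [summary.nsna_fit()], [predict.nsna_fit()], [plot.nsna_fit()].
#' @examples
#' I <- seq(2, 75, length.out = 12)
#' v <- 2 * I - I^2 / 50 + 1
#' fit <- fit_variance_mean(data.frame(I_pa = I, var_pa2 = v))
#' coef(fit)
#' @export
fit_variance_mean <- function(curve, weighting = c("iterative", "points", "none"),
                              fix_b = NULL, min_points = 5, min_span = 0.5) {
  weighting <- match.arg(weighting)
  cl <- match.call()
  I <- curve$I_pa
  v <- curve$var_pa2
  ok <- is.finite(I) & is.finite(v)
  I <- I[ok]; v <- v[ok]
  if (length(I) < min_points)
    stop(sprintf("need at least %d variance-mean points, got %d",
                 min_points, length(I)))
  I_peak <- attr(curve, "I_peak_pa") %||% max(I)
  if (I_peak <= 0 || all(abs(I) < 1e-9))
    stop("degenerate variance-mean curve: mean currents are all ~0")
  if ((max(I) - min(I)) < min_span * I_peak)
    stop("variance-mean points span less than half of the peak current")
  npts <- (curve$n_bins %||% rep(1, nrow(curve)))[ok] *
    (curve$n_events %||% rep(1, nrow(curve)))[ok]
  base_w <- switch(weighting, none = rep(1, length(I)), as.numeric(npts))
  flags <- character(0)

  do_fit <- function(w, force_b0 = FALSE) {
    if (is.null(fix_b) && !force_b0) {
      f <- lm(v ~ I + I(I^2), weights = w)
      beta <- coef(f); b <- beta[[1]]; i <- beta[[2]]; q <- beta[[3]]
    } else {
      b <- if (force_b0) 0 else fix_b
      f <- lm(I(v - b) ~ 0 + I + I(I^2), weights = w)
      beta <- coef(f); i <- beta[[1]]; q <- beta[[2]]
    }
    list(fit = f, i = i, q = q, b = b)
  }

  w <- base_w
  res <- do_fit(w)
  if (weighting == "iterative") {
    for (iter in 1:2) {
      pred <- pmax(res$i * I + res$q * I^2 + res$b, 1e-8)
      w <- base_w / pred^2
      res <- do_fit(w)
    }
  }
  if (is.null(fix_b) && res$b < 0) {
    flags <- c(flags, "b_clamped_to_zero")
    res <- do_fit(w, force_b0 = TRUE)
  }
  censored_n <- FALSE
  # curvature indistinguishable from zero (relative to the curve's scale)
  # means no parabolic rollover: the N -> Inf regime
  eps_q <- 1e-10 * max(abs(v)) / max(I)^2
  if (is.na(res$q) || res$q >= -eps_q) {
    censored_n <- TRUE
    flags <- c(flags, "linear_variance_mean:N_unbounded")
    # refit without curvature
    b <- if (!is.null(fix_b)) fix_b else NULL
    if (is.null(b)) {
      f <- lm(v ~ I, weights = w)
      bb <- coef(f)
      res <- list(fit = f, i = bb[[2]], q = 0, b = max(bb[[1]], 0))
    } else {
      f <- lm(I(v - b) ~ 0 + I, weights = w)
      res <- list(fit = f, i = coef(f)[[1]], q = 0, b = b)
    }
  }
  if (!is.finite(res$i) || res$i <= 0)
    stop("degenerate fit: non-positive unitary current estimate")
  N <- if (censored_n) Inf else -1 / res$q
  i <- res$i; b <- res$b

  pred <- i * I + res$q * I^2 + b
  resid <- v - pred
  ss_res <- sum(w * resid^2); ss_tot <- sum(w * (v - weighted.mean(v, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1

  # delta-method covariance on (i, N, b) from the linear fit on (b, i, q)
  vc <- tryCatch(suppressWarnings(stats::vcov(res$fit)),
                 error = function(e) NULL)
  vcov_out <- matrix(NA_real_, 3, 3,
                     dimnames = list(c("unitary_current_pa", "n_channels",
                                       "background_variance_pa2"),
                                     c("unitary_current_pa", "n_channels",
                                       "background_variance_pa2")))
  if (!is.null(vc) && !censored_n && is.null(fix_b) &&
      !("b_clamped_to_zero" %in% flags) && nrow(vc) == 3) {
    # parameter order in vc: (Intercept)=b, I=i, I^2=q; N = -1/q
    J <- rbind(c(0, 1, 0),
               c(0, 0, 1 / res$q^2),
               c(1, 0, 0))
    vcov_out[] <- J %*% vc %*% t(J)
  }

  structure(list(
    coefficients = c(unitary_current_pa = i, n_channels = N,
                     background_variance_pa2 = b),
    vcov = vcov_out,
    curve = data.frame(I_pa = I, var_pa2 = v),
    weights = w,
    fitted.values = pred,
    residuals = resid,
    r.squared = r2,
    sigma = sqrt(ss_res / max(length(I) - 3, 1)),
    I_peak_pa = I_peak,
    channels_open_at_peak = I_peak / i,
    censored_n = censored_n,
    flags = flags,
    n_events = max(curve$n_events %||% NA),
    baseline_var_pa2 = attr(curve, "baseline_var_pa2"),
    call = cl), class = "nsna_fit")
}

#' Non-stationary noise analysis of a recording
#'
#' End-to-end NSNA for one cell: select isolated accepted events (more than
#' `isolation_ms` from any neighbour), align them at their 50%-rise point,
#' build the ensemble variance-mean curve over the decay phase, and fit the
#' parabola \eqn{\sigma^2 = iI - I^2/N + b}.  Cells whose ensemble does not
#' align precisely (median absolute residual of the re-measured 50% crossing
#' at or above `max_align_residual` samples) are rejected, mirroring the
#' practice of only analysing cells with precise event alignment.
#'
#' @param trace A [psc_trace()].
#' @param catalog A `psc_events` catalog (from [detect_events()]); computed
#'   from the trace when `NULL`.
#' @param isolation_ms Isolation rule (ms, default 200).
#' @param pre_ms,post_ms Alignment window (ms).
#' @param nbins Mean-current bins for the variance-mean curve.
#' @param min_events Minimum isolated events required for a fit (default 20).
#' @param max_align_residual Cell-level alignment-quality gate (samples).
#' @param ... Passed to [fit_variance_mean()].
#' @return An `nsna_fit` (see [fit_variance_mean()]), with the alignment
#'   stored in `$alignment_quality`, or an error if the cell fails the
#'   event-count or alignment-quality gates.
#' @export
nsna <- function(trace, catalog = NULL, isolation_ms = 200, pre_ms = 5,
                 post_ms = 50, nbins = 10, min_events = 20,
                 max_align_residual = 0.5, ...) {
  if (is.null(catalog)) catalog <- detect_events(trace)
  iso <- select_isolated_events(catalog, isolation_ms)
  al <- align_events(trace, iso, pre_ms = pre_ms, post_ms = post_ms,
                     min_events = min_events)
  q <- stats::median(attr(al, "quality"))
  if (is.finite(q) && q >= max_align_residual)
    stop(sprintf("imprecise event alignment (median 50%%-crossing residual %.2f samples >= %.2f): cell excluded from noise analysis",
                 q, max_align_residual))
  curve <- ensemble_variance_mean(al, nbins = nbins)
  fit <- fit_variance_mean(curve, ...)
  fit$alignment_quality <- q
  fit$n_isolated <- nrow(al)
  fit$call <- match.call()
  fit
}

#' @export
print.nsna_fit <- function(x, digits = 4, ...) {
  cat("Non-stationary noise analysis fit: sigma^2 = i*I - I^2/N + b\n")
  co <- x$coefficients
  cat(sprintf("  unitary current i      = %s pA\n", format(co[1], digits = digits)))
  cat(sprintf("  channel count N        = %s%s\n",
              format(co[2], digits = digits),
              if (x$censored_n) "  (censored: no parabolic rollover)" else ""))
  cat(sprintf("  background variance b  = %s pA^2\n", format(co[3], digits = digits)))
  cat(sprintf("  channels open at peak  = %s (I_peak = %s pA)\n",
              format(x$channels_open_at_peak, digits = digits),
              format(x$I_peak_pa, digits = digits)))
  cat(sprintf("  %d curve points, R^2 = %.4f\n", nrow(x$curve), x$r.squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.nsna_fit <- function(object, ...) object$coefficients

#' @export
vcov.nsna_fit <- function(object, ...) object$vcov

#' Predict ensemble variance at given mean currents
#'
#' @param object An `nsna_fit`.
#' @param newdata Optional data frame with column `I_pa` (or a numeric
#'   vector of mean currents, pA); defaults to the fitted curve.
#' @param ... Unused.
#' @return Predicted variance (pA^2).
#' @export
predict.nsna_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  I <- if (is.data.frame(newdata)) newdata$I_pa else as.numeric(newdata)
  co <- object$coefficients
  q <- if (is.infinite(co[2])) 0 else -1 / co[2]
  unname(co[1] * I + q * I^2 + co[3])
}

#' @export
fitted.nsna_fit <- function(object, ...) object$fitted.values

#' @export
residuals.nsna_fit <- function(object, ...) object$residuals

#' @export
summary.nsna_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  peak <- if (!object$censored_n) {
    c(I_at_max = unname(object$coefficients[1] * object$coefficients[2] / 2),
      var_max = unname(object$coefficients[1]^2 * object$coefficients[2] / 4 +
                         object$coefficients[3]))
  } else c(I_at_max = NA_real_, var_max = NA_real_)
  structure(list(coefficients = tab, r.squared = object$r.squared,
                 sigma = object$sigma, parabola_peak = peak,
                 channels_open_at_peak = object$channels_open_at_peak,
                 n_points = nrow(object$curve), n_events = object$n_events,
                 censored_n = object$censored_n, flags = object$flags,
                 call = object$call),
            class = "summary.nsna_fit")
}

#' @export
print.summary.nsna_fit <- function(x, digits = 4, ...) {
  cat("Non-stationary noise analysis: sigma^2 = i*I - I^2/N + b\n\nCall: ")
  print(x$call)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nChannels open at peak: %s\n",
              format(x$channels_open_at_peak, digits = digits)))
  if (!x$censored_n)
    cat(sprintf("Parabola peak: I = %s pA, variance = %s pA^2\n",
                format(x$parabola_peak[1], digits = digits),
                format(x$parabola_peak[2], digits = digits)))
  cat(sprintf("R^2 = %.4f on %d points (%s events); residual SD %.3g pA^2\n",
              x$r.squared, x$n_points,
              format(x$n_events), x$sigma))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a variance-mean curve and its fitted parabola
#'
#' @param x An `nsna_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.nsna_fit <- function(x, ...) {
  plot(x$curve$I_pa, x$curve$var_pa2,
       xlab = "mean current I (pA)",
       ylab = expression(paste("ensemble variance ", sigma^2, " (", pA^2, ")")),
       main = "Non-stationary noise analysis", ...)
  Igrid <- seq(0, max(x$curve$I_pa), length.out = 200)
  lines(Igrid, predict(x, Igrid), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate variance-mean curves from a fitted NSNA model
#'
#' Draws replicate ensemble variance values at the fitted curve's mean
#' currents: each simulated variance is the model-predicted variance scaled
#' by a chi-square deviate with `n_events - 1` degrees of freedom, the
#' sampling distribution of an across-event sample variance under
#' approximate normality.
#'
#' @param object An `nsna_fit`.
#' @param nsim Number of replicate curves.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with columns `sim`, `I_pa`, `var_pa2`.
#' @export
simulate.nsna_fit <- function(object, nsim = 1, seed = NULL, ...) {
  M <- object$n_events
  if (!is.finite(M) || M < 2) M <- 100
  I <- object$curve$I_pa
  pred <- predict(object, I)
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(s) {
      data.frame(sim = s, I_pa = I,
                 var_pa2 = pred * rchisq(length(I), df = M - 1) / (M - 1))
    })
    do.call(rbind, out)
  })
}
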