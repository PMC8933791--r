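#' Empirical cumulative distribution points
#'
#' Sorted unique values and cumulative probabilities k/n (right-continuous
#' convention), the representation behind cumulative-probability plots of
#' pooled event distributions.
#'
#' @param values Numeric vector, n >= 1.
#' @return Data frame with columns `value` (sorted unique) and `prob`.
#' @examples
#' ecdf_points(c(3, 1, 2))
#' @export
ecdf_points <- function(values) {
  if (!length(values)) stop("empty input")
  values <- sort(values)
  tab <- table(values)
  data.frame(value = as.numeric(names(tab)),
             prob = cumsum(as.numeric(tab)) / length(values))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test of distributional equality,
#' \eqn{D = \sup_x |F_a(x) - F_b(x)|}.  The p-value is exact for small
#' tie-free samples (product of sizes below 10^4) and asymptotic otherwise;
#' with ties the asymptotic approximation is used.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @return List with `statistic` (D), `p.value`, `n_a`, `n_b`, `exact`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0
  ht <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n_a = length(a), n_b = length(b),
       exact = !ties && length(a) * length(b) < 1e4)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling.  U is reported for the first
#' sample: \eqn{U_a = R_a - n_a(n_a+1)/2} where \eqn{R_a} is the rank sum of
#' `a` in the pooled ranking, so \eqn{U_a + U_b = n_a n_b} always.  The
#' p-value is exact (enumeration of the Wilcoxon null distribution) for
#' tie-free samples below 50 observations each, and a normal approximation
#' with tie correction and continuity correction otherwise.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @return List with `statistic` (U for `a`), `p.value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, alternative = "two.sided") {
  if (!length(a) || !length(b)) stop("empty sample")
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ht <- suppressWarnings(wilcox.test(a, b, alternative = alternative,
                                     correct = TRUE))
  stopifnot(isTRUE(all.equal(unname(ht$statistic), U)))
  list(statistic = U, p.value = ht$p.value,
       n_a = length(a), n_b = length(b))
}

#' Median, interquartile range, and 5-95% interval
#'
#' Distribution summary in the box-and-whisker convention: median,
#' quartiles, and 5%/95% whiskers, all by linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param values Numeric vector, n >= 1.
#' @return Named numeric vector: `median`, `q25`, `q75`, `p5`, `p95`, `n`.
#' @export
summarize_values <- function(values) {
  if (!length(values)) stop("empty input")
  q <- quantile(values, c(0.5, 0.25, 0.75, 0.05, 0.95), type = 7, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3], p5 = q[4], p95 = q[5],
    n = length(values))
}

# Pool one event-level variable across the cells of a cohort.
pool_events <- function(cells, variable, cutoff = NULL) {
  vals <- unlist(lapply(cells, function(cell) cell$metrics[[variable]]),
                 use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (!is.null(cutoff)) vals <- vals[vals <= cutoff]
  vals
}

# One per-cell value per cell for a cohort; NA for cells lacking it.
cell_values <- function(cells, variable) {
  vapply(cells, function(cell) {
    if (variable %in% names(cell$summary)) return(cell$summary[[variable]])
    if (!is.null(cell$nsna)) {
      co <- coef(cell$nsna)
      if (variable %in% names(co)) return(unname(co[variable]))
      if (variable == "channels_open_at_peak")
        return(cell$nsna$channels_open_at_peak)
    }
    NA_real_
  }, numeric(1))
}

#' Compare two cohorts of cells
#'
#' Implements the standard spontaneous-PSC comparison plan between two
#' groups of analysed cells: two-sample Kolmogorov-Smirnov tests on
#' event-level distributions pooled across the cells of each cohort
#' (amplitude, inter-event interval, rise time), and Mann-Whitney tests on
#' per-cell quantities (charge transfer per second and, where noise-analysis
#' fits are available, channel count and unitary current).  Pooling
#' event-level values across cells deliberately reproduces the common
#' practice of event-count-based cumulative distributions; see the package
#' vignette for the pseudoreplication caveat.  An optional upper amplitude
#' cut-off (e.g. 100 pA for IPSC recordings) is applied to the pooled
#' amplitudes before testing.
#'
#' @param group_a,group_b Lists of per-cell analysis results as returned by
#'   [analyze_cell()] (each element a list with `metrics`, `summary`, and
#'   optionally `nsna`).
#' @param labels Character vector of length 2 naming the cohorts.
#' @param ks_variables Event-level variables tested by KS (columns of the
#'   metrics table).
#' @param mw_variables Per-cell variables tested by Mann-Whitney (columns of
#'   the cell summary, or NSNA coefficient names).
#' @param amplitude_cutoff_pa Optional upper amplitude cut-off (pA) applied
#'   before pooling amplitudes; `NULL` (default) applies none.
#' @return Data frame of class `psc_comparison`: one row per (variable,
#'   test) with the statistic, p-value, per-group n and median/IQR/5-95%
#'   summaries.
#' @export
compare_cohorts <- function(group_a, group_b, labels = c("A", "B"),
                            ks_variables = c("amplitude_pa", "iei_ms",
                                             "rise_10_90_ms"),
                            mw_variables = c("charge_transfer_pc_per_s",
                                             "n_channels",
                                             "unitary_current_pa"),
                            amplitude_cutoff_pa = NULL) {
  if (!length(group_a) || !length(group_b))
    stop("both cohorts must contain at least one cell")
  rows <- list()
  add_row <- function(variable, test, stat, p, va, vb) {
    sa <- summarize_values(va); sb <- summarize_values(vb)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = stat, p_value = p,
      n_a = length(va), n_b = length(vb),
      median_a = sa[["median"]], q25_a = sa[["q25"]], q75_a = sa[["q75"]],
      p5_a = sa[["p5"]], p95_a = sa[["p95"]],
      median_b = sb[["median"]], q25_b = sb[["q25"]], q75_b = sb[["q75"]],
      p5_b = sb[["p5"]], p95_b = sb[["p95"]],
      stringsAsFactors = FALSE)
  }
  for (v in ks_variables) {
    cut <- if (v == "amplitude_pa") amplitude_cutoff_pa else NULL
    va <- pool_events(group_a, v, cut)
    vb <- pool_events(group_b, v, cut)
    if (!length(va) || !length(vb))
      stop("no pooled events for variable '", v, "' in one cohort")
    ks <- ks_two_sample(va, vb)
    add_row(v, "KS", ks$statistic, ks$p.value, va, vb)
  }
  for (v in mw_variables) {
    va <- cell_values(group_a, v); va <- va[is.finite(va)]
    vb <- cell_values(group_b, v); vb <- vb[is.finite(vb)]
    if (!length(va) || !length(vb))
      stop("no per-cell values for variable '", v, "' in one cohort")
    mw <- mann_whitney(va, vb)
    add_row(v, "MW", mw$statistic, mw$p.value, va, vb)
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  attr(out, "amplitude_cutoff_pa") <- amplitude_cutoff_pa
  attr(out, "quantile_type") <- 7L
  class(out) <- c("psc_comparison", "data.frame")
  out
}

#' @export
print.psc_comparison <- function(x, digits = 4, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("Cohort comparison: %s vs %s\n", lab[1], lab[2]))
  df <- as.data.frame(x)[, c("variable", "test", "statistic", "p_value",
                             "n_a", "n_b", "median_a", "median_b")]
  df$statistic <- signif(df$statistic, digits)
  df$p_value <- signif(df$p_value, digits)
  df$median_a <- signif(df$median_a, digits)
  df$median_b <- signif(df$median_b, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
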