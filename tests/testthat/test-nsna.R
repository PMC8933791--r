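test_that("isolation rule keeps only events >200 ms from any neighbour", {
  fs <- 20000
  cat <- make_catalog(onset_index = round(c(0.10, 0.25, 0.60) * fs) + 1,
                      fs = fs)
  kept <- select_isolated_events(cat)
  expect_equal(kept$onset_s, 0.60)

  expect_identical(nrow(select_isolated_events(make_catalog(5, fs = fs))), 1L)

  spaced <- make_catalog(onset_index = round(seq(0.5, 5, by = 0.5) * fs),
                         fs = fs)
  expect_identical(nrow(select_isolated_events(spaced)), nrow(spaced))

  # artifacts break isolation on both sides but are never retained
  mixed <- make_catalog(onset_index = round(c(0.5, 0.65, 1.5) * fs) + 1,
                        accepted = c(TRUE, FALSE, TRUE), fs = fs)
  expect_equal(select_isolated_events(mixed)$onset_s, 1.5)
})

test_that("alignment registers events at their 50% rise with sub-sample accuracy", {
  fs <- 20000
  wf <- 60 * open_prob_waveform(0.5, 5, 1, dt_ms = 1000 / fs)
  # identical events at jittered integer onsets: zero column variance
  onsets <- c(4000, 12000, 21000, 32000) + c(0, 3, 7, 11)
  tr <- waveform_trace(wf, onsets, n = 40000, fs = fs)
  cat <- make_catalog(onset_index = onsets,
                      peak_index = onsets + which.max(wf) - 1L,
                      amplitude_pa = max(wf), fs = fs)
  al <- align_events(tr, cat)
  vm <- ensemble_variance_mean(al, nbins = NULL)
  expect_lt(max(vm$var_pa2), 1e-18)

  # single event: ensemble mean equals the event waveform
  one <- make_catalog(onset_index = 4000, peak_index = 4000 + which.max(wf) - 1L,
                      amplitude_pa = max(wf), fs = fs)
  al1 <- align_events(tr, one, min_events = 1)
  k <- attr(al1, "align_col")
  start <- which(abs(wf - al1[1, k]) < 1e-9)[1]
  expect_false(is.na(start))
  expect_equal(as.numeric(al1[1, k:(k + 200)]), wf[start + 0:200],
               tolerance = 1e-12)

  # events placed at sub-sample offsets: interpolated alignment leaves
  # residual misalignment < 0.5 sample
  offs <- c(0, 0.3, 0.6)
  t_hi <- seq(0, 55, by = 1e-3)
  raw <- exp(-t_hi / 5) - exp(-t_hi / 0.5)
  starts <- c(4000, 12000, 20000)
  x <- numeric(28000)
  for (j in seq_along(starts)) {
    tt <- ((0:1100) - offs[j]) / fs * 1000
    v <- approx(t_hi, 60 * raw / max(raw), xout = pmax(tt, 0), rule = 2)$y
    v[tt < 0] <- 0
    x[starts[j] + 0:1100] <- v
  }
  tr2 <- psc_trace(x, fs)
  pk <- vapply(starts, function(s0) s0 + which.max(x[s0 + 0:1100]) - 1L, 1)
  cat2 <- make_catalog(onset_index = starts, peak_index = pk,
                       amplitude_pa = vapply(starts, function(s0)
                         max(x[s0 + 0:1100]), 1), fs = fs)
  al2 <- align_events(tr2, cat2, shift = "interpolate")
  expect_lt(max(attr(al2, "quality")), 0.5)
  al3 <- align_events(tr2, cat2, shift = "nearest")
  expect_lte(max(attr(al3, "quality")), 0.5 + 1e-9)
})

test_that("ensemble variance-mean points obey the binomial closed form", {
  # two identical rows: zero variance everywhere
  m <- structure(rbind(1:10, 1:10), class = c("psc_ensemble", "matrix"),
                 align_col = 1L, dt_ms = 0.05, quality = c(0, 0),
                 baseline_var_pa2 = 0)
  vm0 <- ensemble_variance_mean(m, nbins = NULL)
  expect_true(all(vm0$var_pa2 == 0))
  expect_error(ensemble_variance_mean(m[1, , drop = FALSE]), "2 aligned")

  # binomial ensemble: sigma^2 = i*I - I^2/N within Monte-Carlo error
  set.seed(101)
  p <- open_prob_waveform(0.5, 5, 0.8, dt_ms = 0.05)
  ens <- binomial_ensemble(500, n_channels = 50, unitary_pa = 2,
                           p_waveform = p)
  vm <- ensemble_variance_mean(ens, nbins = NULL)
  pred <- 2 * vm$I_pa - vm$I_pa^2 / 50
  # SE of a sample variance: sigma^2 * sqrt(2/(M-1))
  se <- pmax(pred, 1) * sqrt(2 / 499)
  expect_lt(mean(abs(vm$var_pa2 - pred) > 3 * se), 0.05)

  # additive Gaussian noise shifts every variance up by its variance
  set.seed(102)
  ens_n <- unclass(ens) + rnorm(length(ens), sd = 3)
  attributes(ens_n) <- attributes(ens)
  vm_n <- ensemble_variance_mean(ens_n, nbins = NULL)
  expect_equal(mean(vm_n$var_pa2 - vm$var_pa2), 9, tolerance = 0.6)
})

test_that("fitting the parabola to its own noiseless output is exact", {
  I <- seq(2, 80, length.out = 15)
  v <- 2 * I - I^2 / 50 + 1
  fit <- fit_variance_mean(data.frame(I_pa = I, var_pa2 = v))
  co <- coef(fit)
  expect_equal(unname(co["unitary_current_pa"]), 2, tolerance = 1e-7)
  expect_equal(unname(co["n_channels"]), 50, tolerance = 1e-7)
  expect_equal(unname(co["background_variance_pa2"]), 1, tolerance = 1e-6)
  # parabola peak at I = i*N/2, height i^2*N/4 + b
  expect_equal(unname(co[1] * co[2] / 2), 50, tolerance = 1e-6)
  expect_equal(unname(co[1]^2 * co[2] / 4 + co[3]), 51, tolerance = 1e-6)
  expect_gt(fit$r.squared, 1 - 1e-12)
})

test_that("a linear variance-mean relation yields a censored channel count", {
  I <- seq(1, 40, length.out = 12)
  fit <- fit_variance_mean(data.frame(I_pa = I, var_pa2 = 1.5 * I + 2))
  expect_true(fit$censored_n)
  expect_identical(unname(coef(fit)["n_channels"]), Inf)
  expect_true(any(grepl("N_unbounded", fit$flags)))
  expect_equal(unname(coef(fit)["unitary_current_pa"]), 1.5, tolerance = 1e-7)
})

test_that("degenerate variance-mean curves are rejected explicitly", {
  expect_error(fit_variance_mean(data.frame(I_pa = rep(0, 8),
                                            var_pa2 = rep(1, 8))),
               "degenerate")
  expect_error(fit_variance_mean(data.frame(I_pa = 1:3, var_pa2 = 1:3)),
               "at least 5")
  # points clustered far below the peak current violate the span rule
  curve <- structure(data.frame(I_pa = seq(1, 5, length.out = 8),
                                var_pa2 = seq(1, 5, length.out = 8)),
                     I_peak_pa = 80)
  expect_error(fit_variance_mean(curve), "span")
})

test_that("current scaling maps (i, N) -> (c*i, N) exactly", {
  set.seed(55)
  p <- open_prob_waveform(0.5, 5, 0.8, dt_ms = 0.05)
  ens <- binomial_ensemble(300, 50, 2, p)
  f1 <- fit_variance_mean(ensemble_variance_mean(ens))
  ens3 <- unclass(ens) * 3
  attributes(ens3) <- attributes(ens)
  f3 <- fit_variance_mean(ensemble_variance_mean(ens3))
  expect_equal(coef(f3)[["unitary_current_pa"]],
               3 * coef(f1)[["unitary_current_pa"]], tolerance = 1e-8)
  expect_equal(coef(f3)[["n_channels"]], coef(f1)[["n_channels"]],
               tolerance = 1e-8)
})

test_that("fitted background variance tracks the injected baseline variance", {
  set.seed(77)
  p <- open_prob_waveform(0.5, 5, 0.8, dt_ms = 0.05)
  ens <- binomial_ensemble(400, 93, 1, p, noise_sd = 2)
  fit <- fit_variance_mean(ensemble_variance_mean(ens))
  # SE of the pooled variance estimate ~ b * sqrt(2/(M-1)) per bin
  expect_lt(abs(coef(fit)[["background_variance_pa2"]] - 4),
            3 * 4 * sqrt(2 / 399))
})

test_that("recovery error shrinks with ensemble size", {
  p <- open_prob_waveform(0.5, 5, 0.8, dt_ms = 0.1)
  sizes <- c(50, 100, 250, 500)
  set.seed(303)
  err <- sapply(sizes, function(M) {
    e <- replicate(50, {
      ens <- binomial_ensemble(M, 93, 1, p, noise_sd = 2)
      co <- coef(fit_variance_mean(ensemble_variance_mean(ens)))
      abs(co[["unitary_current_pa"]] - 1)
    })
    median(e)
  })
  expect_true(all(diff(err) < 0))
})

test_that("nsna model object supports the standard methods", {
  sim <- isolated_event_sim(k = 60, seed = 9)
  fit <- nsna(sim$trace)
  expect_s3_class(fit, "nsna_fit")
  co <- coef(fit)
  expect_gt(co[["unitary_current_pa"]], 0)
  expect_gt(co[["n_channels"]], 0)
  expect_gte(co[["background_variance_pa2"]], 0)
  expect_equal(fit$channels_open_at_peak,
               fit$I_peak_pa / co[["unitary_current_pa"]])
  # predict/fitted/residuals coherence
  expect_equal(predict(fit), fitted(fit))
  expect_equal(fit$curve$var_pa2 - fitted(fit), residuals(fit))
  expect_equal(predict(fit, newdata = data.frame(I_pa = 0)),
               co[["background_variance_pa2"]])
  # summary carries delta-method standard errors
  sm <- summary(fit)
  expect_true(all(is.finite(sm$coefficients[, "Std. Error"])))
  expect_output(print(fit), "unitary current")
  expect_output(print(sm), "Coefficients")
  # simulate returns replicate curves centred on the fit
  sims <- simulate(fit, nsim = 500, seed = 1)
  i0 <- fit$curve$I_pa[1]
  expect_equal(mean(sims$var_pa2[sims$I_pa == i0]), predict(fit, i0),
               tolerance = 0.1)
  grDevices::pdf(NULL)
  expect_error(plot(fit), NA)
  grDevices::dev.off()
})

test_that("cells with too few isolated events are rejected from noise analysis", {
  sim <- isolated_event_sim(k = 5, seed = 15)
  expect_error(nsna(sim$trace), "alignable|required")
})
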