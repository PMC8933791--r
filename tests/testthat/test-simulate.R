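test_that("open-probability waveform has the closed-form peak and stays in [0, p_peak]", {
  # difference of exponentials peaks at t* = tr*td/(td-tr) * log(td/tr)
  p <- open_prob_waveform(0.5, 5, 1, dt_ms = 0.05)
  t_star <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)
  expect_equal(t_star, 1.279, tolerance = 1e-3)
  expect_equal((which.max(p) - 1) * 0.05, t_star, tolerance = 0.05)
  expect_lte(max(p), 1)
  expect_gt(max(p), 1 - 1e-3)           # grid point near the analytic max
  expect_identical(p[1], 0)

  p2 <- open_prob_waveform(1, 2, 0.5, dt_ms = 0.05)
  expect_equal(max(p2), 0.5, tolerance = 1e-3)

  for (pars in list(c(0.2, 3, 0.9), c(1, 20, 0.1), c(0.5, 5, 1))) {
    pd <- open_prob_waveform(pars[1], pars[2], pars[3], dt_ms = 0.01)
    expect_true(all(pd >= 0))
    expect_lt(pd[length(pd)], 1e-3 * pars[3])  # decayed by the horizon
  }

  expect_error(open_prob_waveform(5, 1, 0.5, 0.05), "tau")
  expect_error(open_prob_waveform(0.5, 5, 1.5, 0.05), "peak_open_prob")
})

test_that("event current sampling has binomial mean N*i*p and variance N*i^2*p(1-p)", {
  set.seed(11)
  draws <- sample_event_current(rep(0.5, 10000), n_channels = 50,
                                unitary_current_pa = 2)
  expect_equal(mean(draws), 50, tolerance = 1 / 50)     # 50 +- 1 pA
  expect_lt(abs(var(draws) - 50), 3)                     # 50 +- 3 pA^2

  one <- sample_event_current(rep(1, 100), n_channels = 1,
                              unitary_current_pa = 3.5)
  expect_true(all(one == 3.5))

  expect_identical(sample_event_current(rep(0.3, 50), 10, 1, seed = 9),
                   sample_event_current(rep(0.3, 50), 10, 1, seed = 9))
  expect_error(sample_event_current(numeric(0), 10, 1), "empty")
})

test_that("a rate-zero simulation is pure Gaussian noise at the configured RMS", {
  sim <- simulate_trace(sim_config(duration_s = 5, event_rate_hz = 0,
                                   baseline_rms_pa = 2, seed = 3))
  expect_identical(nrow(sim$events), 0L)
  expect_equal(sd(sim$trace$current_pa), 2, tolerance = 0.02)
  expect_identical(length(sim$trace), 100000L)
})

test_that("event counts follow the Poisson law", {
  # 500 seeded replicates of rate 0.2 Hz x 120 s: mean count 24 +- 0.7 (~3 SE)
  counts <- vapply(1:500, function(s) {
    nrow(simulate_trace(sim_config(duration_s = 120, sampling_rate_hz = 1000,
                                   event_rate_hz = 0.2, baseline_rms_pa = 0,
                                   n_channels = 1, seed = s))$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 24), 0.7)

  # chi-square goodness of fit of counts against Poisson(20) at alpha = .01
  counts2 <- vapply(1:1000, function(s) {
    nrow(simulate_trace(sim_config(duration_s = 10, sampling_rate_hz = 500,
                                   event_rate_hz = 2, baseline_rms_pa = 0,
                                   n_channels = 1, seed = 5000 + s))$events)
  }, numeric(1))
  lam <- 20
  br <- c(-Inf, 14:25, Inf)
  obs <- table(cut(counts2, br))
  pr <- diff(ppois(c(-Inf, 14:25, Inf), lam))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulation is bit-for-bit reproducible and polarity flips the event component", {
  cfg <- sim_config(duration_s = 3, event_rate_hz = 2, seed = 21)
  s1 <- simulate_trace(cfg)
  s2 <- simulate_trace(cfg)
  expect_identical(s1$trace$current_pa, s2$trace$current_pa)
  expect_identical(s1$events, s2$events)

  cfg_in <- sim_config(duration_s = 3, event_rate_hz = 2, baseline_rms_pa = 0,
                       polarity = "inward", seed = 8)
  cfg_out <- sim_config(duration_s = 3, event_rate_hz = 2, baseline_rms_pa = 0,
                        polarity = "outward", seed = 8)
  expect_identical(simulate_trace(cfg_in)$trace$current_pa,
                   -simulate_trace(cfg_out)$trace$current_pa)
})

test_that("a noiseless event peaks near N*i*p_peak", {
  # N*i*p_peak = 125 * 0.5 * 0.8 = 50 pA; binomial SD at peak ~2.2 pA
  sim <- simulate_trace(sim_config(duration_s = 1, event_rate_hz = 0,
                                   onset_times_s = 0.2, n_channels = 125,
                                   unitary_current_pa = 0.5,
                                   baseline_rms_pa = 0, polarity = "outward",
                                   seed = 4))
  expect_lt(abs(max(sim$trace$current_pa) - 50), 9)  # ~4 SD of the bin max
})

test_that("config invariants are enforced", {
  expect_error(sim_config(tau_rise_ms = 5, tau_decay_ms = 2), "tau_decay")
  expect_error(sim_config(peak_open_prob = 0), "peak_open_prob")
  expect_error(sim_config(n_channels = 0.5), "n_channels")
  expect_error(sim_config(onset_times_s = c(2, 1), duration_s = 5),
               "strictly increasing")
  expect_error(sim_config(lowpass_cutoff_hz = 100), "lowpass")
})

test_that("cohort fixtures carry labels and expected pooled event counts", {
  coh <- simulate_cohort(
    nt_config = sim_config(duration_s = 120, sampling_rate_hz = 500,
                           event_rate_hz = 76 / (10 * 120), n_channels = 1,
                           baseline_rms_pa = 0, cohort = "NT"),
    ht_config = sim_config(duration_s = 120, sampling_rate_hz = 500,
                           event_rate_hz = 278 / (12 * 120), n_channels = 1,
                           baseline_rms_pa = 0, cohort = "HT"),
    cells_per_group = c(10, 12), seed = 5)
  expect_length(coh$nt, 10)
  expect_length(coh$ht, 12)
  expect_identical(coh$nt[[3]]$trace$metadata$cohort, "NT")
  expect_identical(coh$ht[[1]]$trace$metadata$cohort, "HT")
  # pooled counts within ~3 SE of the 76 / 278 design values
  n_nt <- sum(vapply(coh$nt, function(s) nrow(s$events), numeric(1)))
  n_ht <- sum(vapply(coh$ht, function(s) nrow(s$events), numeric(1)))
  expect_lt(abs(n_nt - 76), 3 * sqrt(76))
  expect_lt(abs(n_ht - 278), 3 * sqrt(278))
  # determinism under the master seed
  coh2 <- simulate_cohort(
    nt_config = sim_config(duration_s = 120, sampling_rate_hz = 500,
                           event_rate_hz = 76 / (10 * 120), n_channels = 1,
                           baseline_rms_pa = 0, cohort = "NT"),
    ht_config = sim_config(duration_s = 120, sampling_rate_hz = 500,
                           event_rate_hz = 278 / (12 * 120), n_channels = 1,
                           baseline_rms_pa = 0, cohort = "HT"),
    cells_per_group = c(10, 12), seed = 5)
  expect_identical(coh$nt[[7]]$trace$current_pa, coh2$nt[[7]]$trace$current_pa)
})
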