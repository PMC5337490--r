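test_that("noise-floor estimation is accurate and spike-robust", {
  set.seed(1)
  x <- rnorm(50000, 0, 5)
  expect_equal(estimate_noise_sd(x), 5, tolerance = 0.05)
  expect_equal(estimate_noise_sd(rep(2.5, 50000)), 0)
  expect_error(estimate_noise_sd(rnorm(100)), "unmasked")

  # sparse large spikes barely move the robust estimate
  spiky <- x
  spiky[sample(length(x), 200)] <- 60
  expect_lt(abs(estimate_noise_sd(spiky) - estimate_noise_sd(x)) /
              estimate_noise_sd(x), 0.10)
})

test_that("exponential artifact subtraction removes what it models and no more", {
  fs <- 25000
  t <- (seq_len(fs / 2) - 1) / fs
  pulse <- 0.1
  art <- ifelse(t >= pulse, 500 * exp(-(t - pulse) / 0.005), 0)

  out <- remove_stim_artifact(art, pulse, fs)
  resid <- out$trace[out$valid & t > pulse & t < pulse + 0.045]
  expect_lt(sqrt(mean(resid^2)), 0.01 * 500)
  expect_false(any(out$valid[t >= pulse & t < pulse + 0.005]))

  # flat trace passes through unchanged (A ~ 0)
  flat <- rep(3, length(t))
  out2 <- remove_stim_artifact(flat, pulse, fs)
  expect_equal(out2$trace, flat)

  # an embedded spike survives the subtraction with its shape intact
  cfg <- small_cfg(seed = 2)
  ev <- spike_events(26L, pulse + 0.020)
  log <- stim_log(26L, 1L, pulse, min_wait_s = 0)
  rec <- simulate_raw_trace(ev, log, cfg, channels = 26L, t_start = 0,
                            t_end = 0.5)
  corrected <- remove_stim_artifact(rec$samples[, 1], pulse, fs)
  win <- which(t > pulse + 0.018 & t < pulse + 0.022)
  ptp_before <- diff(range(rec$samples[win, 1] -
                             500 * exp(-(t[win] - pulse) / 0.005)))
  ptp_after <- diff(range(corrected$trace[win]))
  expect_lt(abs(ptp_after - ptp_before) / ptp_before, 0.10)
})

test_that("peak-to-peak detection thresholds, times and refractoriness behave", {
  fs <- 25000
  sdv <- 5
  # sub-threshold sinusoid: excursion 7 x SD never triggers
  t <- (0:fs) / fs
  sine <- 3.5 * sdv * sin(2 * pi * 100 * t)
  expect_length(detect_spikes(sine, sdv, sampling_rate = fs), 0)

  # a single biphasic template (peak-to-peak 10 x SD) gives one event at
  # its extremum
  cfg <- small_cfg(seed = 3)
  ev <- spike_events(26L, 0.5)
  log <- one_site_log(p1 = 100)
  rec <- simulate_raw_trace(ev, log, cfg, channels = 26L, t_start = 0, t_end = 1)
  st <- detect_spikes(rec$samples[, 1], sdv, sampling_rate = fs)
  expect_length(st, 1)
  expect_lt(abs(st - 0.5), 0.0005)

  # two supra-threshold deflections half a refractory period apart merge
  # into the earlier event
  x <- numeric(fs)
  x[round(0.5 * fs) + 1] <- -12 * sdv
  x[round(0.5005 * fs) + 1] <- -12 * sdv
  st2 <- detect_spikes(x, sdv, sampling_rate = fs)
  expect_length(st2, 1)
  expect_equal(st2, 0.5)

  # identical input, identical output
  expect_identical(detect_spikes(rec$samples[, 1], sdv, sampling_rate = fs),
                   st)
})

test_that("detection on simulated recordings recovers inserted events", {
  cfg <- small_cfg(seed = 9, n_sites_per_region = 2, n_trials = 5,
                   wait_s = 0.5, protocol_start_s = 1, spont_duration_s = 1)
  tr <- generate_ground_truth(cfg)
  sim <- simulate_spike_events(tr)
  chan <- 63L                        # a CA3 electrode
  t_end <- max(sim$stim_log$p2_time_s) + 0.2
  rec <- simulate_raw_trace(sim$events, sim$stim_log, cfg, channels = chan,
                            t_start = 0, t_end = t_end)
  truth_t <- sim$events$spike_time_s[sim$events$electrode_id == chan]

  det <- detect_recording(rec, sim$stim_log)
  got <- det$spike_time_s
  recall <- mean(vapply(truth_t, function(x) any(abs(got - x) < 0.001),
                        logical(1)))
  precision <- mean(vapply(got, function(x) any(abs(truth_t - x) < 0.001),
                           logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # no detected event inside any blanking window (hard guarantee)
  pulses <- sort(c(sim$stim_log$p1_time_s, sim$stim_log$p2_time_s))
  for (p in pulses)
    expect_false(any(got >= p & got < p + cfg$blank_s))

  # regression guard: skipping artifact subtraction floods detection with
  # artifact-tail false positives
  det_raw <- detect_recording(rec, sim$stim_log, remove_artifacts = FALSE)
  got_raw <- det_raw$spike_time_s
  precision_raw <- mean(vapply(got_raw,
                               function(x) any(abs(truth_t - x) < 0.001),
                               logical(1)))
  expect_lt(precision_raw, 0.8)
})
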