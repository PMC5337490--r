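test_that("the generator is deterministic given its seed", {
  cfg <- small_cfg(seed = 11)
  t1 <- generate_ground_truth(cfg)
  t2 <- generate_ground_truth(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_trial_counts(t1), simulate_trial_counts(t2))
  s1 <- simulate_spike_events(t1)
  s2 <- simulate_spike_events(t2)
  expect_identical(s1$events, s2$events)
  expect_false(identical(
    generate_ground_truth(small_cfg(seed = 12))$mean_rates$dg,
    t1$mean_rates$dg))
})

test_that("responsive-set structure follows the sparseness parameters", {
  tr <- generate_ground_truth(synth_config(seed = 2, sparseness_m = 3,
                                           specificity_overlap = 0))
  sizes <- lengths(tr$responsive$dg_to_ca3)
  expect_true(all(sizes == 3))
  ca3 <- region_electrodes(tr$layout, "CA3")
  expect_true(all(unlist(tr$responsive$dg_to_ca3) %in% ca3))

  # degenerate limit: m = 22 makes every CA3 electrode responsive everywhere
  full <- generate_ground_truth(synth_config(seed = 2, sparseness_m = 22))
  expect_true(all(vapply(full$responsive$dg_to_ca3,
                         function(s) identical(s, sort(ca3)), logical(1))))
  expect_error(synth_config(sparseness_m = 23), "sparseness_m")
})

test_that("trial counts are Poisson around the ground-truth means", {
  tr <- generate_ground_truth(small_cfg(seed = 5, n_sites_per_region = 4,
                                        n_trials = 60))
  sim <- simulate_trial_counts(tr)
  x <- sim$counts$dg
  lam <- tr$mean_rates$dg * 0.080      # per-trial expected count
  for (j in 1:2) {
    for (el in c("26", "63")) {        # one DG, one CA3 electrode
      v <- x[j, , el]
      if (all(is.na(v))) next
      se <- sqrt(lam[j, el] / length(v))
      expect_lt(abs(mean(v) - lam[j, el]), 3 * se + 1e-9)
    }
  }
})

test_that("silent networks yield empty counts and masked cells sit at the stimulated electrode", {
  cfg <- small_cfg(seed = 1, baseline_rate_dg = 0, baseline_rate_ca3 = 0,
                   evoked_rate_dg = 0, evoked_rate_ca3 = 0)
  sim <- simulate_trial_counts(generate_ground_truth(cfg))
  expect_true(all(sim$counts$dg == 0, na.rm = TRUE))

  tr <- generate_ground_truth(small_cfg(seed = 3))
  x <- simulate_trial_counts(tr)$counts$dg
  for (j in seq_len(dim(x)[1])) {
    stim <- rownames(tr$mean_rates$dg)[j]
    expect_true(all(is.na(x[j, , stim])))
    expect_false(anyNA(x[j, , setdiff(dimnames(x)[[3]], stim)]))
  }
})

test_that("regional evoked rates land within 10% of the configured values", {
  lay <- mea_layout()
  cfg <- synth_config(seed = 8)      # full-size protocol
  sim <- simulate_trial_counts(generate_ground_truth(cfg))
  sr_dg <- rate_matrix(sim$counts$dg)
  sr_ca3 <- rate_matrix(sim$counts$ca3)
  dg_mean <- mean(region_rates(sr_dg, lay, "DG"), na.rm = TRUE)
  ca3_mean <- mean(region_rates(sr_ca3, lay, "CA3"), na.rm = TRUE)
  expect_lt(abs(dg_mean - cfg$evoked_rate_dg) / cfg$evoked_rate_dg, 0.10)
  expect_lt(abs(ca3_mean - cfg$evoked_rate_ca3) / cfg$evoked_rate_ca3, 0.10)
})

test_that("event tables agree with the counting pipeline they feed", {
  cfg <- small_cfg(seed = 4)
  tr <- generate_ground_truth(cfg)
  sim <- simulate_spike_events(tr)
  # recount from scratch and compare against the tensors shipped alongside
  again <- count_trial_spikes(sim$events, sim$stim_log, tr$layout,
                              window_s = cfg$window_s, blank_s = cfg$blank_s)
  expect_identical(again, sim$counts)
  # no generated event sits inside a blanking window
  pulses <- sort(c(sim$stim_log$p1_time_s, sim$stim_log$p2_time_s))
  for (p in pulses)
    expect_false(any(sim$events$spike_time_s >= p &
                     sim$events$spike_time_s < p + cfg$blank_s))
})

test_that("raw traces carry the configured noise floor and spike templates", {
  cfg <- small_cfg(seed = 6, artifact_amplitude_uV = 0)
  empty <- spike_events()
  log <- one_site_log(p1 = 100)      # far outside the rendered span
  rec <- simulate_raw_trace(empty, log, cfg, channels = 26L,
                            t_start = 0, t_end = 2)
  expect_equal(sd(rec$samples), cfg$noise_sd_uV, tolerance = 0.05)

  one <- spike_events(26L, 1.000)
  rec2 <- simulate_raw_trace(one, log, cfg, channels = 26L,
                             t_start = 0, t_end = 2)
  peak_t <- (which.max(abs(rec2$samples[, 1])) - 1) / cfg$sampling_rate
  expect_lt(abs(peak_t - 1.000), 0.0006)   # extremum within a half-width
})
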