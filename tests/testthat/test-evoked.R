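lay <- mea_layout()

test_that("evoked windows are half-open, blanked and pooled over both pulses", {
  log <- one_site_log(p1 = 10)       # site 26, P1 at 10 s, P2 at 10.05 s
  in_window <- spike_events(16L, 10.020)
  x <- count_trial_spikes(in_window, log, lay)$dg
  expect_equal(x[1, 1, "16"], 1L, ignore_attr = TRUE)

  outside <- spike_events(c(16L, 16L), c(10.002, 10.046))  # blank + post-window
  expect_equal(count_trial_spikes(outside, log, lay)$dg[1, 1, "16"], 0L,
               ignore_attr = TRUE)

  edges <- spike_events(c(16L, 16L, 16L), c(10.005, 10.045, 10.055))
  # [p+5ms, p+45ms): start inclusive, end exclusive, P2 window counts too
  expect_equal(count_trial_spikes(edges, log, lay)$dg[1, 1, "16"], 2L,
               ignore_attr = TRUE)

  close_log <- stim_log(c(26L, 26L), 1:2, c(10, 10.05), min_wait_s = 0)
  expect_error(count_trial_spikes(in_window, close_log, lay), "overlap")
})

test_that("count + rate pipeline equals a brute-force recount on random events", {
  cfg <- small_cfg(seed = 13)
  tr <- generate_ground_truth(cfg)
  sim <- simulate_spike_events(tr)
  sr <- rate_matrix(sim$counts$dg)
  sites <- as.integer(rownames(sr))
  electrodes <- c(sites, region_electrodes(lay, "CA3")[1:4])
  oracle <- oracle_rate_matrix(sim$events, sim$stim_log[
    sim$stim_log$site_electrode_id %in% sites, ], sites, electrodes,
    window_s = cfg$window_s, blank_s = cfg$blank_s)
  expect_equal(unclass(sr)[, as.character(electrodes)], oracle,
               ignore_attr = TRUE)
})

test_that("rate denominator is trials x 80 ms and arithmetic matches", {
  x <- array(2L, c(3, 25, 2), dimnames = list(c(16, 17, 18), NULL, c(63, 64)))
  sr <- rate_matrix(trial_count_tensor(x))
  expect_identical(attr(sr, "denominator_s"), 2)         # 25 x 0.080 s
  expect_true(all(sr == 25))                             # 50 spikes / 2 s
  expect_true(all(rate_matrix(trial_count_tensor(x * 0L)) == 0))
})

test_that("tunnel selection keeps the stronger electrode with documented ties", {
  tun <- lay[lay$region == "TUNNEL", ]
  pair <- tun$electrode_id[tun$tunnel_index == 1]        # two members
  single <- tun$electrode_id[tun$tunnel_index == 8]      # one member
  sr <- matrix(0, 4, nrow(tun), dimnames = list(1:4, tun$electrode_id))
  sr[, as.character(pair[1])] <- 5
  sr[, as.character(pair[2])] <- 3
  out <- select_tunnel_electrode(sr, lay)
  expect_true(as.character(pair[1]) %in% colnames(out))
  expect_false(as.character(pair[2]) %in% colnames(out))
  expect_true(as.character(single) %in% colnames(out))
  expect_equal(ncol(out), 8)

  sr[, as.character(pair[2])] <- 5                       # exact tie
  out2 <- select_tunnel_electrode(sr, lay)
  expect_true(as.character(min(pair)) %in% colnames(out2))
})

test_that("activity gating is strict and monotone in the threshold", {
  sr <- matrix(c(1.6, 1.5, 0), 5, 3, byrow = TRUE,
               dimnames = list(1:5, c("a", "b", "c")))
  act <- active_mask(sr)
  expect_true(act[["a"]])            # 1.6 Hz > 1.5 Hz
  expect_false(act[["b"]])           # exactly 1.5 Hz: strict >
  expect_false(act[["c"]])

  set.seed(4)
  sr2 <- matrix(rexp(60, 1), 6, 10)
  for (th in c(0.5, 1, 2, 4))
    expect_true(all(active_mask(sr2, th + 0.5) <= active_mask(sr2, th)))
})

test_that("masking hits exactly the within-region stimulated electrodes", {
  tr <- generate_ground_truth(small_cfg(seed = 3))
  x <- simulate_trial_counts(tr)$counts$dg
  n_masked_cells <- sum(is.na(x)) / dim(x)[2]
  expect_equal(n_masked_cells, dim(x)[1])  # every site is also an electrode
})

test_that("baseline estimators recover the generating rate and agree", {
  cfg <- small_cfg(seed = 21, n_trials = 40, baseline_rate_dg = 20,
                   baseline_rate_ca3 = 20, spont_duration_s = 60,
                   protocol_start_s = 60)
  tr <- generate_ground_truth(cfg)
  sim <- simulate_spike_events(tr)
  pre <- baseline_rates(sim$events, sim$stim_log, tr$layout, "pre_trigger")
  spo <- baseline_rates(sim$events, sim$stim_log, tr$layout, "spontaneous",
                        spont_duration_s = 60)
  # pooled pre-trigger duration per electrode
  t_pool <- nrow(sim$stim_log) * 0.005
  se_pre <- sqrt(20 / t_pool)
  expect_lt(abs(pre$regional_means_hz[["DG"]] - 20), 3 * se_pre / sqrt(22))
  se_spo <- sqrt(20 / 60)
  expect_lt(abs(spo$regional_means_hz[["DG"]] - 20), 3 * se_spo / sqrt(22))
  expect_lt(abs(pre$regional_means_hz[["DG"]] - spo$regional_means_hz[["DG"]]),
            3 * (se_pre + se_spo) / sqrt(22))

  none <- baseline_rates(spike_events(), sim$stim_log, tr$layout, "pre_trigger")
  expect_true(all(none$rates_hz == 0))
  expect_error(baseline_rates(sim$events, sim$stim_log, tr$layout,
                              "spontaneous", spont_duration_s = 1e5), "segment")
})

test_that("PSTHs localise responses and reference the all-site average", {
  log <- one_site_log(p1 = c(10, 20, 30), site = 26L)
  ev <- spike_events(rep(16L, 3), c(10, 20, 30) + 0.0225)
  p <- compute_psth(ev, log, electrode = 16L, site = 26L, layout = lay)
  expect_equal(sum(p$mean_counts > 0), 1)
  expect_equal(which(p$mean_counts > 0), 5L)   # the 20-25 ms bin
  expect_equal(p$mean_counts[5], 1)

  expect_error(compute_psth(ev, log, 16L, site = 99L, layout = lay), "site")

  # a uniform-rate electrode yields a flat histogram within sampling error
  set.seed(9)
  nlog <- one_site_log(p1 = seq(10, by = 5, length.out = 200), site = 26L)
  times <- sort(runif(4000, 10, 10 + 5 * 200))
  up <- compute_psth(spike_events(rep(16L, 4000), times), nlog, 16L, 26L, lay)
  lam <- mean(up$mean_counts)
  expect_true(all(abs(up$mean_counts - lam) < 5 * sqrt(lam / 200)))
})
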