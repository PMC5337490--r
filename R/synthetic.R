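# Synthetic two-chamber experiments with known ground truth.  The generator
# emulates the study conditions of the co-culture protocol: 22 paired-pulse
# stimulation sites per chamber, 25 trials, 50 ms inter-pulse interval, 5 s
# wait between pairs, regional baseline rates near 22/11 Hz (DG/CA3) and
# evoked rates near 87/56 Hz, a sparse site-specific DG->CA3 map, a broader
# and weaker CA3->DG map, and tunnel rates tightly coupled to the source
# region's aggregate drive.

#' Configuration for the synthetic experiment generator
#'
#' All rates are total rates (Hz) inside the evoked counting windows;
#' trial-to-trial count variability is Poisson.
#'
#' @param seed integer RNG seed; every downstream draw is deterministic
#'   given the seed.
#' @param n_sites_per_region stimulation sites per chamber (default 22).
#' @param n_trials paired-pulse repetitions per site (default 25).
#' @param sparseness_m number of CA3 electrodes responsive to each DG site
#'   (default 4, within the observed 3-6 range).
#' @param specificity_overlap probability that a responsive electrode is
#'   re-used from another site's responsive set rather than drawn fresh
#'   (0 = fully independent sets).
#' @param baseline_rate_dg,baseline_rate_ca3 spontaneous rates, Hz.
#' @param evoked_rate_dg,evoked_rate_ca3 mean evoked rates on driven
#'   electrodes, Hz.
#' @param directionality fraction of tunnel axons oriented DG->CA3
#'   (default 0.84); the reverse CA3->DG drive is scaled by
#'   `(1 - directionality) / directionality`.
#' @param reverse_breadth multiplier on `sparseness_m` for the size of the
#'   (broader, weaker) DG sets responsive to CA3 stimulation.
#' @param rate_dispersion log-normal sdlog of per-(site, electrode) mean
#'   rates around the regional mean (mean-preserving) for within-region
#'   responses.
#' @param evoked_dispersion_sdlog log-normal sdlog of the graded
#'   cross-region evoked amplitudes (default 0.7: evoked rates span about
#'   an order of magnitude across responsive (site, electrode) pairs, as
#'   log-scale rate matrices of real arrays do).
#' @param site_strength_sdlog log-normal sdlog of the per-site excitability
#'   factor multiplying the source-region drive (and hence the tunnel
#'   drive); this spread, against `tunnel_noise_sdlog`, sets the high
#'   source-tunnel log-log correlation of the mass-action pathway.
#' @param tunnel_noise_sdlog log-normal scatter of tunnel drive around the
#'   source aggregate; small values give the high source-tunnel log-log
#'   correlation seen on the native direction.
#' @param inter_pulse_s,wait_s,protocol_start_s protocol timing: inter-pulse
#'   interval, wait between pairs, and start of the stimulation protocol
#'   (the preceding `spont_duration_s` seconds carry spontaneous activity).
#' @param window_s,blank_s evoked counting window per pulse and post-pulse
#'   blanking (defaults 0.040 and 0.005 s).
#' @param spont_duration_s length of the pre-protocol spontaneous segment.
#' @param noise_sd_uV,artifact_amplitude_uV,artifact_tau_ms raw-trace
#'   parameters: Gaussian noise floor, stimulus-artifact amplitude and decay
#'   constant.
#' @param sampling_rate raw-trace sampling rate, Hz.
#' @return Validated list of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, n_sites_per_region = 4, n_trials = 5)
#' @export
synth_config <- function(seed = 1L,
                         n_sites_per_region = 22L,
                         n_trials = 25L,
                         sparseness_m = 4L,
                         specificity_overlap = 0.25,
                         baseline_rate_dg = 22.2,
                         baseline_rate_ca3 = 11.2,
                         evoked_rate_dg = 86.5,
                         evoked_rate_ca3 = 55.7,
                         directionality = 0.84,
                         reverse_breadth = 2,
                         rate_dispersion = 0.25,
                         evoked_dispersion_sdlog = 0.7,
                         site_strength_sdlog = 0.5,
                         tunnel_noise_sdlog = 0.15,
                         inter_pulse_s = 0.050,
                         wait_s = 5,
                         protocol_start_s = 180,
                         window_s = 0.040,
                         blank_s = 0.005,
                         spont_duration_s = 180,
                         noise_sd_uV = 5,
                         artifact_amplitude_uV = 500,
                         artifact_tau_ms = 5,
                         sampling_rate = 25000) {
  cfg <- as.list(environment())
  rates <- c(baseline_rate_dg, baseline_rate_ca3, evoked_rate_dg,
             evoked_rate_ca3)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (specificity_overlap < 0 || specificity_overlap > 1)
    stop("specificity_overlap must lie in [0, 1]")
  if (directionality <= 0 || directionality > 1)
    stop("directionality must lie in (0, 1]")
  if (sparseness_m < 1 || sparseness_m > 22)
    stop("sparseness_m must lie in 1..22")
  if (n_sites_per_region < 2 || n_sites_per_region > 22)
    stop("n_sites_per_region must lie in 2..22")
  stopifnot(n_trials >= 1, window_s > 0, blank_s >= 0, inter_pulse_s > 0,
            wait_s > 0, sampling_rate > 0)
  if (inter_pulse_s < blank_s + window_s)
    stop("inter-pulse interval shorter than blanking + counting window")
  class(cfg) <- "synth_config"
  cfg
}

# mean-preserving log-normal draws around `mean_rate`
rlnorm_mean <- function(n, mean_rate, sdlog) {
  if (mean_rate == 0) return(rep(0, n))
  stats::rlnorm(n, meanlog = log(mean_rate) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate the ground-truth response map of a synthetic network
#'
#' Draws, deterministically given `config$seed`, the mean evoked rate of
#' every electrode for every stimulation site in both chambers:
#' within-region responses are broad (every electrode driven), the DG->CA3
#' map is sparse (exactly `sparseness_m` responsive CA3 electrodes per DG
#' site), the CA3->DG map is broader and weaker (scaled by
#' `(1 - directionality)/directionality`), and tunnel electrodes carry a
#' noisy scaled copy of the source region's aggregate drive.
#'
#' @param config a [synth_config()].
#' @return List of class `mea_ground_truth` with elements `layout`,
#'   `config`, `mean_rates` (list `dg`, `ca3`: site x electrode matrices of
#'   total in-window rates, Hz, one row per stimulation site), `responsive`
#'   (list `dg_to_ca3`, `ca3_to_dg`: per-site responsive electrode sets) and
#'   `tunnel_drive` (per-site mean tunnel rate by stimulation region).
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  layout <- mea_layout()
  with_local_seed(config$seed, {
    dg_el <- region_electrodes(layout, "DG")
    ca3_el <- region_electrodes(layout, "CA3")
    tun_el <- region_electrodes(layout, "TUNNEL")
    ns <- config$n_sites_per_region
    sites <- list(dg = dg_el[seq_len(ns)], ca3 = ca3_el[seq_len(ns)])
    m <- config$sparseness_m
    if (m > length(ca3_el)) stop("sparseness_m exceeds electrode count")
    rev_scale <- (1 - config$directionality) / config$directionality
    m_rev <- min(length(dg_el), max(m, round(config$reverse_breadth * m)))

    draw_sets <- function(targets, size, overlap) {
      sets <- vector("list", ns)
      used <- integer(0)
      for (j in seq_len(ns)) {
        s <- integer(0)
        for (slot in seq_len(size)) {
          pool_old <- setdiff(used, s)
          from_old <- length(pool_old) > 0 && runif(1) < overlap
          pool <- if (from_old) pool_old else setdiff(targets, s)
          s <- c(s, pool[sample.int(length(pool), 1)])
        }
        sets[[j]] <- sort(s)
        used <- union(used, s)
      }
      sets
    }
    set_ca3 <- draw_sets(ca3_el, m, config$specificity_overlap)
    set_dg <- draw_sets(dg_el, m_rev, config$specificity_overlap)

    all_el <- layout$electrode_id
    mk <- function(stim_region) {
      M <- matrix(0, ns, length(all_el),
                  dimnames = list(sites[[stim_region]], all_el))
      # per-site excitability: how strongly a site drives its own region
      # (and, through the mass-action pathway, the tunnels); the sparse
      # cross-region map does not scale with it
      strength <- rlnorm_mean(ns, 1, config$site_strength_sdlog)
      strength <- strength / mean(strength)   # regional means stay calibrated
      for (j in seq_len(ns)) {
        if (stim_region == "dg") {
          M[j, as.character(dg_el)] <- strength[j] *
            rlnorm_mean(length(dg_el), config$evoked_rate_dg,
                        config$rate_dispersion)
          M[j, as.character(ca3_el)] <- config$baseline_rate_ca3
          M[j, as.character(set_ca3[[j]])] <-
            rlnorm_mean(m, config$evoked_rate_ca3,
                        config$evoked_dispersion_sdlog)
        } else {
          M[j, as.character(ca3_el)] <- strength[j] *
            rlnorm_mean(length(ca3_el), config$evoked_rate_ca3,
                        config$rate_dispersion)
          M[j, as.character(dg_el)] <- config$baseline_rate_dg
          extra <- rev_scale *
            rlnorm_mean(m_rev, config$evoked_rate_dg - config$baseline_rate_dg,
                        config$evoked_dispersion_sdlog)
          M[j, as.character(set_dg[[j]])] <- config$baseline_rate_dg + extra
        }
      }
      # tunnel drive: noisy scaled copy of the source aggregate (mass action)
      src_cols <- as.character(if (stim_region == "dg") dg_el else ca3_el)
      gain <- if (stim_region == "dg") 1 else rev_scale
      agg <- rowMeans(M[, src_cols, drop = FALSE])
      for (j in seq_len(ns))
        M[j, as.character(tun_el)] <- gain * agg[j] *
          stats::rlnorm(length(tun_el), -config$tunnel_noise_sdlog^2 / 2,
                        config$tunnel_noise_sdlog)
      M
    }
    structure(list(layout = layout, config = config, sites = sites,
                   mean_rates = list(dg = mk("dg"), ca3 = mk("ca3")),
                   responsive = list(dg_to_ca3 = set_ca3, ca3_to_dg = set_dg),
                   tunnel_drive = NULL),
              class = "mea_ground_truth")
  })
}

# build the alternating DG/CA3 paired-pulse schedule
build_stim_log <- function(truth) {
  cfg <- truth$config
  ns <- cfg$n_sites_per_region
  # pairs alternate between chambers: DG site, CA3 site, next DG site, ...
  site_seq <- integer(0)
  for (t in seq_len(cfg$n_trials))
    for (j in seq_len(ns))
      site_seq <- c(site_seq, truth$sites$dg[j], truth$sites$ca3[j])
  n_pairs <- length(site_seq)
  p1 <- cfg$protocol_start_s + (seq_len(n_pairs) - 1) * cfg$wait_s
  # trial index: each site appears once per round of 2 * ns pairs
  trial <- rep(seq_len(cfg$n_trials), each = 2L * ns)
  stim_log(site_seq, trial, p1, p1 + cfg$inter_pulse_s,
           inter_pulse_s = cfg$inter_pulse_s, min_wait_s = min(cfg$wait_s, 5))
}

#' Simulate per-trial evoked spike counts
#'
#' Draws Poisson trial counts around the ground-truth mean rates: the count
#' of electrode i on trial t of site j is Poisson with mean
#' `rate[j, i] * 2 * window_s` (the two 40 ms counting windows of a pair).
#' The stimulated electrode itself is masked (`NA`), mirroring amplifier
#' saturation at the stimulation site.
#'
#' @param truth a [generate_ground_truth()] result.
#' @return List with elements `counts` (list `dg`, `ca3` of
#'   `trial_count_tensor` arrays, site x trial x electrode, stimulation in
#'   that region) and `stim_log`.
#' @export
simulate_trial_counts <- function(truth) {
  stopifnot(inherits(truth, "mea_ground_truth"))
  cfg <- truth$config
  log <- build_stim_log(truth)
  win <- 2 * cfg$window_s
  with_local_seed(derive_seed(cfg$seed, 101L), {
    counts <- lapply(c(dg = "dg", ca3 = "ca3"), function(reg) {
      M <- truth$mean_rates[[reg]]
      ns <- nrow(M); ne <- ncol(M); nt <- cfg$n_trials
      # mean of cell (e, t, j) in fill order is M[j, e], independent of t
      lam <- as.vector(t(M)[, rep(seq_len(ns), each = nt)]) * win
      x <- aperm(array(rpois(ns * nt * ne, lam), dim = c(ne, nt, ns)),
                 c(3, 2, 1))
      dimnames(x) <- list(rownames(M), NULL, colnames(M))
      for (j in seq_len(ns)) {
        stim_el <- as.character(truth$sites[[reg]][j])
        if (stim_el %in% colnames(M)) x[j, , stim_el] <- NA_integer_
      }
      trial_count_tensor(x, window_s = cfg$window_s)
    })
    list(counts = counts, stim_log = log)
  })
}

#' Simulate a spike-event table consistent with Poisson trial counts
#'
#' Generates the event-level view of a synthetic experiment: evoked spikes
#' are drawn per counting window (Poisson, mean `rate * window_s`) and
#' placed uniformly within `[pulse + blank_s, pulse + blank_s + window_s)`;
#' spontaneous background is generated in a pre-protocol segment of
#' `spont_duration_s` seconds and in the 10 ms immediately before each
#' pair (so both baseline estimators have data).  Inter-pair gaps carry no
#' events, which keeps tables compact at desk scale.
#'
#' @param truth a [generate_ground_truth()] result.
#' @return List with `events` (a [spike_events()] table), `stim_log`, and
#'   `counts` (tensors recounted from the generated events; exactly what
#'   [count_trial_spikes()] recovers).
#' @export
simulate_spike_events <- function(truth) {
  stopifnot(inherits(truth, "mea_ground_truth"))
  cfg <- truth$config
  log <- build_stim_log(truth)
  layout <- truth$layout
  with_local_seed(derive_seed(cfg$seed, 202L), {
    el <- numeric(0); tm <- numeric(0)
    base_rate <- ifelse(layout$region == "DG", cfg$baseline_rate_dg,
                        ifelse(layout$region == "CA3", cfg$baseline_rate_ca3,
                               mean(c(cfg$baseline_rate_dg, cfg$baseline_rate_ca3))))
    # pre-protocol spontaneous segment
    t1 <- cfg$protocol_start_s
    t0 <- max(0, t1 - cfg$spont_duration_s)
    for (i in seq_len(nrow(layout))) {
      n <- rpois(1, base_rate[i] * (t1 - t0))
      if (n) { el <- c(el, rep(layout$electrode_id[i], n))
               tm <- c(tm, runif(n, t0, t1)) }
    }
    # per-pair evoked + pre-trigger background
    reg_of_site <- function(s) layout$region[match(s, layout$electrode_id)]
    for (r in seq_len(nrow(log))) {
      s <- log$site_electrode_id[r]
      reg <- tolower(reg_of_site(s))
      M <- truth$mean_rates[[reg]]
      rates <- M[as.character(s), ]
      ids <- as.integer(colnames(M))
      stim_idx <- which(ids == s)
      for (p in c(log$p1_time_s[r], log$p2_time_s[r])) {
        a <- p + cfg$blank_s
        n <- rpois(length(rates), rates * cfg$window_s)
        if (length(stim_idx)) n[stim_idx] <- 0L  # saturated channel is silent
        tot <- sum(n)
        if (tot) { el <- c(el, rep(ids, n))
                   tm <- c(tm, a + runif(tot, 0, cfg$window_s)) }
      }
      # 10 ms background before P1 at baseline rates
      nb <- rpois(nrow(layout), base_rate * 0.010)
      totb <- sum(nb)
      if (totb) { el <- c(el, rep(layout$electrode_id, nb))
                  tm <- c(tm, log$p1_time_s[r] - runif(totb, 0, 0.010)) }
    }
    events <- spike_events(el, tm, layout = layout)
    counts <- count_trial_spikes(events, log, layout,
                                 window_s = cfg$window_s, blank_s = cfg$blank_s)
    list(events = events, stim_log = log, counts = counts)
  })
}

# biphasic spike template, 1 ms, peak-to-peak 10 noise SDs, absolute
# extremum (the negative lobe) at the template centre
spike_template <- function(noise_sd, sampling_rate) {
  n <- round(0.001 * sampling_rate)
  n_pos <- round(0.4 * n)
  n_neg <- n - n_pos
  pos <- 4 * noise_sd * sin(pi * seq_len(n_pos) / (n_pos + 1))
  neg <- -6 * noise_sd * sin(pi * seq_len(n_neg) / (n_neg + 1))
  tpl <- c(pos, neg)
  list(shape = tpl, center = n_pos + which.min(neg))
}

#' Simulate a raw voltage trace from spike events
#'
#' Builds the signal that spike detection and artifact removal consume:
#' Gaussian background noise, a fixed biphasic spike template (1 ms,
#' peak-to-peak 10 noise SDs, absolute extremum at the event time) inserted
#' at each event, and an exponential stimulus artifact
#' `A exp(-t / tau)` added at every pulse time.  Overlapping insertions sum.
#'
#' @param events a [spike_events()] table (only the requested channels are
#'   rendered).
#' @param log a [stim_log()]; artifacts appear on every channel.
#' @param config a [synth_config()] supplying noise/artifact parameters.
#' @param channels electrode ids to render.
#' @param t_start,t_end rendered time span, seconds.
#' @return A [raw_recording()].
#' @export
simulate_raw_trace <- function(events, log, config, channels,
                               t_start = 0, t_end = NULL) {
  stopifnot(inherits(config, "synth_config"), t_end > t_start)
  fs <- config$sampling_rate
  n <- round((t_end - t_start) * fs)
  with_local_seed(derive_seed(config$seed, 303L), {
    x <- matrix(rnorm(n * length(channels), 0, config$noise_sd_uV),
                n, length(channels))
    tpl <- spike_template(config$noise_sd_uV, fs)
    tau <- config$artifact_tau_ms / 1000
    pulses <- c(log$p1_time_s, log$p2_time_s)
    pulses <- pulses[pulses >= t_start - 1 & pulses <= t_end]
    for (ci in seq_along(channels)) {
      ev <- events$spike_time_s[events$electrode_id == channels[ci] &
                                  events$spike_time_s >= t_start &
                                  events$spike_time_s < t_end]
      for (tt in ev) {
        i0 <- round((tt - t_start) * fs) + 1 - tpl$center + 1
        idx <- seq(i0, i0 + length(tpl$shape) - 1)
        ok <- idx >= 1 & idx <= n
        x[idx[ok], ci] <- x[idx[ok], ci] + tpl$shape[ok]
      }
      for (p in pulses) {
        i0 <- max(1, floor((p - t_start) * fs) + 1)
        if (i0 > n) next
        tdec <- (seq(i0, n) - 1) / fs + t_start - p
        keep <- tdec <= 8 * tau
        x[seq(i0, n)[keep], ci] <- x[seq(i0, n)[keep], ci] +
          config$artifact_amplitude_uV * exp(-tdec[keep] / tau)
      }
    }
    raw_recording(x, sampling_rate = fs, t0 = t_start, channel_ids = channels)
  })
}

#' @export
print.mea_ground_truth <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<mea_ground_truth> seed %d: %d sites/region x %d trials, ",
                     "sparseness m = %d, directionality %.2f\n"),
              cfg$seed, cfg$n_sites_per_region, cfg$n_trials,
              cfg$sparseness_m, cfg$directionality))
  invisible(x)
}
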