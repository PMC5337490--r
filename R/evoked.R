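# Evoked-response extraction: per-trial counts, trial-averaged spike-rate
# matrices, baselines, tunnel-electrode selection, activity filtering, PSTHs.

#' Per-trial evoked count tensors
#'
#' A `trial_count_tensor` is a 3-d integer array indexed
#' (stimulation site x trial x electrode); `NA` marks the saturated
#' stimulated electrode.  `window_s` is the per-pulse counting window, so a
#' trial spans `2 * window_s` seconds of counted time.
#'
#' @param x site x trial x electrode array with dimnames on sites and
#'   electrodes.
#' @param window_s counting window per pulse, seconds (default 0.040).
#' @return The array with class `trial_count_tensor`.
#' @export
trial_count_tensor <- function(x, window_s = 0.040) {
  stopifnot(length(dim(x)) == 3, window_s > 0)
  if (any(x < 0, na.rm = TRUE)) stop("negative counts")
  attr(x, "window_s") <- window_s
  class(x) <- "trial_count_tensor"
  x
}

#' Count evoked spikes per trial from events and a stimulation log
#'
#' For each (site, trial, electrode), counts spikes in the two half-open
#' evoked windows `[p + blank_s, p + blank_s + window_s)` after pulses P1
#' and P2.  The stimulated electrode's own entries are masked (`NA`),
#' reflecting amplifier saturation at the stimulation site.  One tensor is
#' returned per stimulation region.
#'
#' @param events a [spike_events()] table.
#' @param log a [stim_log()].
#' @param layout a [mea_layout()].
#' @param window_s counting window per pulse (default 0.040 s).
#' @param blank_s post-pulse blanking (default 0.005 s).
#' @return Named list of [trial_count_tensor()] arrays, one per stimulation
#'   region present in the log (lower-case region names), each
#'   site x trial x electrode over all layout electrodes.
#' @export
count_trial_spikes <- function(events, log, layout,
                               window_s = 0.040, blank_s = 0.005) {
  # windows of consecutive pairs must not overlap
  ord <- order(log$p1_time_s)
  ends <- log$p2_time_s[ord] + blank_s + window_s
  if (any(ends[-length(ends)] > log$p1_time_s[ord][-1] + 1e-9))
    stop("response windows of consecutive trials overlap; log invalid")

  by_el <- split(events$spike_time_s, events$electrode_id)
  count_in <- function(times, a, b) {
    if (is.null(times)) return(0L)
    as.integer(diff(findInterval(c(a, b), times, left.open = TRUE)))
  }
  regions <- unique(layout$region[match(log$site_electrode_id,
                                        layout$electrode_id)])
  out <- list()
  for (reg in regions) {
    sites <- sort(unique(log$site_electrode_id[
      layout$region[match(log$site_electrode_id, layout$electrode_id)] == reg]))
    nt <- max(log$trial)
    el <- layout$electrode_id
    x <- array(0L, dim = c(length(sites), nt, length(el)),
               dimnames = list(sites, NULL, el))
    sub <- log[log$site_electrode_id %in% sites, ]
    for (r in seq_len(nrow(sub))) {
      j <- match(sub$site_electrode_id[r], sites)
      t <- sub$trial[r]
      # boundaries on the 1 us time grid of the event-table format
      a1 <- round(sub$p1_time_s[r] + blank_s, 6)
      a2 <- round(sub$p2_time_s[r] + blank_s, 6)
      b1 <- round(a1 + window_s, 6)
      b2 <- round(a2 + window_s, 6)
      for (i in seq_along(el)) {
        times <- by_el[[as.character(el[i])]]
        x[j, t, i] <- count_in(times, a1, b1) + count_in(times, a2, b2)
      }
    }
    for (j in seq_along(sites)) {
      k <- match(sites[j], el)
      if (!is.na(k)) x[j, , k] <- NA_integer_
    }
    out[[tolower(reg)]] <- trial_count_tensor(x, window_s = window_s)
  }
  out
}

#' Trial-averaged spike-rate matrix
#'
#' Collapses a count tensor into the spike-rate matrix SR: rows are
#' stimulation sites, columns electrodes, and
#' `SR[j, i] = sum over trials of counts / (n_trials * 2 * window_s)` -- at
#' the default 25 trials of 80 ms counted time the denominator is exactly
#' 2 s.  Masked (`NA`) cells propagate.
#'
#' @param tensor a [trial_count_tensor()].
#' @return Matrix of class `spike_rate_matrix` (Hz) with attributes
#'   `n_trials`, `window_s` and `denominator_s`.
#' @examples
#' x <- array(2L, c(2, 25, 3), dimnames = list(1:2, NULL, 1:3))
#' rate_matrix(trial_count_tensor(x))[1, 1]   # 50 spikes / 2 s = 25 Hz
#' @export
rate_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "trial_count_tensor"))
  nt <- dim(tensor)[2]
  if (nt < 1) stop("tensor holds zero trials")
  win <- attr(tensor, "window_s")
  denom <- nt * 2 * win
  sr <- apply(unclass(tensor), c(1, 3), function(v)
    if (all(is.na(v))) NA_real_ else sum(v))
  sr <- sr / denom
  structure(sr, n_trials = nt, window_s = win, denominator_s = denom,
            class = c("spike_rate_matrix", class(sr)))
}

# subset the electrode columns of a rate matrix by layout region
#' Restrict a spike-rate matrix to the electrodes of one region
#' @param rates a [rate_matrix()] result over all electrodes.
#' @param layout a [mea_layout()].
#' @param region `"DG"`, `"CA3"` or `"TUNNEL"`.
#' @return The sub-matrix (same class and attributes).
#' @export
region_rates <- function(rates, layout, region) {
  keep <- as.character(region_electrodes(layout, region))
  out <- rates[, intersect(colnames(rates), keep), drop = FALSE]
  attributes(out)[c("n_trials", "window_s", "denominator_s")] <-
    attributes(rates)[c("n_trials", "window_s", "denominator_s")]
  class(out) <- class(rates)
  out
}

#' Select one electrode per tunnel
#'
#' Of the (up to two) electrodes in each micro-tunnel, retains the one with
#' the larger mean spike rate over stimulation sites -- the better
#' axon-to-electrode coupling -- dropping the other.  Ties keep the lower
#' electrode id; masked cells are ignored in the mean.
#'
#' @param rates a rate matrix whose columns include tunnel electrodes.
#' @param layout a [mea_layout()].
#' @return The rate matrix restricted to one column per tunnel, ordered by
#'   tunnel index, with attribute `selected` naming the kept electrode per
#'   tunnel.
#' @export
select_tunnel_electrode <- function(rates, layout) {
  tun <- layout[layout$region == "TUNNEL", ]
  keep <- vapply(sort(unique(tun$tunnel_index)), function(ti) {
    members <- tun$electrode_id[tun$tunnel_index == ti]
    members <- members[as.character(members) %in% colnames(rates)]
    if (!length(members)) return(NA_integer_)
    mu <- vapply(as.character(members), function(e)
      mean(rates[, e], na.rm = TRUE), numeric(1))
    mu[is.nan(mu)] <- -Inf
    members[order(-mu, members)][1]   # higher rate, tie -> lower id
  }, integer(1))
  keep <- keep[!is.na(keep)]
  out <- rates[, as.character(keep), drop = FALSE]
  attributes(out)[c("n_trials", "window_s", "denominator_s")] <-
    attributes(rates)[c("n_trials", "window_s", "denominator_s")]
  attr(out, "selected") <- keep
  class(out) <- class(rates)
  out
}

#' Active-electrode mask
#'
#' An electrode is active when its maximum unmasked rate over stimulation
#' sites strictly exceeds the threshold (default 1.5 Hz), i.e. when at
#' least one stimulation site drives it above threshold.
#'
#' @param rates a rate matrix (sites x electrodes).
#' @param threshold_hz activity threshold, Hz (default 1.5, strict `>`).
#' @return Named logical vector over electrodes.
#' @export
active_mask <- function(rates, threshold_hz = 1.5) {
  apply(rates, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && max(v) > threshold_hz
  })
}

#' Baseline firing-rate estimates
#'
#' Two estimators of per-electrode baseline rates: `"pre_trigger"` pools
#' spikes in the 5 ms immediately before every P1 pulse (over all sites and
#' trials) and divides by the pooled duration; `"spontaneous"` counts
#' spikes in a pre-protocol segment (default the 180 s before the first
#' pulse) and divides by its duration.
#'
#' @param events a [spike_events()] table.
#' @param log a [stim_log()].
#' @param layout a [mea_layout()].
#' @param method `"pre_trigger"` or `"spontaneous"`.
#' @param pre_window_s pre-trigger window length (default 0.005 s).
#' @param spont_duration_s spontaneous segment length (default 180 s).
#' @param electrodes electrodes to report (default: all in the layout).
#' @return List of class `baseline_estimate`: `method`, `rates_hz` (named
#'   per electrode) and `regional_means_hz` for DG and CA3.
#' @export
baseline_rates <- function(events, log, layout,
                           method = c("pre_trigger", "spontaneous"),
                           pre_window_s = 0.005, spont_duration_s = 180,
                           electrodes = NULL) {
  method <- match.arg(method)
  electrodes <- electrodes %||% layout$electrode_id
  by_el <- split(events$spike_time_s, events$electrode_id)
  count_in <- function(times, a, b) {
    if (is.null(times)) return(0L)
    as.integer(diff(findInterval(c(a, b), times, left.open = TRUE)))
  }
  if (method == "pre_trigger") {
    total_t <- nrow(log) * pre_window_s
    rates <- vapply(as.character(electrodes), function(e) {
      times <- by_el[[e]]
      n <- sum(vapply(seq_len(nrow(log)), function(r)
        count_in(times, log$p1_time_s[r] - pre_window_s, log$p1_time_s[r]),
        integer(1)))
      n / total_t
    }, numeric(1))
  } else {
    t1 <- min(log$p1_time_s)
    t0 <- t1 - spont_duration_s
    if (t0 < -1e-9)
      stop("no ", spont_duration_s, " s pre-protocol segment before the first pulse")
    rates <- vapply(as.character(electrodes), function(e)
      count_in(by_el[[e]], t0, t1) / spont_duration_s, numeric(1))
  }
  reg <- layout$region[match(as.integer(names(rates)), layout$electrode_id)]
  structure(list(method = method, rates_hz = rates,
                 regional_means_hz = c(DG = mean(rates[reg == "DG"]),
                                       CA3 = mean(rates[reg == "CA3"]))),
            class = "baseline_estimate")
}

#' Post-stimulus time histogram
#'
#' Mean spike count per peri-stimulus bin across the trials of one
#' (electrode, stimulation site) pair, over 0-100 ms after P1 (5 ms bins by
#' default, spanning both pulses of a pair), together with the same
#' electrode's average over all stimulation sites of the same region -- the
#' reference curve against which site-specific facilitation or suppression
#' is read.
#'
#' @param events a [spike_events()] table.
#' @param log a [stim_log()].
#' @param electrode recorded electrode id.
#' @param site stimulation site (electrode id present in the log).
#' @param layout a [mea_layout()] (used to find the site's region).
#' @param bin_ms bin width, ms (default 5; must divide `span_ms`).
#' @param span_ms peri-stimulus span after P1, ms (default 100).
#' @return List of class `psth`: `bin_edges_ms`, `mean_counts` (per bin),
#'   `all_site_mean_counts`, `electrode`, `site`.
#' @export
compute_psth <- function(events, log, electrode, site, layout,
                         bin_ms = 5, span_ms = 100) {
  if (!site %in% log$site_electrode_id) stop("unknown stimulation site ", site)
  if (!electrode %in% layout$electrode_id) stop("unknown electrode ", electrode)
  stopifnot(span_ms %% bin_ms == 0)
  edges <- seq(0, span_ms, by = bin_ms)
  times <- events$spike_time_s[events$electrode_id == electrode]
  hist_for <- function(p1s) {
    m <- matrix(0, length(p1s), length(edges) - 1)
    for (r in seq_along(p1s)) {
      rel <- (times - p1s[r]) * 1000
      rel <- rel[rel >= 0 & rel < span_ms]
      if (length(rel))
        m[r, ] <- tabulate(findInterval(rel, edges), length(edges) - 1)
    }
    colMeans(m)
  }
  site_reg <- layout$region[match(site, layout$electrode_id)]
  log_reg <- log[layout$region[match(log$site_electrode_id,
                                     layout$electrode_id)] == site_reg, ]
  structure(list(bin_edges_ms = edges,
                 mean_counts = hist_for(log$p1_time_s[log$site_electrode_id == site]),
                 all_site_mean_counts = hist_for(log_reg$p1_time_s),
                 electrode = electrode, site = site),
            class = "psth")
}

#' @export
print.spike_rate_matrix <- function(x, ...) {
  cat(sprintf("<spike_rate_matrix> %d sites x %d electrodes, denominator %.3g s/cell\n",
              nrow(x), ncol(x), attr(x, "denominator_s")))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(8, ncol(x))),
                   drop = FALSE], digits = 3)
  invisible(x)
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> method %s: DG %.2f Hz, CA3 %.2f Hz\n",
              x$method, x$regional_means_hz["DG"], x$regional_means_hz["CA3"]))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  mids <- head(x$bin_edges_ms, -1) + diff(x$bin_edges_ms) / 2
  plot(mids, x$mean_counts, type = "s", xlab = "time after P1 (ms)",
       ylab = "mean spikes / bin",
       main = sprintf("e%d | stim e%d", x$electrode, x$site), ...)
  lines(mids, x$all_site_mean_counts, type = "s", col = "darkgreen")
  legend("topright", bty = "n", lty = 1, col = c("black", "darkgreen"),
         legend = c("this site", "all sites"))
  invisible(x)
}
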