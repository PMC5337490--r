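# Raw-trace preprocessing: noise estimation, stimulus-artifact removal with
# post-pulse blanking, and peak-to-peak threshold spike detection.

#' Spike-detection parameters
#'
#' @param threshold_multiplier differential threshold in units of the
#'   baseline-noise SD (default 8).
#' @param peak_lifetime_ms length of the sliding peak-to-peak window, ms
#'   (default 2).
#' @param refractory_ms minimum separation between events, ms (default 1).
#' @param blanking_ms post-pulse blanking window, ms (default 5).
#' @return List of class `detection_params`.
#' @export
detection_params <- function(threshold_multiplier = 8, peak_lifetime_ms = 2,
                             refractory_ms = 1, blanking_ms = 5) {
  stopifnot(threshold_multiplier > 0, peak_lifetime_ms > 0,
            refractory_ms > 0, blanking_ms > 0)
  structure(list(threshold_multiplier = threshold_multiplier,
                 peak_lifetime_ms = peak_lifetime_ms,
                 refractory_ms = refractory_ms,
                 blanking_ms = blanking_ms),
            class = "detection_params")
}

# logical sample validity mask: FALSE inside [pulse, pulse + blank) windows
blanking_valid_mask <- function(n, sampling_rate, pulse_times, blanking_s,
                                t0 = 0) {
  valid <- rep(TRUE, n)
  for (p in pulse_times) {
    i0 <- floor((p - t0) * sampling_rate) + 1
    i1 <- ceiling((p + blanking_s - t0) * sampling_rate)
    lo <- max(1, i0); hi <- min(n, i1)
    if (lo <= hi) valid[lo:hi] <- FALSE
  }
  valid
}

#' Robust noise-floor estimate of a voltage trace
#'
#' Estimates the standard deviation of the baseline noise with the median
#' absolute deviation scaled to the Gaussian SD -- insensitive to the sparse
#' large excursions spikes produce.
#'
#' @param trace numeric voltage vector (microvolts).
#' @param sampling_rate Hz; with `min_duration_s` sets the minimum usable
#'   data requirement (default 1 s of unmasked samples).
#' @param valid optional logical mask; `FALSE` samples are excluded.
#' @param min_duration_s minimum unmasked duration, seconds.
#' @return Noise SD in microvolts.
#' @export
estimate_noise_sd <- function(trace, sampling_rate = 25000, valid = NULL,
                              min_duration_s = 1) {
  x <- if (is.null(valid)) trace else trace[valid]
  if (length(x) < min_duration_s * sampling_rate)
    stop("fewer than ", min_duration_s, " s of unmasked samples")
  mad(x)
}

#' Remove exponential stimulus artifacts from a trace
#'
#' For each pulse, fits `A * exp(-t / tau) + C` by nonlinear least squares
#' on the fit window starting at the end of the blanking window, and
#' subtracts the exponential component `A * exp(-t / tau)`.  Samples inside
#' the blanking window are flagged invalid rather than corrected.  A failed
#' fit leaves that pulse uncorrected and is recorded.
#'
#' @param trace numeric voltage vector (microvolts).
#' @param pulse_times pulse onset times, seconds.
#' @param sampling_rate Hz.
#' @param fit_window_s fit window after blanking end (default 0.040 s,
#'   matching the analysis window over which artifacts decay to baseline).
#' @param blanking_s post-pulse blanking (default 0.005 s).
#' @param t0 time of the first sample.
#' @return List of class `artifact_corrected`: `trace` (corrected),
#'   `valid` (logical mask, `FALSE` in blanking windows), `fits` (per-pulse
#'   A, tau, C or NA), `failed_pulses` (indices with no correction).
#' @export
remove_stim_artifact <- function(trace, pulse_times, sampling_rate = 25000,
                                 fit_window_s = 0.040, blanking_s = 0.005,
                                 t0 = 0) {
  n <- length(trace)
  out <- trace
  valid <- blanking_valid_mask(n, sampling_rate, pulse_times, blanking_s, t0)
  fits <- matrix(NA_real_, length(pulse_times), 3,
                 dimnames = list(NULL, c("A", "tau", "C")))
  failed <- integer(0)
  for (k in seq_along(pulse_times)) {
    p <- pulse_times[k]
    i0 <- floor((p + blanking_s - t0) * sampling_rate) + 1
    i1 <- min(n, i0 + round(fit_window_s * sampling_rate) - 1)
    if (i0 < 1 || i1 - i0 < 10) { failed <- c(failed, k); next }
    idx <- i0:i1
    tt <- (idx - 1) / sampling_rate + t0 - p   # time since pulse
    y <- out[idx]
    if (stats::sd(y) < 1e-12) { fits[k, ] <- c(0, 1, y[1]); next }
    st <- artifact_start_values(tt, y)
    resid_fn <- function(par) y - (par[1] * exp(-tt / exp(par[2])) + par[3])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(st$A, log(st$tau), st$C), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4 || !all(is.finite(fit$par))) {
      failed <- c(failed, k); next
    }
    cf <- c(A = fit$par[1], tau = exp(fit$par[2]), C = fit$par[3])
    fits[k, ] <- cf
    out[idx] <- out[idx] - cf["A"] * exp(-tt / cf["tau"])
  }
  structure(list(trace = out, valid = valid, fits = fits,
                 failed_pulses = failed),
            class = "artifact_corrected")
}

# crude log-linear starting values for the exponential fit
artifact_start_values <- function(tt, y) {
  C0 <- stats::median(y[tt > max(tt) * 0.75])
  d <- y - C0
  pos <- which(abs(d) > max(abs(d)) * 0.05)
  tau0 <- if (length(pos) > 5) {
    fit <- stats::lm(log(abs(d[pos]) + 1e-9) ~ tt[pos])
    sl <- coef(fit)[2]
    if (is.finite(sl) && sl < -1e-6) -1 / sl else 0.01
  } else 0.01
  tau0 <- min(max(tau0, 1e-3), 0.1)
  A0 <- d[1] / exp(-tt[1] / tau0)
  list(A = as.numeric(A0), tau = tau0, C = as.numeric(C0))
}

#' Peak-to-peak threshold spike detection on one channel
#'
#' Slides a window of `peak_lifetime_ms` over the trace; wherever the
#' peak-to-peak excursion among valid samples exceeds
#' `threshold_multiplier * noise_sd`, the absolute extremum of that window
#' becomes a candidate event (ties resolve to the earlier sample).
#' Candidates closer than the refractory period are merged keeping the
#' earlier one.  Samples flagged invalid (blanking) can neither contribute
#' to the excursion nor carry an event, so no event ever falls inside a
#' blanking window.
#'
#' @param trace voltage vector (microvolts), artifact-corrected.
#' @param noise_sd baseline-noise SD (from [estimate_noise_sd()]).
#' @param params a [detection_params()].
#' @param sampling_rate Hz.
#' @param valid optional logical validity mask (e.g. from
#'   [remove_stim_artifact()]).
#' @param t0 time of the first sample, seconds.
#' @return Numeric vector of spike times, seconds.
#' @export
detect_spikes <- function(trace, noise_sd, params = detection_params(),
                          sampling_rate = 25000, valid = NULL, t0 = 0) {
  stopifnot(inherits(params, "detection_params"), noise_sd > 0)
  if (is.null(valid)) valid <- rep(TRUE, length(trace))
  win <- max(2L, round(params$peak_lifetime_ms / 1000 * sampling_rate))
  refr <- max(1L, round(params$refractory_ms / 1000 * sampling_rate))
  idx <- detect_peaks_cpp(as.numeric(trace), valid, win,
                          params$threshold_multiplier * noise_sd, refr)
  t0 + (idx - 1) / sampling_rate
}

#' Detect spikes on every channel of a raw recording
#'
#' Convenience pipeline per channel: artifact removal (optional), robust
#' noise estimation on the corrected trace, peak-to-peak detection.
#'
#' @param rec a [raw_recording()].
#' @param log optional [stim_log()] supplying pulse times for artifact
#'   removal and blanking.
#' @param params a [detection_params()].
#' @param remove_artifacts subtract exponential artifacts before detection
#'   (default `TRUE` when a log is given).
#' @return A [spike_events()] table.
#' @export
detect_recording <- function(rec, log = NULL, params = detection_params(),
                             remove_artifacts = !is.null(log)) {
  pulses <- if (!is.null(log))
    sort(c(log$p1_time_s, log$p2_time_s)) else numeric(0)
  el <- integer(0); tm <- numeric(0)
  for (ci in seq_along(rec$channel_ids)) {
    x <- rec$samples[, ci]
    valid <- NULL
    if (length(pulses)) {
      if (remove_artifacts) {
        ac <- remove_stim_artifact(x, pulses, rec$sampling_rate,
                                   blanking_s = params$blanking_ms / 1000,
                                   t0 = rec$t0)
        x <- ac$trace; valid <- ac$valid
      } else {
        valid <- blanking_valid_mask(length(x), rec$sampling_rate, pulses,
                                     params$blanking_ms / 1000, rec$t0)
      }
    }
    sdv <- estimate_noise_sd(x, rec$sampling_rate, valid,
                             min_duration_s = min(1, length(x) /
                                                    rec$sampling_rate / 2))
    st <- detect_spikes(x, sdv, params, rec$sampling_rate, valid, rec$t0)
    el <- c(el, rep(rec$channel_ids[ci], length(st)))
    tm <- c(tm, st)
  }
  spike_events(el, tm)
}
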