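# Delimited-text interchange formats.  All tables are tab-separated with a
# header line; times are seconds from recording start (t0 = 0) written with
# microsecond precision so round-trips are lossless at the stated precision.

#' Spike-event tables
#'
#' A spike-event table records detected spikes as (electrode_id,
#' spike_time_s) pairs, sorted by electrode then time.  `spike_events()`
#' constructs and validates one; `read_spike_events()` / `write_spike_events()`
#' exchange the documented tab-separated format (times at 1 microsecond
#' precision).
#'
#' @param electrode_id integer electrode labels.
#' @param spike_time_s spike times in seconds, non-negative.
#' @param layout optional [mea_layout()]; if given, electrode ids must occur
#'   in it.
#' @return A data frame of class `spike_events` with columns `electrode_id`
#'   and `spike_time_s`, sorted by electrode then time.
#' @examples
#' ev <- spike_events(c(12, 12, 21), c(0.5, 0.25, 1))
#' f <- tempfile(fileext = ".tsv")
#' write_spike_events(ev, f)
#' identical(read_spike_events(f), ev)
#' @export
spike_events <- function(electrode_id = integer(0), spike_time_s = numeric(0),
                         layout = NULL) {
  if (length(electrode_id) != length(spike_time_s))
    stop("electrode_id and spike_time_s must have equal length")
  if (anyNA(electrode_id) || anyNA(spike_time_s))
    stop("missing values in spike events")
  if (any(spike_time_s < 0))
    stop("negative spike times")
  if (!is.null(layout) && length(electrode_id) &&
      !all(electrode_id %in% layout$electrode_id))
    stop("unknown electrode ids: ",
         paste(unique(setdiff(electrode_id, layout$electrode_id)), collapse = ", "))
  ord <- order(electrode_id, spike_time_s)
  out <- data.frame(electrode_id = as.integer(electrode_id)[ord],
                    spike_time_s = as.numeric(spike_time_s)[ord])
  class(out) <- c("spike_events", "data.frame")
  out
}

#' @rdname spike_events
#' @param path file path.
#' @export
read_spike_events <- function(path, layout = NULL) {
  tab <- read.delim(path, colClasses = c("integer", "numeric"))
  if (!identical(names(tab), c("electrode_id", "spike_time_s")))
    stop("expected columns electrode_id, spike_time_s; found: ",
         paste(names(tab), collapse = ", "))
  spike_events(tab$electrode_id, tab$spike_time_s, layout = layout)
}

#' @rdname spike_events
#' @param events a `spike_events` table (unsorted input is normalised).
#' @export
write_spike_events <- function(events, path) {
  events <- spike_events(events$electrode_id, events$spike_time_s)
  out <- data.frame(electrode_id = events$electrode_id,
                    spike_time_s = sprintf("%.6f", events$spike_time_s))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stimulation logs
#'
#' A stimulation log records one row per paired-pulse trial: stimulated
#' electrode, trial index, pulse times and pulse parameters.
#' `stim_log()` validates the paired-pulse structure (fixed inter-pulse
#' interval, equal trials per site, minimum wait between pairs).
#'
#' @param site_electrode_id stimulated electrode id per trial.
#' @param trial trial index (1..n_trials within each site).
#' @param p1_time_s,p2_time_s pulse times, seconds; `p2 - p1` must equal
#'   `inter_pulse_s` everywhere.
#' @param amplitude_uA,phase_duration_us pulse amplitude and per-phase
#'   duration (defaults 30 uA, 100 us biphasic).
#' @param inter_pulse_s inter-pulse interval (default 0.050 s).
#' @param min_wait_s minimum wait between consecutive pairs (default 5 s);
#'   set lower for compressed synthetic protocols.
#' @return Data frame of class `stim_log`.
#' @export
stim_log <- function(site_electrode_id, trial, p1_time_s,
                     p2_time_s = p1_time_s + inter_pulse_s,
                     amplitude_uA = 30, phase_duration_us = 100,
                     inter_pulse_s = 0.050, min_wait_s = 5) {
  n <- length(site_electrode_id)
  stopifnot(length(trial) == n, length(p1_time_s) == n, length(p2_time_s) == n)
  if (any(abs((p2_time_s - p1_time_s) - inter_pulse_s) > 1e-9))
    stop("p2_time - p1_time must equal the inter-pulse interval (",
         inter_pulse_s, " s)")
  tt <- table(site_electrode_id)
  if (length(unique(tt)) > 1)
    stop("unequal number of trials per stimulation site")
  ord <- order(p1_time_s)
  gaps <- diff(p1_time_s[ord])
  if (any(gaps < min_wait_s - 1e-9))
    stop("inter-pair wait below the configured minimum of ", min_wait_s, " s")
  out <- data.frame(site_electrode_id = as.integer(site_electrode_id),
                    trial = as.integer(trial),
                    p1_time_s = as.numeric(p1_time_s),
                    p2_time_s = as.numeric(p2_time_s),
                    amplitude_uA = rep_len(amplitude_uA, n),
                    phase_duration_us = rep_len(phase_duration_us, n))[ord, ]
  rownames(out) <- NULL
  attr(out, "inter_pulse_s") <- inter_pulse_s
  attr(out, "min_wait_s") <- min_wait_s
  class(out) <- c("stim_log", "data.frame")
  out
}

#' @rdname stim_log
#' @param path file path.
#' @export
read_stim_log <- function(path, min_wait_s = NULL) {
  tab <- read.delim(path)
  need <- c("site_electrode_id", "trial", "p1_time_s", "p2_time_s",
            "amplitude_uA", "phase_duration_us")
  if (!all(need %in% names(tab)))
    stop("stimulation log missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  ipi <- round(stats::median(tab$p2_time_s - tab$p1_time_s), 6)
  stim_log(tab$site_electrode_id, tab$trial, tab$p1_time_s, tab$p2_time_s,
           tab$amplitude_uA, tab$phase_duration_us, inter_pulse_s = ipi,
           min_wait_s = min_wait_s %||% 0)
}

#' @rdname stim_log
#' @param log a `stim_log` data frame.
#' @export
write_stim_log <- function(log, path) {
  out <- log
  out$p1_time_s <- sprintf("%.6f", out$p1_time_s)
  out$p2_time_s <- sprintf("%.6f", out$p2_time_s)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname mea_layout
#' @param path file path for the tab-separated layout description.
#' @export
read_layout <- function(path) {
  tab <- read.delim(path)
  lay <- tab[order(tab$electrode_id), ]
  rownames(lay) <- NULL
  class(lay) <- c("mea_layout", "data.frame")
  v <- validate_layout(lay)
  if (length(v)) warning("layout violations: ", paste(v, collapse = "; "))
  lay
}

#' @rdname mea_layout
#' @param layout the layout to write.
#' @export
write_layout <- function(layout, path) {
  write.table(as.data.frame(layout), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Raw multi-channel recordings
#'
#' A raw recording holds per-channel extracellular voltage (microvolts) at a
#' fixed sampling rate.  `raw_recording()` wraps a samples matrix; the
#' read/write pair exchanges a simple chunked binary container (magic header,
#' little-endian metadata, float32 samples in channel-major chunks).
#'
#' @param samples numeric matrix, samples x channels, microvolts.
#' @param sampling_rate sampling frequency in Hz (default 25000).
#' @param t0 time of the first sample, seconds (default 0).
#' @param channel_ids electrode ids of the columns.
#' @return List of class `raw_recording`.
#' @export
raw_recording <- function(samples, sampling_rate = 25000, t0 = 0,
                          channel_ids = NULL) {
  samples <- as.matrix(samples)
  stopifnot(sampling_rate > 0)
  channel_ids <- as.integer(channel_ids %||% seq_len(ncol(samples)))
  stopifnot(length(channel_ids) == ncol(samples))
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 t0 = t0, channel_ids = channel_ids),
            class = "raw_recording")
}

#' @rdname raw_recording
#' @param path file path for the binary container.
#' @export
write_raw_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MEARAW1\n", con, eos = NULL)
  writeBin(as.numeric(c(nrow(rec$samples), ncol(rec$samples))), con,
           size = 8, endian = "little")
  writeBin(c(rec$sampling_rate, rec$t0), con, size = 8, endian = "little")
  writeBin(as.integer(rec$channel_ids), con, size = 4, endian = "little")
  for (j in seq_len(ncol(rec$samples)))
    writeBin(as.numeric(rec$samples[, j]), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname raw_recording
#' @param rec a `raw_recording`.
#' @export
read_raw_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, "MEARAW1\n")) stop("not a MEARAW1 container")
  dims <- readBin(con, "double", 2, size = 8, endian = "little")
  meta <- readBin(con, "double", 2, size = 8, endian = "little")
  ids <- readBin(con, "integer", dims[2], size = 4, endian = "little")
  x <- matrix(NA_real_, dims[1], dims[2])
  for (j in seq_len(dims[2]))
    x[, j] <- readBin(con, "double", dims[1], size = 4, endian = "little")
  raw_recording(x, sampling_rate = meta[1], t0 = meta[2], channel_ids = ids)
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d spikes on %d electrodes", nrow(x),
              length(unique(x$electrode_id))))
  if (nrow(x)) cat(sprintf(", t in [%.3f, %.3f] s", min(x$spike_time_s),
                           max(x$spike_time_s)))
  cat("\n")
  invisible(x)
}

#' @export
print.stim_log <- function(x, ...) {
  cat(sprintf("<stim_log> %d paired pulses: %d sites x %d trials\n",
              nrow(x), length(unique(x$site_electrode_id)),
              max(x$trial)))
  invisible(x)
}
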