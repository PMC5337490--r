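# Independent brute-force reimplementations used as oracles.  These are
# written directly from the defining formulas with plain loops and share no
# code with the package internals.

# regional uniqueness %U(n) for n = 1..Ne, literal translation of the
# adjacency / uniqueness-index / regional-average definitions
oracle_uniqueness_curve <- function(sr, zero_policy) {
  n_stim <- nrow(sr)
  n_e <- ncol(sr)
  pct <- numeric(n_e)
  for (n in seq_len(n_e)) {
    A <- matrix(0, n_stim, n_e)
    for (j in seq_len(n_stim)) {
      v <- sr[j, ]
      ok <- which(!is.na(v))
      if (zero_policy == "exclude_zeros") ok <- ok[v[ok] > 0]
      if (!length(ok)) next
      vals <- sort(v[ok], decreasing = TRUE)
      nth <- vals[min(n, length(vals))]
      for (i in ok) if (v[i] >= nth) A[j, i] <- 1
    }
    u <- numeric(n_e)
    for (i in seq_len(n_e)) {
      s <- sum(A[, i])
      u[i] <- if (s == 0) 0 else 1 - (s - 1) / (n_stim - 1)
    }
    pct[n] <- sum(u) / n_e * 100
  }
  pct
}

# rate matrix by direct interval-membership recount from raw events
oracle_rate_matrix <- function(events, log, sites, electrodes,
                               window_s = 0.040, blank_s = 0.005) {
  sr <- matrix(0, length(sites), length(electrodes),
               dimnames = list(sites, electrodes))
  nt <- max(log$trial)
  for (j in seq_along(sites)) {
    rows <- which(log$site_electrode_id == sites[j])
    for (i in seq_along(electrodes)) {
      if (electrodes[i] == sites[j]) { sr[j, i] <- NA; next }
      tot <- 0
      for (r in rows) {
        for (p in c(log$p1_time_s[r], log$p2_time_s[r])) {
          tt <- events$spike_time_s[events$electrode_id == electrodes[i]]
          tot <- tot + sum(tt >= p + blank_s & tt < p + blank_s + window_s)
        }
      }
      sr[j, i] <- tot / (nt * 2 * window_s)
    }
  }
  sr
}

# random rate matrix with ties and zeros (rounding forces ties)
random_tied_matrix <- function(n_sites, n_e, zero_frac = 0.3) {
  v <- round(stats::rexp(n_sites * n_e, 1 / 10), 0)
  v[stats::runif(n_sites * n_e) < zero_frac] <- 0
  matrix(v, n_sites, n_e)
}
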