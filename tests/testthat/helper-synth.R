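# compact study configurations used across tests (small protocols, short
# waits, short spontaneous segment: fast to simulate, same structure)
small_cfg <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_sites_per_region = 4, n_trials = 5,
                   sparseness_m = 2, wait_s = 0.5, protocol_start_s = 2,
                   spont_duration_s = 2)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# minimal single-site log for window-level tests
one_site_log <- function(p1 = c(10, 15), site = 26L) {
  stim_log(rep(site, length(p1)), seq_along(p1), p1, min_wait_s = 1)
}
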