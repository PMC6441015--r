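# Shared fixtures: every test input is generated in code at run time.

# Degradation parameters with every stochastic corruption switched off;
# individual rates can be switched back on via ...
zero_noise_params <- function(...) {
  args <- list(p_stay0 = 0, p_skip0 = 0, p_sub0 = 0, p_ins0 = 0,
               c_stay = 0, c_skip = 0, c_err = 0, drift_pA_per_gray = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(degradation_params, args)
}

# Desk-scale run configuration: full flow-cell geometry, reduced read rate
# and fragment length so suites stay fast.
tiny_config <- function(rate = 0.3, hours = 1, frag_mean = 400,
                        frag_sd = 0.3, barcodes = NULL, seed = 1) {
  run_config(run_hours = hours,
             mean_reads_per_active_channel_per_hour = rate,
             fragment_length_log_mean = log(frag_mean),
             fragment_length_log_sd = frag_sd,
             barcodes = barcodes, seed = seed)
}

# Event table from a bare move vector (for hand-computed metric checks).
events_from_moves <- function(moves, k = 5) {
  data.frame(mean_pA = rep(100, length(moves)),
             start_s = seq_along(moves) / 10,
             dur_s = rep(0.1, length(moves)),
             move = as.integer(moves),
             kmer = rep(strrep("A", k), length(moves)))
}

pooled_event_fractions <- function(per_read) {
  n_dec <- sum(per_read$n_events - 1L)
  list(stay = sum(per_read$n_stays) / n_dec,
       skip = sum(per_read$n_skips) / n_dec,
       n = n_dec)
}
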