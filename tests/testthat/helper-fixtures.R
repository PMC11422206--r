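# Shared fixtures: small protocols and recordings built in code.

# short protocol for fast unit tests (one cycle)
mini_schedule <- function() {
  build_schedule(baseline_s = 120, occlusion_s = 120,
                 reperfusion_s = 240, cuff_ramp_s = 6)
}

# fast kinetics matching the mini schedule
mini_params <- function(...) {
  args <- list(tau_deoxy = 30, tau_reoxy = 8, t_peak = 20,
               noise_sd = 0, drift_slope = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

mini_baseline_window <- c(20, 100)

# a recording whose channels all carry the same injected signal
signal_recording <- function(y, fs = 10) {
  tt <- seq(0, by = 1 / fs, length.out = length(y))
  nirs_recording(tt, y, y, y, sampling_rate = fs)
}

# noiseless extraction pipeline for a simulated session (no filter: isolates
# the measurement operators from filter edge effects)
extract_noiseless <- function(sim, schedule, window = mini_baseline_window) {
  rec <- normalize_to_baseline(sim$recording, window)
  extract_cycle_features(rec, schedule)
}
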