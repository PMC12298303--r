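# Shared fixtures, built in code at test time.

# a recording holding a pure sine, long enough to ignore filter edge effects
sine_recording <- function(freq_hz, rate = 8, duration_s = 60, amp = 1,
                           offset = 0) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  eda_recording(offset + amp * sin(2 * pi * freq_hz * t), rate = rate)
}

# write a two-column EDA CSV and return its path
write_eda_fixture <- function(time_s, eda_us) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = time_s, eda_us = eda_us), path,
                   row.names = FALSE)
  path
}

# phasic trace with Bateman pulses at given onset times (seconds)
pulse_phasic <- function(onsets_s, amps, n = 1440, rate = 8,
                         p = bateman_params()) {
  drv <- numeric(n)
  idx <- floor(onsets_s * rate) + 1L
  drv[idx] <- amps
  kern <- bateman_kernel(p, rate = rate)
  edadecomp:::convolve_truncated(drv, kern, n)
}

# time of the Bateman kernel peak after an event onset
bateman_peak_time <- function(p = bateman_params()) {
  (p$tau_rise * p$tau_decay / (p$tau_decay - p$tau_rise)) *
    log(p$tau_decay / p$tau_rise)
}

# small transformer configuration for fast unit tests (16 s frames at 8 Hz)
tiny_model_config <- function(...) {
  model_config(embed_dim = 8, ff_dim = 4, n_heads = 2, pool_kernel = 33,
               frame_len = 128, decomp_kernel = 9, ...)
}

tiny_sim_config <- function(seed, ...) {
  sim_config(duration = 16, seed = seed, ...)
}
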