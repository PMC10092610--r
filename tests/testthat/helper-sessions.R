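# small session configs used across tests: full montage, scaled trial
# counts and inter-stimulus interval so a session is a few seconds long
tiny_config <- function(seed = 1, ...) {
  session_config(seed = seed, n_rats = 2, n_trials_per_rat = 5,
                 inter_stimulus_interval = 2, ...)
}

# config with everything off except what the caller turns on
silent_gains <- c(delta = 0, theta = 0, sigma = 0, beta = 0, gamma = 0)

quiet_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_rats = 2, n_trials_per_rat = 5,
                   inter_stimulus_interval = 2,
                   background_gains = silent_gains, pink_gain = 0,
                   evoked_amplitude = 0, induced_gain_beta = 0,
                   induced_gain_gamma = 0, broadband_noise_gain = 0)
  defaults[names(args)] <- args
  do.call(session_config, defaults)
}

gains_only <- function(band, value = 1) {
  g <- silent_gains
  g[band] <- value
  g
}

fft_freqs_for_test <- function(n, fs) ctcgamma:::fft_freqs(n, fs)
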