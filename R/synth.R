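#' Session configuration for the synthetic LFP generator
#'
#' Describes one recording session of the paired-design experiment the
#' pipeline analyses: a pentobarbital-sedated rat receiving one vibrissa
#' stimulation every `inter_stimulus_interval` seconds, `n_trials_per_rat`
#' trials in each of `n_rats` animals (trials are pooled; "rat" exists
#' only as trial grouping). Each of the four channels (EEG, L6, VPm, PoM)
#' is a sum of phenomenological components:
#'
#' * 1/f (pink) background, amplitude `pink_gain`;
#' * a delta sinusoid (2 Hz, random phase per channel),
#'   amplitude set by `background_gains["delta"]`;
#' * intermittent sigma spindles (10-16 Hz noise under a waxing/waning
#'   envelope), amplitude `background_gains["sigma"]`;
#' * ongoing theta, beta and gamma band-limited noise. Beta and gamma use
#'   narrowband carriers (20-26 and 38-48 Hz) inside the analysis bands,
#'   modelling oscillations with a finite linewidth rather than
#'   band-filling noise -- this is what lets broadband noise move the
#'   band-limited entropy, as in real signals;
#' * the L6 and VPm gamma carriers are a linear mix of one shared source
#'   and private sources, `shared_gamma_mix` in \[0,1\] setting the shared
#'   fraction (this is the sole knob behind L6-VPm gamma coherence);
#' * white noise, amplitude `broadband_noise_gain` (scalar, or named per
#'   channel);
#' * at every stimulus onset a phase-locked evoked transient (identical
#'   every trial, confined to 0-150 ms so it never touches the late
#'   window), amplitude `evoked_amplitude`;
#' * in the 200-700 ms late window only, a random-phase band-limited
#'   beta/gamma burst, power scaled by `induced_gain_beta` /
#'   `induced_gain_gamma` (1 = the canonical saline burst power; gamma
#'   bursts at L6/VPm share a common trial source with the same
#'   `shared_gamma_mix`).
#'
#' @param condition_label `"saline"` or `"ketamine"` (a label only).
#' @param sampling_rate Hz; default 1000 (lossless for the 80 Hz analysis
#'   ceiling; acquisition-grade 20 kHz is supported).
#' @param n_trials_per_rat,n_rats trial structure; defaults 10 and 4
#'   giving the canonical 40 paired trials.
#' @param inter_stimulus_interval s between stimuli; default 15.
#' @param background_gains named amplitude (SD) scalars for
#'   delta/theta/sigma/beta/gamma ongoing components.
#' @param pink_gain amplitude of the 1/f background.
#' @param evoked_amplitude peak amplitude of the evoked kernel.
#' @param induced_gain_beta,induced_gain_gamma dimensionless power
#'   multipliers on the late-window induced bursts.
#' @param shared_gamma_mix fraction in \[0,1\] of L6/VPm gamma drawn from
#'   the common source.
#' @param broadband_noise_gain white-noise amplitude; scalar or named
#'   vector over channels.
#' @param high_gamma_noise_gain amplitude of a fast (55-85 Hz)
#'   band-limited noise component; scalar or named vector over channels.
#'   0 in the saline default; the ketamine condition raises it at L6 and
#'   VPm, modelling the diffusely amplified broadband-gamma noise that
#'   drives the entropy increase in the corticothalamic loop.
#' @param seed integer RNG seed; the generator is fully deterministic
#'   given `(config, seed)`.
#' @return object of class `"session_config"`.
#' @export
session_config <- function(condition_label = "saline",
                           sampling_rate = 1000,
                           n_trials_per_rat = 10,
                           n_rats = 4,
                           inter_stimulus_interval = 15,
                           background_gains = c(delta = 4, theta = 1,
                                                sigma = 1.5, beta = 1,
                                                gamma = 1),
                           pink_gain = 1,
                           evoked_amplitude = 8,
                           induced_gain_beta = 1,
                           induced_gain_gamma = 1,
                           shared_gamma_mix = 0.8,
                           broadband_noise_gain = 1,
                           high_gamma_noise_gain = 0,
                           seed = 1) {
  chans <- c("EEG", "L6", "VPm", "PoM")
  need <- c("delta", "theta", "sigma", "beta", "gamma")
  stopifnot(all(need %in% names(background_gains)))
  if (any(background_gains < 0) || pink_gain < 0 || evoked_amplitude < 0 ||
      induced_gain_beta < 0 || induced_gain_gamma < 0 ||
      any(broadband_noise_gain < 0) || any(high_gamma_noise_gain < 0)) {
    stop("all gains must be >= 0", call. = FALSE)
  }
  if (shared_gamma_mix < 0 || shared_gamma_mix > 1) {
    stop("shared_gamma_mix must lie in [0, 1]", call. = FALSE)
  }
  if (inter_stimulus_interval < 1.2) {
    stop("inter_stimulus_interval must cover the -0.5..0.7 s analysis span",
         call. = FALSE)
  }
  per_channel <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, 4L), chans)
    }
    stopifnot(all(chans %in% names(x)))
    x[chans]
  }
  noise <- per_channel(broadband_noise_gain)
  hg_noise <- per_channel(high_gamma_noise_gain)
  structure(
    list(condition_label = condition_label,
         sampling_rate = sampling_rate,
         n_trials_per_rat = n_trials_per_rat,
         n_rats = n_rats,
         inter_stimulus_interval = inter_stimulus_interval,
         background_gains = background_gains[need],
         pink_gain = pink_gain,
         evoked_amplitude = evoked_amplitude,
         induced_gain_beta = induced_gain_beta,
         induced_gain_gamma = induced_gain_gamma,
         shared_gamma_mix = shared_gamma_mix,
         broadband_noise_gain = noise,
         high_gamma_noise_gain = hg_noise,
         seed = as.integer(seed)),
    class = "session_config"
  )
}

#' Canonical ketamine counterpart of a saline configuration
#'
#' Applies the condition contrast as power multipliers: ongoing beta/gamma
#' power x2 (amplitude x sqrt(2)), induced burst power x0.5, shared gamma
#' mix 0.8 -> 0.4, and fast (55-85 Hz) band-limited noise injected
#' specifically into the L6-VPm loop, which is what elevates gamma-band
#' entropy in L6 and VPm but not PoM (no injection there) while leaving
#' beta-band entropy and the narrowband gamma carrier untouched.
#'
#' @param saline_cfg a saline [session_config()].
#' @param baseline_power_gain multiplier on ongoing beta/gamma power.
#' @param induced_power_gain multiplier on induced burst power.
#' @param shared_gamma_mix replacement mix value.
#' @param high_gamma_noise named per-channel amplitudes of the injected
#'   fast-noise component.
#' @return a ketamine [session_config()].
#' @export
ketamine_config <- function(saline_cfg,
                            baseline_power_gain = 2,
                            induced_power_gain = 0.5,
                            shared_gamma_mix = 0.4,
                            high_gamma_noise = c(EEG = 0, L6 = 0.75,
                                                 VPm = 0.75, PoM = 0)) {
  stopifnot(inherits(saline_cfg, "session_config"))
  cfg <- saline_cfg
  cfg$condition_label <- "ketamine"
  cfg$background_gains[c("beta", "gamma")] <-
    cfg$background_gains[c("beta", "gamma")] * sqrt(baseline_power_gain)
  cfg$induced_gain_beta <- cfg$induced_gain_beta * induced_power_gain
  cfg$induced_gain_gamma <- cfg$induced_gain_gamma * induced_power_gain
  cfg$shared_gamma_mix <- shared_gamma_mix
  cfg$high_gamma_noise_gain <-
    cfg$high_gamma_noise_gain +
    high_gamma_noise[names(cfg$high_gamma_noise_gain)]
  cfg
}

# narrowband carriers of the ongoing/induced oscillation sources (Hz);
# deliberately narrower than the analysis bands (finite linewidth)
.beta_carrier <- c(20, 26)
.gamma_carrier <- c(38, 48)
# canonical induced burst amplitudes (SD, pre-taper) at gain 1
.induced_base <- c(beta = 1.5, gamma = 1.8)

#' Unit-variance band-limited Gaussian noise
#'
#' White Gaussian noise spectrally shaped to occupy `[low, high]` Hz
#' (raised-cosine transitions of width `transition`), scaled to unit
#' variance *in expectation* (the realized variance of any finite draw
#' fluctuates naturally, as it should for short bursts).
#' Consumes `n` normal deviates from the current RNG stream.
#'
#' @param n length in samples.
#' @param low,high band edges (Hz).
#' @param sampling_rate Hz.
#' @param transition transition width (Hz).
#' @return numeric series of length `n` with expected SD 1.
#' @export
band_limited_noise <- function(n, low, high, sampling_rate, transition = 1) {
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  h <- raised_cosine_response(abs(fft_freqs(m, sampling_rate)), low, high,
                              transition)
  y <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / m
  # Var(y_j) = sum(h^2) / m for unit-variance white input
  s <- sqrt(sum(h^2) / m)
  if (s > 0) y[seq_len(n)] / s else y[seq_len(n)]
}

#' Unit-variance 1/f (pink) noise
#'
#' White Gaussian noise with its amplitude spectrum scaled by
#' `1/sqrt(f)` (flat below 0.5 Hz), rescaled to unit SD.
#'
#' @inheritParams band_limited_noise
#' @return numeric series of length `n`, SD 1.
#' @export
pink_noise <- function(n, sampling_rate = 1000) {
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  f <- abs(fft_freqs(m, sampling_rate))
  h <- 1 / sqrt(pmax(f, 0.5))
  y <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

# waxing/waning spindle envelope: Hanning bumps of `dur` s at random
# intervals (uniform gap_range s between bump ends and next starts)
spindle_envelope <- function(n, sampling_rate, dur = 0.7, gap_range = c(1.5, 4)) {
  env <- numeric(n)
  bump_len <- max(2L, round(dur * sampling_rate))
  bump <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = bump_len)))
  pos <- 1L + round(stats::runif(1, 0, gap_range[2]) * sampling_rate)
  while (pos + bump_len <= n) {
    env[seq.int(pos, pos + bump_len - 1L)] <- bump
    gap <- stats::runif(1, gap_range[1], gap_range[2])
    pos <- pos + bump_len + round(gap * sampling_rate)
  }
  env
}

# phase-locked evoked kernel: 40 Hz carrier under a Gaussian envelope
# (centre 50 ms, SD 20 ms), support clipped to 0-150 ms so it is over
# well before the 200 ms start of the late window
evoked_kernel <- function(amplitude, sampling_rate) {
  t <- seq(0, 0.15, by = 1 / sampling_rate)
  amplitude * exp(-((t - 0.05) / 0.02)^2 / 2) * sin(2 * pi * 40 * t)
}

# Tukey (tapered-cosine) window, taper fraction r at each end
tukey_taper <- function(n, r = 0.25) {
  w <- rep(1, n)
  edge <- floor(r * n)
  if (edge > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(edge) / edge))
    w[seq_len(edge)] <- ramp
    w[seq.int(n - edge + 1L, n)] <- rev(ramp)
  }
  w
}

#' Generate one synthetic session
#'
#' Builds the continuous four-channel recording and its stimulus train
#' from a [session_config()]. Fully deterministic given the config (the
#' seed lives in the config). Stimuli start after a 2 s lead-in and the
#' recording extends 1.5 s past the last onset, so every baseline and
#' late window fits.
#'
#' @param config a [session_config()].
#' @return list with elements `recording` (a [recording()]) and `stims`
#'   (a [stim_train()]).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$sampling_rate
  n_stim <- config$n_rats * config$n_trials_per_rat
  lead <- 2
  onsets <- lead + (seq_len(n_stim) - 1L) * config$inter_stimulus_interval
  dur <- onsets[n_stim] + 1.5
  n <- round(dur * fs)
  chans <- c("EEG", "L6", "VPm", "PoM")
  g <- config$background_gains
  mix <- config$shared_gamma_mix
  mix_norm <- sqrt(mix^2 + (1 - mix)^2)
  if (mix_norm == 0) mix_norm <- 1

  set.seed(config$seed)

  # shared ongoing gamma source (L6/VPm)
  gamma_common <- band_limited_noise(n, .gamma_carrier[1], .gamma_carrier[2], fs)

  data <- matrix(0, nrow = 4L, ncol = n, dimnames = list(chans, NULL))
  t_grid <- (seq_len(n) - 1L) / fs
  kernel <- evoked_kernel(config$evoked_amplitude, fs)
  on_samp <- round(onsets * fs)   # 0-based onset samples

  for (ch in chans) {
    x <- config$pink_gain * pink_noise(n, fs)
    x <- x + g[["delta"]] * sqrt(2) * sin(2 * pi * 2 * t_grid +
                                          stats::runif(1, 0, 2 * pi))
    x <- x + g[["theta"]] * band_limited_noise(n, 5, 9, fs)
    x <- x + g[["sigma"]] * spindle_envelope(n, fs) *
      band_limited_noise(n, 10, 16, fs)
    x <- x + g[["beta"]] * band_limited_noise(n, .beta_carrier[1],
                                              .beta_carrier[2], fs)
    gamma_priv <- band_limited_noise(n, .gamma_carrier[1], .gamma_carrier[2], fs)
    if (ch %in% c("L6", "VPm")) {
      x <- x + g[["gamma"]] * (mix * gamma_common + (1 - mix) * gamma_priv) /
        mix_norm
    } else {
      x <- x + g[["gamma"]] * gamma_priv
    }
    x <- x + config$broadband_noise_gain[[ch]] * stats::rnorm(n)
    if (config$high_gamma_noise_gain[[ch]] > 0) {
      x <- x + config$high_gamma_noise_gain[[ch]] *
        band_limited_noise(n, 55, 85, fs)
    }
    # phase-locked evoked transient, identical every trial
    if (config$evoked_amplitude > 0) {
      for (s0 in on_samp) {
        idx <- s0 + seq_along(kernel)
        keep <- idx <= n
        x[idx[keep]] <- x[idx[keep]] + kernel[keep]
      }
    }
    data[ch, ] <- x
  }

  # random-phase induced bursts, 200-700 ms post-stimulus only
  # near-rectangular burst envelope: a 10 ms cosine ramp at each edge
  # avoids onset clicks while keeping the burst statistically stationary
  # across the window, so saline and ketamine epochs differ only in
  # component variances, not temporal structure
  burst_len <- round(0.5 * fs)
  taper <- tukey_taper(burst_len, 0.02)
  amp_beta <- .induced_base[["beta"]] * sqrt(config$induced_gain_beta)
  amp_gamma <- .induced_base[["gamma"]] * sqrt(config$induced_gain_gamma)
  if (amp_beta > 0 || amp_gamma > 0) {
    for (k in seq_len(n_stim)) {
      idx <- on_samp[k] + round(0.2 * fs) + seq_len(burst_len)
      gamma_burst_common <- band_limited_noise(burst_len, .gamma_carrier[1],
                                               .gamma_carrier[2], fs)
      for (ch in chans) {
        b <- amp_beta * taper *
          band_limited_noise(burst_len, .beta_carrier[1], .beta_carrier[2], fs)
        gpriv <- band_limited_noise(burst_len, .gamma_carrier[1],
                                    .gamma_carrier[2], fs)
        gsrc <- if (ch %in% c("L6", "VPm")) {
          (mix * gamma_burst_common + (1 - mix) * gpriv) / mix_norm
        } else {
          gpriv
        }
        data[ch, idx] <- data[ch, idx] + b + amp_gamma * taper * gsrc
      }
    }
  }

  list(recording = recording(data, fs, config$condition_label),
       stims = stim_train(onsets))
}

#' Generate a paired saline/ketamine session pair
#'
#' Trial i of the ketamine session is paired with trial i of the saline
#' session (same rat index), mirroring the within-animal repeated-measures
#' design. RNG policy: the saline session uses `saline_cfg$seed` and the
#' ketamine session uses `ketamine_cfg$seed + 499979`, so the two
#' conditions are independent draws even when the configs are identical.
#'
#' @param saline_cfg,ketamine_cfg [session_config()]s sharing sampling
#'   rate and trial structure. `ketamine_cfg` defaults to
#'   [ketamine_config()] of `saline_cfg`.
#' @return object of class `"condition_pair"`: list with `saline` and
#'   `ketamine`, each a `generate_session()` result.
#' @export
generate_condition_pair <- function(saline_cfg,
                                    ketamine_cfg = ketamine_config(saline_cfg)) {
  same <- function(f) identical(saline_cfg[[f]], ketamine_cfg[[f]])
  if (!same("sampling_rate") || !same("n_trials_per_rat") || !same("n_rats") ||
      !same("inter_stimulus_interval")) {
    stop("saline and ketamine configs must share sampling rate and trial structure",
         call. = FALSE)
  }
  kcfg <- ketamine_cfg
  kcfg$seed <- as.integer((kcfg$seed + 499979) %% .Machine$integer.max)
  structure(
    list(saline = generate_session(saline_cfg),
         ketamine = generate_session(kcfg)),
    class = "condition_pair"
  )
}

#' Read a session configuration from a YAML or JSON file
#'
#' The file holds any subset of [session_config()]'s arguments by name
#' (unknown names are rejected); missing arguments keep their defaults.
#' Format is chosen by extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path file path.
#' @return a [session_config()].
#' @export
read_session_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  args <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  )
  known <- names(formals(session_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (f in c("background_gains", "broadband_noise_gain",
              "high_gamma_noise_gain")) {
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  }
  do.call(session_config, args)
}
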