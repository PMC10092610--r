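#' Zero-phase band-pass filter
#'
#' Filters a real series into a frequency band with exactly zero phase
#' shift, preserving length. The filter is applied in the frequency
#' domain: the series is reflection-padded at both ends (to suppress
#' circular wrap-around), transformed, multiplied by a real transfer
#' function that is 1 inside the band and rolls off through a
#' raised-cosine transition of width `transition` Hz centred on each band
#' edge, and transformed back. Zero phase matters here because the
#' analysis windows (baseline -500-0 ms, late 200-700 ms) are defined in
#' absolute post-stimulus time and a causal filter would shift energy
#' across their boundaries.
#'
#' @param x numeric series.
#' @param band a [band()] or canonical band name.
#' @param sampling_rate Hz.
#' @param transition transition band width (Hz) of the raised-cosine
#'   roll-off at each edge; default 2 Hz.
#' @return filtered series, same length as `x`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 1, by = 1 / fs)
#' x <- sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t)
#' y <- bandpass(x, "gamma", fs)  # keeps the 50 Hz component
#' @export
bandpass <- function(x, band, sampling_rate, transition = 2) {
  band <- as_band(band)
  check_band_vs_fs(band, sampling_rate)
  n <- length(x)
  if (n < ceiling(sampling_rate / band$low)) {
    stop(sprintf(
      "series too short (%d samples) for the %s band: need at least one cycle of %g Hz",
      n, band$name, band$low), call. = FALSE)
  }
  if (all(x == 0)) return(x)
  # reflect-pad by up to one series length (capped at 2 s) on each side
  pad <- min(n, ceiling(2 * sampling_rate))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
  np <- length(xp)
  freqs <- fft_freqs(np, sampling_rate)
  h <- raised_cosine_response(abs(freqs), band$low, band$high, transition)
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / np
  y[seq.int(pad + 1L, pad + n)]
}

# full (two-sided) FFT frequency grid, negative frequencies included
fft_freqs <- function(n, sampling_rate) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * sampling_rate / n
}

# amplitude response: 1 in [low, high], raised-cosine over [low - tw, low]
# and [high, high + tw], 0 outside
raised_cosine_response <- function(f, low, high, tw) {
  h <- numeric(length(f))
  h[f >= low & f <= high] <- 1
  lo_t <- f >= low - tw & f < low
  h[lo_t] <- 0.5 * (1 + cos(pi * (low - f[lo_t]) / tw))
  hi_t <- f > high & f <= high + tw
  h[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - high) / tw))
  h
}

#' Analysis windows
#'
#' Baseline is the 500 ms before each stimulus; the late window is the
#' 200-700 ms post-stimulus period where induced (non-phase-locked)
#' oscillations are measured. Both last 500 ms, so their single-segment
#' spectra share the same 2 Hz bin grid.
#'
#' @return numeric length-2 vector `(start, end)` in seconds relative to
#'   stimulus onset.
#' @export
baseline_window <- function() c(-0.5, 0)

#' @rdname baseline_window
#' @export
late_window <- function() c(0.2, 0.7)

#' Extract per-trial epochs around stimulus onsets
#'
#' Cuts one row per stimulus from a channel of a continuous recording.
#' Sample convention: samples are 0-based, onset time `t` maps to sample
#' `round(t * fs)`, and a window `(a, b)` takes the half-open sample range
#' `[round((t + a) * fs), round((t + b) * fs))`, so a 500 ms window at
#' 1 kHz is exactly 500 samples. Epoching performs no resampling,
#' filtering or detrending; any onset whose window falls outside the
#' recording aborts the whole extraction (trials are never dropped
#' silently).
#'
#' @param rec a [recording()].
#' @param train a [stim_train()].
#' @param channel channel name.
#' @param window length-2 numeric `(start, end)` in s relative to onset,
#'   e.g. [baseline_window()] or [late_window()].
#' @return object of class `"epoch_set"`: list with `trials` (trial x time
#'   matrix), `channel`, `condition_label`, `window`, `window_label`,
#'   `sampling_rate`.
#' @export
extract_epochs <- function(rec, train, channel, window) {
  stopifnot(inherits(rec, "recording"), inherits(train, "stim_train"),
            length(window) == 2L, window[2] > window[1])
  x <- get_channel(rec, channel)
  fs <- rec$sampling_rate
  n <- length(x)
  start_s <- round((train$onsets + window[1]) * fs)
  end_s <- round((train$onsets + window[2]) * fs)   # exclusive
  if (any(start_s < 0) || any(end_s > n)) {
    bad <- which(start_s < 0 | end_s > n)
    stop(sprintf("onset(s) %s have windows outside the recording; aborting (no silent trial dropping)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  len <- unique(end_s - start_s)
  stopifnot(length(len) == 1L)
  trials <- t(vapply(start_s,
                     function(s0) x[seq.int(s0 + 1L, s0 + len)],
                     numeric(len)))
  wl <- if (isTRUE(all.equal(window, baseline_window()))) "baseline"
        else if (isTRUE(all.equal(window, late_window()))) "late"
        else "custom"
  structure(
    list(trials = trials, channel = channel,
         condition_label = rec$condition_label,
         window = window, window_label = wl, sampling_rate = fs),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s/%s %s: %d trials x %d samples @ %g Hz\n",
              x$channel, x$condition_label, x$window_label,
              nrow(x$trials), ncol(x$trials), x$sampling_rate))
  invisible(x)
}

n_trials <- function(epochs) nrow(epochs$trials)
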