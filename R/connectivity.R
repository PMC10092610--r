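#' Magnitude-squared coherence (Welch estimator)
#'
#' `C(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))` with cross- and auto-spectra
#' averaged over Hamming-tapered segments. Defaults follow the common
#' engineering convention for this estimator: the series is divided into
#' 8 segments with 50% overlap. A single segment is rejected (coherence
#' would be identically 1).
#'
#' @param x,y equal-length numeric series.
#' @param sampling_rate Hz.
#' @param n_segments number of segments (>= 2).
#' @param overlap_frac fractional overlap between consecutive segments,
#'   in `[0, 1)`; default 0.5.
#' @return object of class `"coherence_spectrum"`: list with
#'   `frequencies` (the estimator's own grid, set by the segment length)
#'   and `coherence` in `[0, 1]`.
#' @export
ms_coherence <- function(x, y, sampling_rate, n_segments = 8,
                         overlap_frac = 0.5) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n_segments < 2) {
    stop("n_segments must be >= 2 (single-segment coherence is identically 1)",
         call. = FALSE)
  }
  n <- length(x)
  seg_len <- floor(n / ((n_segments - 1) * (1 - overlap_frac) + 1))
  if (seg_len < 8) stop("series too short for the requested segmentation", call. = FALSE)
  step <- max(1L, floor(seg_len * (1 - overlap_frac)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hamming_window(seg_len)
  half <- floor(seg_len / 2)
  Sxx <- Syy <- numeric(half + 1L)
  Sxy <- complex(real = numeric(half + 1L), imaginary = numeric(half + 1L))
  for (s0 in starts) {
    idx <- seq.int(s0, s0 + seg_len - 1L)
    X <- stats::fft(w * x[idx])[seq_len(half + 1L)]
    Y <- stats::fft(w * y[idx])[seq_len(half + 1L)]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  denom <- Sxx * Syy
  coh <- ifelse(denom > 0, Mod(Sxy)^2 / denom, 0)
  structure(
    list(frequencies = (0:half) * sampling_rate / seg_len,
         coherence = pmin(pmax(coh, 0), 1),
         n_segments = length(starts), segment_length = seg_len),
    class = "coherence_spectrum"
  )
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d bins to %g Hz (%d segments of %d samples)\n",
              length(x$frequencies), max(x$frequencies), x$n_segments,
              x$segment_length))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Mean of the coherence over the estimator's own frequency bins falling
#' inside the band (inclusive edges). No interpolation onto a finer grid:
#' the short analysis epochs set the resolution.
#'
#' @param spec a [ms_coherence()] result.
#' @param band a [band()] or name.
#' @return scalar in `[0, 1]`.
#' @export
band_coherence <- function(spec, band) {
  band <- as_band(band)
  sel <- spec$frequencies >= band$low & spec$frequencies <= band$high
  if (!any(sel)) {
    stop(sprintf("no coherence bins inside %s (%g-%g Hz)",
                 band$name, band$low, band$high), call. = FALSE)
  }
  mean(spec$coherence[sel])
}

#' Per-trial band coherence between two channels' epoch sets
#'
#' The default estimator computes coherence within each trial's epoch and
#' band-averages it, yielding one value per trial (these 40 values are
#' what the condition contrast tests). `pooled = TRUE` instead averages
#' cross- and auto-spectra over all trials before forming coherence --
#' a lower-variance estimator offered as an alternative (single value).
#'
#' @param epochs_a,epochs_b [extract_epochs()] sets of the two channels,
#'   same trials and window.
#' @param band a [band()] or name.
#' @param n_segments,overlap_frac see [ms_coherence()].
#' @param pooled average spectra across trials before coherence.
#' @return numeric vector of per-trial band coherences (or a single
#'   pooled value when `pooled = TRUE`).
#' @export
trial_band_coherence <- function(epochs_a, epochs_b, band, n_segments = 8,
                                 overlap_frac = 0.5, pooled = FALSE) {
  stopifnot(inherits(epochs_a, "epoch_set"), inherits(epochs_b, "epoch_set"),
            n_trials(epochs_a) == n_trials(epochs_b))
  fs <- epochs_a$sampling_rate
  if (!pooled) {
    return(vapply(seq_len(n_trials(epochs_a)), function(i) {
      band_coherence(
        ms_coherence(epochs_a$trials[i, ], epochs_b$trials[i, ], fs,
                     n_segments, overlap_frac),
        band)
    }, numeric(1)))
  }
  # pooled: accumulate spectra over trials x segments
  n <- ncol(epochs_a$trials)
  seg_len <- floor(n / ((n_segments - 1) * (1 - overlap_frac) + 1))
  step <- max(1L, floor(seg_len * (1 - overlap_frac)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hamming_window(seg_len)
  half <- floor(seg_len / 2)
  Sxx <- Syy <- numeric(half + 1L)
  Sxy <- complex(real = numeric(half + 1L), imaginary = numeric(half + 1L))
  for (i in seq_len(n_trials(epochs_a))) {
    for (s0 in starts) {
      idx <- seq.int(s0, s0 + seg_len - 1L)
      X <- stats::fft(w * epochs_a$trials[i, idx])[seq_len(half + 1L)]
      Y <- stats::fft(w * epochs_b$trials[i, idx])[seq_len(half + 1L)]
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
      Sxy <- Sxy + X * Conj(Y)
    }
  }
  spec <- structure(
    list(frequencies = (0:half) * fs / seg_len,
         coherence = pmin(pmax(Mod(Sxy)^2 / pmax(Sxx * Syy, .Machine$double.xmin), 0), 1),
         n_segments = length(starts) * n_trials(epochs_a),
         segment_length = seg_len),
    class = "coherence_spectrum"
  )
  band_coherence(spec, band)
}
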