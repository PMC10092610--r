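#' Single-segment Hamming periodogram of a 500 ms epoch
#'
#' Spectral estimate used for all band-power measures: the epoch is
#' (optionally) mean-subtracted, Hamming-tapered as one segment (no
#' splitting, no overlap) and transformed; a 500 ms epoch therefore yields
#' exactly a 2 Hz bin grid at any sampling rate. The one-sided power is
#' normalised so that `sum(power)` equals the energy of the windowed
#' signal (Parseval), with non-DC/non-Nyquist bins doubled.
#'
#' @param epoch numeric series of duration 500 ms (`length == fs / 2`).
#' @param sampling_rate Hz.
#' @param demean subtract the epoch mean before tapering (default TRUE;
#'   suppresses DC leakage through the Hamming window).
#' @return object of class `"band_spectrum"`: list with `frequencies`
#'   (0, 2, 4, ... Hz), `power`, `sampling_rate`.
#' @export
epoch_spectrum <- function(epoch, sampling_rate, demean = TRUE) {
  n <- length(epoch)
  expected <- round(sampling_rate / 2)
  if (n != expected) {
    stop(sprintf("epoch must be 500 ms (%d samples at %g Hz), got %d",
                 expected, sampling_rate, n), call. = FALSE)
  }
  x <- if (demean) epoch - mean(epoch) else epoch
  w <- hamming_window(n)
  X <- stats::fft(w * x)
  half <- floor(n / 2)                        # Nyquist bin index (n even)
  p2 <- Mod(X)^2 / n                          # two-sided, sums to energy
  power <- p2[seq_len(half + 1L)]
  if (n %% 2 == 0) {
    if (half >= 2) power[2:half] <- 2 * power[2:half]
  } else {
    power[-1] <- 2 * power[-1]
  }
  structure(
    list(frequencies = (0:half) * sampling_rate / n,
         power = power, sampling_rate = sampling_rate),
    class = "band_spectrum"
  )
}

hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' @export
print.band_spectrum <- function(x, ...) {
  cat(sprintf("<band_spectrum> %d bins, %g-%g Hz, %g Hz spacing\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$frequencies[2] - x$frequencies[1]))
  invisible(x)
}

#' Band power: sum of spectral power across a band
#'
#' Sums the power of all bins with `low <= f <= high` (both edges
#' inclusive; on the 2 Hz grid the canonical odd-Hz band boundaries never
#' produce a bin shared between adjacent bands).
#'
#' @param spectrum a [epoch_spectrum()] result.
#' @param band a [band()] or canonical band name.
#' @return nonnegative scalar.
#' @export
band_power <- function(spectrum, band) {
  band <- as_band(band)
  sel <- spectrum$frequencies >= band$low & spectrum$frequencies <= band$high
  if (!any(sel)) {
    stop(sprintf("no spectral bins inside %s (%g-%g Hz)",
                 band$name, band$low, band$high), call. = FALSE)
  }
  sum(spectrum$power[sel])
}

#' Per-trial baseline/late band-power table
#'
#' One row per trial with the baseline-window band power `P_b` and the
#' late-window (stimulus-related) band power `P_e`, for one channel, band
#' and condition. These are the `P_bi` / `P_ei` entering the normalised
#' power and baseline-ratio statistics.
#'
#' @param baseline,late [extract_epochs()] sets for the same channel and
#'   condition (baseline -500-0 ms, late 200-700 ms windows).
#' @param band a [band()] or name.
#' @param demean per-epoch mean subtraction before the spectrum.
#' @return tibble with columns `trial`, `P_b`, `P_e`, `band`, `channel`,
#'   `condition`.
#' @export
band_power_table <- function(baseline, late, band, demean = TRUE) {
  band <- as_band(band)
  stopifnot(inherits(baseline, "epoch_set"), inherits(late, "epoch_set"),
            n_trials(baseline) == n_trials(late),
            baseline$channel == late$channel)
  fs <- baseline$sampling_rate
  bp <- function(row) band_power(epoch_spectrum(row, fs, demean), band)
  tibble::tibble(
    trial = seq_len(n_trials(baseline)),
    P_b = apply(baseline$trials, 1, bp),
    P_e = apply(late$trials, 1, bp),
    band = band$name,
    channel = baseline$channel,
    condition = baseline$condition_label
  )
}

#' Average normalised power
#'
#' The mean over trials of the per-trial ratio of stimulus-related to
#' baseline band power, `mean(P_ei / P_bi)` -- the mean of ratios, not
#' the ratio of means. Applied per condition (saline `P_v`, ketamine
#' `P_kv`).
#'
#' @param table a [band_power_table()].
#' @return positive scalar.
#' @export
normalized_power <- function(table) {
  stopifnot(all(c("P_b", "P_e") %in% names(table)))
  if (any(table$P_b <= 0)) {
    stop("normalized_power undefined: nonpositive baseline power in table",
         call. = FALSE)
  }
  mean(table$P_e / table$P_b)
}

#' Baseline power ratio, ketamine relative to saline
#'
#' Mean over paired trials of `P_kbi / P_bi`: the condition contrast of
#' ongoing (pre-stimulus) band power, the quantity behind the
#' "baseline power relative to saline" bar plots.
#'
#' @param ketamine_table,saline_table paired [band_power_table()]s (same
#'   trial indices, same channel and band).
#' @return positive scalar.
#' @export
baseline_ratio <- function(ketamine_table, saline_table) {
  if (nrow(ketamine_table) != nrow(saline_table) ||
      !identical(ketamine_table$trial, saline_table$trial)) {
    stop("tables are not trial-paired", call. = FALSE)
  }
  if (any(saline_table$P_b <= 0)) {
    stop("nonpositive saline baseline power", call. = FALSE)
  }
  mean(ketamine_table$P_b / saline_table$P_b)
}

#' Evoked/induced decomposition of late-window band power
#'
#' Splits the per-trial late-window (total) band power into evoked
#' (phase-locked: the band power of the time-domain average of the same
#' trials' late epochs), baseline, and induced components:
#' `Induced_i = Total_i - Evoked - Baseline_i` (the default, `"methods"`
#' definition). The `"figure3"` variant omits the evoked term
#' (`Induced_i = Total_i - Baseline_i`); both are offered because the two
#' definitions circulate for this decomposition. Also reports the
#' percent change relative to baseline, `100 * Induced_i / Baseline_i`.
#'
#' @param late,baseline paired [extract_epochs()] sets (>= 2 trials).
#' @param band a [band()] or name.
#' @param definition `"methods"` (subtract evoked and baseline) or
#'   `"figure3"` (subtract baseline only).
#' @param demean per-epoch mean subtraction before spectra.
#' @return tibble with columns `trial`, `total`, `evoked` (scalar,
#'   repeated), `baseline`, `induced`, `pct_change`, `band`, `channel`,
#'   `condition`.
#' @export
induced_band_power <- function(late, baseline, band,
                               definition = c("methods", "figure3"),
                               demean = TRUE) {
  definition <- match.arg(definition)
  band <- as_band(band)
  stopifnot(inherits(late, "epoch_set"), inherits(baseline, "epoch_set"))
  if (n_trials(late) < 2L) {
    stop("need >= 2 trials to separate an evoked average", call. = FALSE)
  }
  if (n_trials(late) != n_trials(baseline)) {
    stop("late and baseline epoch sets are not trial-paired", call. = FALSE)
  }
  fs <- late$sampling_rate
  bp <- function(row) band_power(epoch_spectrum(row, fs, demean), band)
  total <- apply(late$trials, 1, bp)
  evoked <- bp(colMeans(late$trials))
  base <- apply(baseline$trials, 1, bp)
  induced <- if (definition == "methods") total - evoked - base else total - base
  tibble::tibble(
    trial = seq_len(n_trials(late)),
    total = total, evoked = evoked, baseline = base, induced = induced,
    pct_change = 100 * induced / base,
    band = band$name, channel = late$channel,
    condition = late$condition_label
  )
}
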