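#' Multi-channel continuous recording
#'
#' Container for a continuous multi-site electrophysiological signal:
#' a channels x time matrix with named rows, a sampling rate and a
#' condition label. The canonical montage has four sites: `EEG` (cortical
#' surface), `L6` (layer-6 field potential), `VPm` and `PoM` (specific and
#' higher-order somatosensory thalamic nuclei).
#'
#' @param data numeric matrix, channels in rows (rownames required) and
#'   samples in columns.
#' @param sampling_rate sampling rate in Hz; must exceed twice the highest
#'   analysed frequency (80 Hz).
#' @param condition_label condition tag, e.g. `"saline"` or `"ketamine"`.
#' @return object of class `"recording"`.
#' @export
recording <- function(data, sampling_rate, condition_label = "unlabelled") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (is.null(rownames(data))) stop("channel names (rownames) required", call. = FALSE)
  if (sampling_rate <= 2 * 80) {
    stop("sampling_rate must exceed 160 Hz (twice the 80 Hz analysis ceiling)",
         call. = FALSE)
  }
  structure(
    list(data = data, channels = rownames(data),
         sampling_rate = sampling_rate, condition_label = condition_label),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s | %d channels (%s) | %.1f s @ %g Hz\n",
              x$condition_label, nrow(x$data),
              paste(x$channels, collapse = ", "),
              ncol(x$data) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate

get_channel <- function(rec, channel) {
  if (!channel %in% rec$channels) {
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(rec$channels, collapse = ", ")), call. = FALSE)
  }
  rec$data[channel, ]
}

#' Stimulus train
#'
#' Strictly increasing stimulus onset times in seconds.
#'
#' @param onsets numeric vector of onset times (s), strictly increasing.
#' @return object of class `"stim_train"`.
#' @export
stim_train <- function(onsets) {
  stopifnot(is.numeric(onsets), length(onsets) >= 1L)
  if (any(diff(onsets) <= 0)) stop("onsets must be strictly increasing", call. = FALSE)
  structure(list(onsets = as.numeric(onsets)), class = "stim_train")
}

#' @export
print.stim_train <- function(x, ...) {
  cat(sprintf("<stim_train> %d onsets, %.1f-%.1f s\n",
              length(x$onsets), min(x$onsets), max(x$onsets)))
  invisible(x)
}

#' Write / read a recording as raw binary + JSON sidecar
#'
#' The sample matrix is stored column-major (time-major: all channels of
#' sample 1, then sample 2, ...) as little-endian float64 in `signal.bin`;
#' channel names, sampling rate and condition go to `meta.json`.
#'
#' @param rec a [recording()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (`write_recording`); a [recording()]
#'   (`read_recording`).
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "signal.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  meta <- list(channels = rec$channels, sampling_rate = rec$sampling_rate,
               condition_label = rec$condition_label,
               n_samples = ncol(rec$data))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n_ch <- length(meta$channels)
  con <- file(file.path(dir, "signal.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n_ch * meta$n_samples, size = 8,
               endian = "little")
  m <- matrix(x, nrow = n_ch, dimnames = list(meta$channels, NULL))
  recording(m, meta$sampling_rate, meta$condition_label)
}

#' Write / read stimulus onsets as a one-column TSV (seconds)
#'
#' @param train a [stim_train()].
#' @param path TSV path.
#' @export
write_stim_train <- function(train, path) {
  stopifnot(inherits(train, "stim_train"))
  utils::write.table(data.frame(onset_s = train$onsets), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stim_train
#' @export
read_stim_train <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stim_train(d[[1]])
}
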