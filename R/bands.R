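#' Frequency band definition
#'
#' A band is a named closed frequency interval `[low, high]` in Hz. The
#' canonical analysis set follows the usual rodent slow-wave-sleep
#' conventions: delta 1-4, theta 5-9, sigma 10-16, beta 17-29 and gamma
#' 30-80 Hz.
#'
#' @param name band name (any string; canonical names get canonical edges
#'   when `low`/`high` are omitted).
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return an object of class `"band"` (list with `name`, `low`, `high`).
#' @examples
#' band("gamma")
#' band("mid", 35, 45)
#' @export
band <- function(name, low = NULL, high = NULL) {
  canon <- canonical_bands()
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(canon)) {
      stop("band '", name, "' is not canonical; give explicit low/high edges",
           call. = FALSE)
    }
    return(canon[[name]])
  }
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  structure(list(name = name, low = low, high = high), class = "band")
}

#' Canonical analysis bands
#'
#' @return named list of [band()] objects: delta (1-4 Hz), theta (5-9),
#'   sigma (10-16), beta (17-29), gamma (30-80).
#' @export
canonical_bands <- function() {
  mk <- function(name, lo, hi) {
    structure(list(name = name, low = lo, high = hi), class = "band")
  }
  list(
    delta = mk("delta", 1, 4),
    theta = mk("theta", 5, 9),
    sigma = mk("sigma", 10, 16),
    beta  = mk("beta", 17, 29),
    gamma = mk("gamma", 30, 80)
  )
}

as_band <- function(x) {
  if (inherits(x, "band")) return(x)
  if (is.character(x) && length(x) == 1L) return(band(x))
  stop("expected a band object or a canonical band name", call. = FALSE)
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

check_band_vs_fs <- function(band, sampling_rate) {
  nyq <- sampling_rate / 2
  if (band$high > nyq) {
    stop(sprintf("band %s (%g-%g Hz) exceeds Nyquist (%g Hz)",
                 band$name, band$low, band$high, nyq), call. = FALSE)
  }
  invisible(TRUE)
}
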