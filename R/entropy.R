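#' Coarse-grain a series at scale factor tau
#'
#' Non-overlapping block means: element `j` of the coarse-grained series
#' is the mean of samples `(j-1)*tau + 1 .. j*tau`; the result has length
#' `floor(N / tau)` and `tau = 1` returns the input unchanged.
#'
#' @param x numeric series.
#' @param tau positive integer scale factor, `tau <= length(x)`.
#' @return numeric series of length `floor(length(x) / tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
coarse_grain <- function(x, tau) {
  if (tau < 1 || tau != round(tau)) stop("tau must be a positive integer", call. = FALSE)
  n <- length(x)
  if (n < tau) stop("series shorter than one block", call. = FALSE)
  if (tau == 1) return(x)
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` is the number of pairs of m-length templates
#' within Chebyshev distance `r` (self-matches excluded) and `A` the same
#' count for (m+1)-length templates, both over the `N - m` template start
#' points. When either count is zero the entropy is undefined and is
#' returned flagged (`defined = FALSE`, `value = NA`), never as a silent
#' NaN.
#'
#' @param x numeric series, `length(x) > m + 1`.
#' @param m embedding (template) length; default 2.
#' @param r absolute match tolerance, `r > 0` (callers usually pass a
#'   fraction of the series SD).
#' @return object of class `"sampen"`: list with `value`, `A`, `B`,
#'   `defined`, `m`, `r`.
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (length(x) <= m + 1) stop("series too short for embedding length m", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("r must be > 0", call. = FALSE)
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), as.numeric(r))
  A <- cnt[["A"]]; B <- cnt[["B"]]
  defined <- A > 0 && B > 0
  structure(
    list(value = if (defined) -log(A / B) else NA_real_,
         A = A, B = B, defined = defined, m = m, r = r),
    class = "sampen"
  )
}

#' @export
print.sampen <- function(x, ...) {
  cat(sprintf("<sampen> m=%d r=%.4g: %s (A=%g, B=%g)\n", x$m, x$r,
              if (x$defined) sprintf("%.4f", x$value) else "undefined",
              x$A, x$B))
  invisible(x)
}

#' Reference (brute-force) sample-entropy counts
#'
#' Literal O(N^2) reference implementation: forms the full pairwise
#' Chebyshev distance matrices of the m- and (m+1)-length embeddings and
#' counts matches. Kept as an independent check of the optimized kernel;
#' identical `A`/`B` counts are a tested invariant.
#'
#' @inheritParams sample_entropy
#' @return named numeric vector `c(A = , B = )`.
#' @export
sample_entropy_naive <- function(x, m = 2, r) {
  n <- length(x)
  stopifnot(n > m + 1, r > 0)
  nt <- n - m
  emb <- function(len) {
    sapply(seq_len(len), function(k) x[seq_len(nt) + k - 1L])  # nt x len
  }
  cheb_pairs <- function(E) {
    d <- matrix(0, nt, nt)
    for (k in seq_len(ncol(E))) d <- pmax(d, abs(outer(E[, k], E[, k], "-")))
    sum(d[upper.tri(d)] <= r)
  }
  c(A = as.numeric(cheb_pairs(emb(m + 1L))), B = as.numeric(cheb_pairs(emb(m))))
}

#' Multiscale entropy curve of a band-limited epoch
#'
#' Band-passes the raw epoch ([bandpass()]), fixes the tolerance
#' `r = r_frac * SD` of the filtered (scale-1) series, then computes
#' sample entropy of the coarse-grained series at each scale factor.
#' Holding `r` fixed across scales is the classic multiscale-entropy
#' procedure; `r_policy = "per_scale"` recomputes `r` from each
#' coarse-grained series instead. Scales whose entropy is undefined (no
#' template matches, or a degenerate all-constant epoch) are flagged, not
#' imputed.
#'
#' @param epoch numeric series (a late-window epoch).
#' @param band a [band()] or name (the decomposition targets beta/gamma).
#' @param sampling_rate Hz.
#' @param scales integer scale factors; default 1:20.
#' @param m embedding length; default 2.
#' @param r_frac tolerance as a fraction of SD; default 0.2.
#' @param r_policy `"scale1"` (default) or `"per_scale"`.
#' @return object of class `"mse_curve"`: list with `scales`, `values`,
#'   `defined`, `m`, `r`, `band`.
#' @export
mse_curve <- function(epoch, band, sampling_rate, scales = 1:20, m = 2,
                      r_frac = 0.2, r_policy = c("scale1", "per_scale")) {
  r_policy <- match.arg(r_policy)
  band <- as_band(band)
  y <- bandpass(epoch, band, sampling_rate)
  s <- stats::sd(y)
  vals <- rep(NA_real_, length(scales))
  defined <- rep(FALSE, length(scales))
  if (s > 0) {
    r1 <- r_frac * s
    for (i in seq_along(scales)) {
      z <- coarse_grain(y, scales[i])
      if (length(z) <= m + 1) next
      r <- if (r_policy == "scale1") r1 else r_frac * stats::sd(z)
      if (r <= 0) next
      se <- sample_entropy(z, m, r)
      vals[i] <- se$value
      defined[i] <- se$defined
    }
  }
  structure(
    list(scales = scales, values = vals, defined = defined,
         m = m, r = if (s > 0) r_frac * s else NA_real_, band = band$name),
    class = "mse_curve"
  )
}

#' Per-trial multiscale entropy over an epoch set
#'
#' Computes one [mse_curve()] per trial (the curves are averaged across
#' trials downstream, matching a per-trial-then-average design, not MSE
#' of concatenated trials).
#'
#' @param epochs an [extract_epochs()] set.
#' @inheritParams mse_curve
#' @return matrix of entropy values, trials x scales (NA where
#'   undefined), with attribute `"n_undefined"` (count per scale).
#' @export
mse_trials <- function(epochs, band, scales = 1:20, m = 2, r_frac = 0.2,
                       r_policy = "scale1") {
  stopifnot(inherits(epochs, "epoch_set"))
  out <- t(apply(epochs$trials, 1, function(row) {
    mse_curve(row, band, epochs$sampling_rate, scales, m, r_frac,
              r_policy)$values
  }))
  colnames(out) <- paste0("scale", scales)
  attr(out, "n_undefined") <- colSums(is.na(out))
  out
}

#' Paired comparison of two multiscale-entropy trial sets
#'
#' Per-scale paired t tests plus the headline mean-over-scales paired t
#' (df = n_trials - 1). Trials undefined at a scale (in either condition)
#' are excluded from that scale's test, with the exclusion count
#' reported; the mean-over-scales value per trial averages its defined
#' scales.
#'
#' @param cond_a,cond_b [mse_trials()] matrices with matching trials and
#'   scales (a - b differences are tested).
#' @return list with `per_scale` (tibble: scale, mean_a, mean_b,
#'   statistic, df, p_value, n_pairs, degenerate) and `mean_test` (one-row
#'   tibble from [paired_t()] on the per-trial scale means).
#' @export
mse_compare <- function(cond_a, cond_b) {
  stopifnot(identical(dim(cond_a), dim(cond_b)))
  scales <- seq_len(ncol(cond_a))
  per_scale <- do.call(rbind, lapply(scales, function(j) {
    ok <- stats::complete.cases(cbind(cond_a[, j], cond_b[, j]))
    a <- cond_a[ok, j]; b <- cond_b[ok, j]
    if (sum(ok) < 2) {
      return(tibble::tibble(scale = j, mean_a = NA_real_, mean_b = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, n_pairs = sum(ok),
                            degenerate = TRUE))
    }
    tt <- paired_t(a, b)
    tibble::tibble(scale = j, mean_a = mean(a), mean_b = mean(b),
                   statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
                   n_pairs = sum(ok), degenerate = tt$degenerate)
  }))
  mean_a <- rowMeans(cond_a, na.rm = TRUE)
  mean_b <- rowMeans(cond_b, na.rm = TRUE)
  list(per_scale = per_scale, mean_test = paired_t(mean_a, mean_b))
}
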