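#' Paired t test
#'
#' Two-sided paired t on `a - b`: `T = mean(d) / (sd(d) / sqrt(n))`,
#' df = n - 1. Zero variance of the differences (including a == b
#' exactly) is flagged degenerate rather than returning an infinite
#' statistic.
#'
#' @param a,b equal-length paired numeric vectors (n >= 2).
#' @return one-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  # zero variance up to floating-point noise (mirrors t.test's own
  # "essentially constant" guard) is reported as degenerate, not an error
  if (stats::sd(d) <= 10 * .Machine$double.eps * max(abs(mean(d)), 1)) {
    return(tibble::tibble(test = "paired_t", statistic = NA_real_,
                          df = length(d) - 1, p_value = NA_real_,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(test = "paired_t",
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 degenerate = FALSE)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped before ranking (their count is reported); the p-value is exact
#' for <= 25 nonzero pairs and uses the tie-corrected normal
#' approximation above that. All differences zero is flagged degenerate.
#'
#' @param a,b equal-length paired numeric vectors.
#' @return one-row tibble: `test`, `statistic` (W = sum of positive
#'   ranks), `df` (NA), `p_value`, `n_zero_dropped`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  nz <- sum(d == 0)
  dd <- d[d != 0]
  if (length(dd) == 0) {
    return(tibble::tibble(test = "wilcoxon_signed_rank", statistic = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          n_zero_dropped = nz, degenerate = TRUE))
  }
  exact <- length(dd) <= 25 && !any(duplicated(abs(dd)))
  # above the exact regime: tie-corrected normal approximation without
  # continuity correction (the corrected version is conservative at the
  # nominal level)
  wt <- suppressWarnings(
    stats::wilcox.test(dd, exact = exact, correct = FALSE)
  )
  tibble::tibble(test = "wilcoxon_signed_rank",
                 statistic = unname(wt$statistic),
                 df = NA_real_,
                 p_value = wt$p.value,
                 n_zero_dropped = nz,
                 degenerate = FALSE)
}

#' One-way ANOVA with Holm-Sidak post hoc
#'
#' Classical fixed-effects one-way ANOVA, `F = MS_between / MS_within`,
#' followed by all pairwise comparisons using the pooled within-group
#' error, adjusted with [holm_sidak()]. Zero within-group variance with
#' differing means is flagged degenerate.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `test` (one-row tibble: statistic, df1, df2,
#'   p_value, degenerate) and `posthoc` (tibble: group_a, group_b,
#'   statistic, p_value, adjusted_p).
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  k <- length(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  n <- length(y)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  if (ss_within == 0) {
    means <- vapply(groups, mean, 1)
    degen <- length(unique(means)) > 1
    if (degen) {
      return(list(
        test = tibble::tibble(test = "one_way_anova", statistic = NA_real_,
                              df1 = k - 1, df2 = n - k, p_value = NA_real_,
                              degenerate = TRUE),
        posthoc = tibble::tibble()))
    }
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  test <- tibble::tibble(test = "one_way_anova",
                         statistic = an[["F value"]][1],
                         df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                         p_value = an[["Pr(>F)"]][1],
                         degenerate = FALSE)
  # pairwise t with pooled within-group error
  ms_w <- an[["Mean Sq"]][2]
  df_w <- an[["Df"]][2]
  combs <- utils::combn(names(groups), 2)
  ph <- do.call(rbind, apply(combs, 2, function(pr) {
    va <- groups[[pr[1]]]; vb <- groups[[pr[2]]]
    se <- sqrt(ms_w * (1 / length(va) + 1 / length(vb)))
    tstat <- (mean(va) - mean(vb)) / se
    tibble::tibble(group_a = pr[1], group_b = pr[2], statistic = tstat,
                   p_value = 2 * stats::pt(-abs(tstat), df_w))
  }))
  ph$adjusted_p <- holm_sidak(ph$p_value)
  list(test = test, posthoc = ph)
}

#' Balanced two-way ANOVA (time x condition)
#'
#' Standard sum-of-squares decomposition for a balanced two-factor
#' layout; the interaction term is the test of interest for the induced
#' power contrast (does the stimulus-related power change differ between
#' conditions).
#'
#' @param values numeric response vector.
#' @param factor_time,factor_condition factors (coerced), balanced
#'   crossing.
#' @return tibble with one row per term (`time`, `condition`,
#'   `time:condition`, `residual`): `sum_sq`, `df`, `statistic`,
#'   `p_value`.
#' @export
two_way_anova <- function(values, factor_time, factor_condition) {
  ft <- factor(factor_time)
  fc <- factor(factor_condition)
  stopifnot(length(values) == length(ft), length(values) == length(fc))
  counts <- table(ft, fc)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("two_way_anova requires a balanced layout", call. = FALSE)
  }
  fit <- stats::aov(values ~ ft * fc)
  an <- summary(fit)[[1]]
  terms <- c("time", "condition", "time:condition", "residual")
  tibble::tibble(
    term = terms,
    sum_sq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]]
  )
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the p-values ascending, sets
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotone
#' non-decreasing adjusted values down the sorted list, caps at 1 and
#' restores the input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input; always
#'   `>= pvals` and `<= 1`.
#' @export
holm_sidak <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  if (m == 0) return(pvals)
  ord <- order(pvals)
  ps <- pvals[ord]
  adj <- 1 - (1 - ps)^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
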