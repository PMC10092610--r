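#' Full paired-condition analysis
#'
#' Runs the complete analysis battery on a paired saline/ketamine session
#' pair, producing machine-readable analogs of the study's headline
#' figures:
#'
#' * per channel x band: the per-trial baseline/late power table, the
#'   average normalised power per condition, the ketamine/saline baseline
#'   power ratio with a paired t test, and the induced (total - evoked -
#'   baseline) percent change with the time x condition two-way ANOVA
#'   interaction;
#' * per channel x band: multiscale-entropy curves per trial and the
#'   per-scale and mean-over-scales paired t comparison;
#' * per site pair x band: per-trial late-window band coherence with the
#'   Wilcoxon matched-pairs signed-rank contrast.
#'
#' Within each figure-analog family (the channels of one band's baseline
#' panel, the channels of one band's induced panel, the channels of one
#' band's entropy panel, the pairs of one band's coherence panel) raw
#' p-values are Holm-Sidak adjusted.
#'
#' @param pair a [generate_condition_pair()] result, or any list with
#'   `saline` and `ketamine` elements each holding `recording` and
#'   `stims`.
#' @param bands character, analysis bands; default beta and gamma.
#' @param channels channels to analyse; all four by default.
#' @param coherence_pairs list of channel pairs; default L6-VPm, L6-PoM,
#'   VPm-PoM.
#' @param mse_scales,mse_m,mse_r_frac multiscale-entropy parameters.
#' @param induced_definition `"methods"` or `"figure3"`, see
#'   [induced_band_power()].
#' @param n_segments,overlap_frac coherence segmentation, see
#'   [ms_coherence()].
#' @param verbose log stage progress and trial counts.
#' @return object of class `"ctc_report"`: list with `power_tables`,
#'   `baseline_tests`, `induced_trials`, `induced_tests`, `mse_values`,
#'   `mse_tests`, `coherence_trials`, `coherence_tests`, `provenance`.
#' @export
run_full_analysis <- function(pair,
                              bands = c("beta", "gamma"),
                              channels = c("EEG", "L6", "VPm", "PoM"),
                              coherence_pairs = list(c("L6", "VPm"),
                                                     c("L6", "PoM"),
                                                     c("VPm", "PoM")),
                              mse_scales = 1:20, mse_m = 2, mse_r_frac = 0.2,
                              induced_definition = "methods",
                              n_segments = 8, overlap_frac = 0.5,
                              verbose = FALSE) {
  for (cond in c("saline", "ketamine")) {
    if (is.null(pair[[cond]]) || is.null(pair[[cond]]$recording)) {
      stop("pair must contain saline and ketamine sessions", call. = FALSE)
    }
  }
  sal <- pair$saline; ket <- pair$ketamine
  need <- unique(c(channels, unlist(coherence_pairs)))
  for (ses in list(sal, ket)) {
    missing_ch <- setdiff(need, ses$recording$channels)
    if (length(missing_ch)) {
      stop(sprintf("channel(s) %s missing from %s recording",
                   paste(missing_ch, collapse = ", "),
                   ses$recording$condition_label), call. = FALSE)
    }
  }
  n_sal <- length(sal$stims$onsets); n_ket <- length(ket$stims$onsets)
  if (n_sal != n_ket) {
    stop(sprintf("unpaired conditions: %d saline vs %d ketamine trials",
                 n_sal, n_ket), call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("epoching: %d paired trials", n_sal)

  ep <- list()
  for (ch in need) {
    ep[[ch]] <- list(
      sal_base = extract_epochs(sal$recording, sal$stims, ch, baseline_window()),
      sal_late = extract_epochs(sal$recording, sal$stims, ch, late_window()),
      ket_base = extract_epochs(ket$recording, ket$stims, ch, baseline_window()),
      ket_late = extract_epochs(ket$recording, ket$stims, ch, late_window())
    )
  }

  power_tables <- list(); baseline_rows <- list()
  induced_trials <- list(); induced_rows <- list()
  mse_vals <- list(); mse_rows <- list()

  for (bd in bands) {
    for (ch in channels) {
      e <- ep[[ch]]
      ts <- band_power_table(e$sal_base, e$sal_late, bd)
      tk <- band_power_table(e$ket_base, e$ket_late, bd)
      power_tables[[paste(ch, bd, sep = ".")]] <- dplyr::bind_rows(ts, tk)

      # paired t on log power (same variance-stabilised scale as the
      # two-way ANOVA); the reported ratio stays on the natural scale
      tt <- paired_t(log10(tk$P_b), log10(ts$P_b))
      baseline_rows[[paste(ch, bd)]] <- tibble::tibble(
        channel = ch, band = bd,
        ratio = baseline_ratio(tk, ts),
        P_v_saline = normalized_power(ts),
        P_v_ketamine = normalized_power(tk),
        statistic = tt$statistic, df = tt$df, p_value = tt$p_value
      )

      is_ <- induced_band_power(e$sal_late, e$sal_base, bd,
                                definition = induced_definition)
      ik <- induced_band_power(e$ket_late, e$ket_base, bd,
                               definition = induced_definition)
      induced_trials[[paste(ch, bd, sep = ".")]] <- dplyr::bind_rows(is_, ik)
      # log10 power: variance-stabilises spectral power so the balanced
      # ANOVA's homoscedasticity assumption holds across conditions
      aw <- two_way_anova(
        values = log10(c(ts$P_b, ts$P_e, tk$P_b, tk$P_e)),
        factor_time = rep(rep(c("baseline", "late"), each = n_sal), 2),
        factor_condition = rep(c("saline", "ketamine"), each = 2 * n_sal)
      )
      inter <- aw[aw$term == "time:condition", ]
      induced_rows[[paste(ch, bd)]] <- tibble::tibble(
        channel = ch, band = bd,
        mean_pct_saline = mean(is_$pct_change),
        mean_pct_ketamine = mean(ik$pct_change),
        # signed interaction contrast on the tested (log-power) scale:
        # negative = the stimulus-related power increase shrinks under
        # ketamine
        interaction_effect =
          (mean(log10(tk$P_e)) - mean(log10(tk$P_b))) -
          (mean(log10(ts$P_e)) - mean(log10(ts$P_b))),
        interaction_F = inter$statistic, p_value = inter$p_value
      )

      say("mse: %s %s", ch, bd)
      ms <- mse_trials(e$sal_late, bd, mse_scales, mse_m, mse_r_frac)
      mk <- mse_trials(e$ket_late, bd, mse_scales, mse_m, mse_r_frac)
      mse_vals[[paste(ch, bd, sep = ".")]] <-
        list(saline = ms, ketamine = mk)
      cmpr <- mse_compare(mk, ms)   # ketamine - saline differences
      mt <- cmpr$mean_test
      mse_rows[[paste(ch, bd)]] <- tibble::tibble(
        channel = ch, band = bd,
        mean_saline = mean(ms, na.rm = TRUE),
        mean_ketamine = mean(mk, na.rm = TRUE),
        statistic = mt$statistic, df = mt$df, p_value = mt$p_value,
        degenerate = mt$degenerate
      )
    }
  }

  coh_trials <- list(); coh_rows <- list()
  for (bd in bands) {
    for (pr in coherence_pairs) {
      key <- paste(pr[1], pr[2], sep = "-")
      cs <- trial_band_coherence(ep[[pr[1]]]$sal_late, ep[[pr[2]]]$sal_late,
                                 bd, n_segments, overlap_frac)
      ck <- trial_band_coherence(ep[[pr[1]]]$ket_late, ep[[pr[2]]]$ket_late,
                                 bd, n_segments, overlap_frac)
      coh_trials[[paste(key, bd, sep = ".")]] <- tibble::tibble(
        pair = key, band = bd,
        trial = rep(seq_along(cs), 2),
        condition = rep(c("saline", "ketamine"), each = length(cs)),
        coherence = c(cs, ck)
      )
      wt <- wilcoxon_signed_rank(ck, cs)
      coh_rows[[paste(key, bd)]] <- tibble::tibble(
        pair = key, band = bd,
        mean_saline = mean(cs), mean_ketamine = mean(ck),
        statistic = wt$statistic, p_value = wt$p_value,
        degenerate = wt$degenerate
      )
    }
  }

  adjust_by_band <- function(rows) {
    d <- dplyr::bind_rows(rows)
    dplyr::mutate(dplyr::group_by(d, band),
                  adjusted_p = ifelse(is.na(p_value), NA,
                                      holm_sidak(ifelse(is.na(p_value), 1, p_value))),
                  .keep = "all") |> dplyr::ungroup()
  }

  structure(
    list(
      power_tables = dplyr::bind_rows(power_tables),
      baseline_tests = adjust_by_band(baseline_rows),
      induced_trials = dplyr::bind_rows(induced_trials),
      induced_tests = adjust_by_band(induced_rows),
      mse_values = mse_vals,
      mse_tests = adjust_by_band(mse_rows),
      coherence_trials = dplyr::bind_rows(coh_trials),
      coherence_tests = adjust_by_band(coh_rows),
      provenance = list(
        n_trials = n_sal,
        sampling_rate = sal$recording$sampling_rate,
        bands = bands, channels = channels,
        induced_definition = induced_definition,
        mse = list(scales = mse_scales, m = mse_m, r_frac = mse_r_frac),
        coherence = list(n_segments = n_segments, overlap_frac = overlap_frac),
        package_version = as.character(utils::packageVersion("ctcgamma"))
      )
    ),
    class = "ctc_report"
  )
}

#' Evaluate the four-way condition signature of a report
#'
#' The qualitative pattern the ketamine condition is expected to produce.
#' All checks consult the Holm-Sidak family-adjusted p-values (families =
#' figure panels, see [run_full_analysis()]) at level `alpha`:
#'
#' 1. `baseline_up`: baseline beta and gamma power ratio > 1 at all
#'    analysed sites, each paired t significant;
#' 2. `induced_down`: the stimulus-related power increase shrinks under
#'    ketamine (negative interaction contrast on the tested log-power
#'    scale) at all sites and bands, with the time x condition
#'    interaction significant at every site for the gamma band (the
#'    interaction test targets the induced gamma oscillations; beta
#'    enters directionally);
#' 3. `entropy_l6_vpm`: gamma-band mean multiscale entropy significantly
#'    higher under ketamine in L6 and VPm, and *not* significantly
#'    different in PoM;
#' 4. `coherence_l6_vpm`: L6-VPm gamma band coherence significantly lower
#'    under ketamine (Wilcoxon), with L6-PoM and VPm-PoM unchanged.
#'
#' @param report a [run_full_analysis()] result.
#' @param alpha significance level; default 0.05.
#' @return tibble with columns `check` and `holds`, plus the conjunction
#'   row `signature`.
#' @export
headline_signature <- function(report, alpha = 0.05) {
  bt <- report$baseline_tests
  it <- report$induced_tests
  mt <- report$mse_tests
  ct <- report$coherence_tests
  sig <- function(p) !is.na(p) & p < alpha

  # one policy throughout: family-wise Holm-Sidak-adjusted p per figure
  # panel, for the must-be-significant and must-be-flat checks alike
  baseline_up <- all(bt$ratio > 1 & sig(bt$adjusted_p))
  induced_down <- all(it$interaction_effect < 0) &&
    all(sig(it$adjusted_p[it$band == "gamma"]))
  mg <- mt[mt$band == "gamma", ]
  up_l6 <- with(mg[mg$channel == "L6", ],
                sig(adjusted_p) && statistic > 0)
  up_vpm <- with(mg[mg$channel == "VPm", ],
                 sig(adjusted_p) && statistic > 0)
  pom_flat <- !sig(mg$adjusted_p[mg$channel == "PoM"])
  entropy_l6_vpm <- isTRUE(up_l6 && up_vpm && pom_flat)
  cg <- ct[ct$band == "gamma", ]
  drop_l6vpm <- with(cg[cg$pair == "L6-VPm", ],
                     sig(adjusted_p) && mean_ketamine < mean_saline)
  others_flat <- all(!sig(cg$adjusted_p[cg$pair != "L6-VPm"]))
  coherence_l6_vpm <- isTRUE(drop_l6vpm && others_flat)

  tibble::tibble(
    check = c("baseline_up", "induced_down", "entropy_l6_vpm",
              "coherence_l6_vpm", "signature"),
    holds = c(baseline_up, induced_down, entropy_l6_vpm, coherence_l6_vpm,
              baseline_up && induced_down && entropy_l6_vpm &&
                coherence_l6_vpm)
  )
}

#' Render a report bundle to TSV tables and figures
#'
#' Writes every table of the bundle as TSV and draws the figure analogs
#' (baseline-ratio bars, induced %-change bars, entropy-vs-scale curves,
#' coherence bars, each with SEM). Deterministic given the bundle.
#'
#' @param report a [run_full_analysis()] result.
#' @param dir output directory (created).
#' @return invisible character vector of files written.
#' @export
render_report <- function(report, dir) {
  required <- c("power_tables", "baseline_tests", "induced_trials",
                "induced_tests", "mse_values", "mse_tests",
                "coherence_trials", "coherence_tests")
  missing_s <- required[vapply(required, function(s) is.null(report[[s]]),
                               logical(1))]
  if (length(missing_s)) {
    stop("incomplete report bundle; missing section(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wt <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
  }
  wt(report$power_tables, "power_tables.tsv")
  wt(report$baseline_tests, "baseline_tests.tsv")
  wt(report$induced_trials, "induced_trials.tsv")
  wt(report$induced_tests, "induced_tests.tsv")
  wt(report$mse_tests, "mse_tests.tsv")
  wt(report$coherence_trials, "coherence_trials.tsv")
  wt(report$coherence_tests, "coherence_tests.tsv")

  mse_long <- do.call(rbind, lapply(names(report$mse_values), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    do.call(rbind, lapply(c("saline", "ketamine"), function(cond) {
      m <- report$mse_values[[k]][[cond]]
      data.frame(channel = parts[1], band = parts[2], condition = cond,
                 trial = rep(seq_len(nrow(m)), ncol(m)),
                 scale = rep(seq_len(ncol(m)), each = nrow(m)),
                 entropy = as.vector(m))
    }))
  }))
  wt(mse_long, "mse_values.tsv")

  gg_save <- function(p, name, w = 7, h = 5) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, p, width = w, height = h, dpi = 120)
    written <<- c(written, path)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))

  pt <- report$power_tables
  pt_sum <- dplyr::summarise(
    dplyr::group_by(pt, channel, band, condition),
    mean_P_b = mean(P_b), sem_P_b = sem(P_b), .groups = "drop")
  gg_save(
    ggplot2::ggplot(pt_sum, ggplot2::aes(channel, mean_P_b, fill = condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_P_b - sem_P_b,
                                          ymax = mean_P_b + sem_P_b),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.25) +
      ggplot2::facet_wrap(~band, scales = "free_y") +
      ggplot2::labs(y = "baseline band power (a.u.)",
                    title = "Ongoing (baseline) band power"),
    "fig_baseline_power.png")

  it <- report$induced_trials
  it_sum <- dplyr::summarise(
    dplyr::group_by(it, channel, band, condition),
    mean_pct = mean(pct_change), sem_pct = sem(pct_change), .groups = "drop")
  gg_save(
    ggplot2::ggplot(it_sum, ggplot2::aes(channel, mean_pct, fill = condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_pct - sem_pct,
                                          ymax = mean_pct + sem_pct),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.25) +
      ggplot2::facet_wrap(~band, scales = "free_y") +
      ggplot2::labs(y = "induced power, % of baseline",
                    title = "Induced (non-phase-locked) late-window power"),
    "fig_induced_power.png")

  mse_sum <- dplyr::summarise(
    dplyr::group_by(mse_long, channel, band, condition, scale),
    mean_h = mean(entropy, na.rm = TRUE),
    sem_h = sem(stats::na.omit(entropy)), .groups = "drop")
  gg_save(
    ggplot2::ggplot(mse_sum, ggplot2::aes(scale, mean_h, colour = condition)) +
      ggplot2::geom_line() +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_h - sem_h,
                                        ymax = mean_h + sem_h,
                                        fill = condition),
                           alpha = 0.2, colour = NA) +
      ggplot2::facet_grid(band ~ channel) +
      ggplot2::labs(x = "scale factor", y = "sample entropy",
                    title = "Band-limited multiscale entropy (late window)"),
    "fig_mse.png", w = 9, h = 5)

  cohs <- dplyr::summarise(
    dplyr::group_by(report$coherence_trials, pair, band, condition),
    mean_c = mean(coherence), sem_c = sem(coherence), .groups = "drop")
  gg_save(
    ggplot2::ggplot(cohs, ggplot2::aes(pair, mean_c, fill = condition)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_c - sem_c,
                                          ymax = mean_c + sem_c),
                             position = ggplot2::position_dodge(0.9),
                             width = 0.25) +
      ggplot2::facet_wrap(~band) +
      ggplot2::labs(y = "band coherence",
                    title = "Late-window coherence between sites"),
    "fig_coherence.png")

  invisible(written)
}

#' @export
print.ctc_report <- function(x, ...) {
  cat(sprintf("<ctc_report> %d paired trials @ %g Hz; bands: %s\n",
              x$provenance$n_trials, x$provenance$sampling_rate,
              paste(x$provenance$bands, collapse = ", ")))
  cat("sections: power_tables, baseline_tests, induced_*, mse_*, coherence_*\n")
  invisible(x)
}
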