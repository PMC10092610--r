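#!/usr/bin/env Rscript
# Band-power analysis of the canonical pair: per-trial baseline/late
# power tables, average normalised power, ketamine/saline baseline
# ratios (paired t on log power) and the induced %-change with the
# time x condition interaction. Writes TSVs under results/power/.

library(ctcgamma)

read_pair <- function(root = "results/sessions") {
  lapply(c(saline = "saline", ketamine = "ketamine"), function(cond) {
    list(recording = read_recording(file.path(root, cond)),
         stims = read_stim_train(file.path(root, cond, "onsets.tsv")))
  })
}
pair <- read_pair()
dir.create("results/power", recursive = TRUE, showWarnings = FALSE)

rows_b <- list(); rows_i <- list(); tables <- list()
for (bd in c("beta", "gamma")) {
  for (ch in c("EEG", "L6", "VPm", "PoM")) {
    ep <- lapply(pair, function(ses) list(
      base = extract_epochs(ses$recording, ses$stims, ch, baseline_window()),
      late = extract_epochs(ses$recording, ses$stims, ch, late_window())))
    ts <- band_power_table(ep$saline$base, ep$saline$late, bd)
    tk <- band_power_table(ep$ketamine$base, ep$ketamine$late, bd)
    tables[[paste(ch, bd)]] <- rbind(ts, tk)
    tt <- paired_t(log10(tk$P_b), log10(ts$P_b))
    rows_b[[paste(ch, bd)]] <- data.frame(
      channel = ch, band = bd, ratio = baseline_ratio(tk, ts),
      P_v_saline = normalized_power(ts), P_v_ketamine = normalized_power(tk),
      t = tt$statistic, df = tt$df, p = tt$p_value)
    ind_s <- induced_band_power(ep$saline$late, ep$saline$base, bd)
    ind_k <- induced_band_power(ep$ketamine$late, ep$ketamine$base, bd)
    n <- nrow(ts)
    aw <- two_way_anova(log10(c(ts$P_b, ts$P_e, tk$P_b, tk$P_e)),
                        rep(rep(c("baseline", "late"), each = n), 2),
                        rep(c("saline", "ketamine"), each = 2 * n))
    inter <- aw[aw$term == "time:condition", ]
    rows_i[[paste(ch, bd)]] <- data.frame(
      channel = ch, band = bd,
      pct_saline = mean(ind_s$pct_change), pct_ketamine = mean(ind_k$pct_change),
      interaction_F = inter$statistic, interaction_p = inter$p_value)
  }
}
write.table(do.call(rbind, tables), "results/power/power_tables.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
bt <- do.call(rbind, rows_b); it <- do.call(rbind, rows_i)
write.table(bt, "results/power/baseline_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(it, "results/power/induced_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("baseline band power under ketamine, relative to saline:")
print(bt[, c("channel", "band", "ratio", "p")], row.names = FALSE)
message("induced power, % of baseline (saline vs ketamine):")
print(it, row.names = FALSE)
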