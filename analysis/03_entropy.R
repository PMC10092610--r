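#!/usr/bin/env Rscript
# Band-limited multiscale entropy of the late (200-700 ms) window:
# per-trial curves for beta and gamma at every site, and the paired
# saline-vs-ketamine comparison (per scale and mean over scales).
# Writes results/mse/.

library(ctcgamma)

pair <- lapply(c(saline = "saline", ketamine = "ketamine"), function(cond) {
  root <- file.path("results/sessions", cond)
  list(recording = read_recording(root),
       stims = read_stim_train(file.path(root, "onsets.tsv")))
})
dir.create("results/mse", recursive = TRUE, showWarnings = FALSE)

curves <- list(); tests <- list()
for (bd in c("beta", "gamma")) {
  for (ch in c("EEG", "L6", "VPm", "PoM")) {
    m <- lapply(pair, function(ses) {
      late <- extract_epochs(ses$recording, ses$stims, ch, late_window())
      mse_trials(late, bd)
    })
    cmp <- mse_compare(m$ketamine, m$saline)
    tests[[paste(ch, bd)]] <- data.frame(
      channel = ch, band = bd,
      mean_saline = mean(m$saline, na.rm = TRUE),
      mean_ketamine = mean(m$ketamine, na.rm = TRUE),
      t = cmp$mean_test$statistic, df = cmp$mean_test$df,
      p = cmp$mean_test$p_value)
    for (cond in names(m)) {
      mm <- m[[cond]]
      curves[[paste(ch, bd, cond)]] <- data.frame(
        channel = ch, band = bd, condition = cond,
        trial = rep(seq_len(nrow(mm)), ncol(mm)),
        scale = rep(seq_len(ncol(mm)), each = nrow(mm)),
        entropy = as.vector(mm))
    }
  }
}
write.table(do.call(rbind, curves), "results/mse/mse_values.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
tt <- do.call(rbind, tests)
write.table(tt, "results/mse/mse_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("mean multiscale entropy, ketamine vs saline (paired t):")
print(tt, row.names = FALSE)
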