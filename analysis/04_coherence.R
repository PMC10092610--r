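#!/usr/bin/env Rscript
# Magnitude-squared coherence between site pairs in the late window:
# per-trial band coherence for L6-VPm, L6-PoM and VPm-PoM with the
# Wilcoxon matched-pairs contrast. Writes results/coherence/.

library(ctcgamma)

pair <- lapply(c(saline = "saline", ketamine = "ketamine"), function(cond) {
  root <- file.path("results/sessions", cond)
  list(recording = read_recording(root),
       stims = read_stim_train(file.path(root, "onsets.tsv")))
})
dir.create("results/coherence", recursive = TRUE, showWarnings = FALSE)

trials <- list(); tests <- list()
for (bd in c("beta", "gamma")) {
  for (pr in list(c("L6", "VPm"), c("L6", "PoM"), c("VPm", "PoM"))) {
    key <- paste(pr, collapse = "-")
    co <- lapply(pair, function(ses) {
      a <- extract_epochs(ses$recording, ses$stims, pr[1], late_window())
      b <- extract_epochs(ses$recording, ses$stims, pr[2], late_window())
      trial_band_coherence(a, b, bd)
    })
    wt <- wilcoxon_signed_rank(co$ketamine, co$saline)
    tests[[paste(key, bd)]] <- data.frame(
      pair = key, band = bd,
      mean_saline = mean(co$saline), mean_ketamine = mean(co$ketamine),
      W = wt$statistic, p = wt$p_value)
    trials[[paste(key, bd)]] <- data.frame(
      pair = key, band = bd, trial = rep(seq_along(co$saline), 2),
      condition = rep(c("saline", "ketamine"), each = length(co$saline)),
      coherence = c(co$saline, co$ketamine))
  }
}
write.table(do.call(rbind, trials), "results/coherence/coherence_trials.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
tt <- do.call(rbind, tests)
write.table(tt, "results/coherence/coherence_tests.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message("band coherence by site pair (Wilcoxon, ketamine vs saline):")
print(tt, row.names = FALSE)
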