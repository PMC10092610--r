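#!/usr/bin/env Rscript
# Generate the canonical paired saline/ketamine synthetic session and
# store it in the package's on-disk formats (binary+JSON recordings,
# TSV onset lists) under results/sessions/.
#
# The canonical experiment follows the analysed design: 4 rats x 10
# trials = 40 paired trials, one stimulus every 15 s, 1 kHz sampling.

library(ctcgamma)

seed <- 20260928 %% 19937
message("simulating canonical condition pair (seed ", seed, ")")

sal_cfg <- session_config(seed = seed)
pair <- generate_condition_pair(sal_cfg)

out <- "results/sessions"
for (cond in c("saline", "ketamine")) {
  dir <- file.path(out, cond)
  write_recording(pair[[cond]]$recording, dir)
  write_stim_train(pair[[cond]]$stims, file.path(dir, "onsets.tsv"))
  message(sprintf("  %s: %.0f s of 4-channel signal, %d stimuli -> %s",
                  cond, ncol(pair[[cond]]$recording$data) /
                    pair[[cond]]$recording$sampling_rate,
                  length(pair[[cond]]$stims$onsets), dir))
}
message("done; downstream scripts read ", out)
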