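#!/usr/bin/env Rscript
# One-shot report: run the full pipeline on the stored canonical pair,
# render every table and figure analog under results/report/, and print
# the four-way condition signature.

library(ctcgamma)

pair <- lapply(c(saline = "saline", ketamine = "ketamine"), function(cond) {
  root <- file.path("results/sessions", cond)
  list(recording = read_recording(root),
       stims = read_stim_train(file.path(root, "onsets.tsv")))
})

report <- run_full_analysis(pair, verbose = TRUE)
files <- render_report(report, "results/report")
message("wrote ", length(files), " files to results/report")

sig <- headline_signature(report)
message("condition signature:")
print(as.data.frame(sig), row.names = FALSE)
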