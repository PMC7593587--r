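#!/usr/bin/env Rscript
# Step 4 — collate the study outputs into one JSON report.

suppressMessages(library(gcescan))

verdicts <- read.table(file.path("results", "genome_verdicts.tsv"),
                       header = TRUE, sep = "\t")
passrate <- read.table(file.path("results", "expression",
                                 "pass_rate_by_divergence.tsv"),
                       header = TRUE, sep = "\t")
report <- list(
  genomes = verdicts,
  expression_pass_rate_by_divergence = passrate)
jsonlite::write_json(report, file.path("results", "summary.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
cat("wrote results/summary.json\n")
str(report, max.level = 2)
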