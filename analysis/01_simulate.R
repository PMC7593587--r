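#!/usr/bin/env Rscript
# Step 1 — build the synthetic study set.
#
# Emits the three genome presets with ground-truth manifests, plus a
# transcript set simulated from the complete genome at 0% and 5%
# amino-acid divergence, under results/fixtures/. Everything downstream
# (02, 03) reads from there.

suppressMessages(library(gcescan))

seed <- 1L
dir <- file.path("results", "fixtures")
dir.create(dir, showWarnings = FALSE, recursive = TRUE)

generate_fixtures(dir, seed = seed)

# a second transcript set at 5% divergence for the threshold study
g <- read_manifest(file.path(dir, "pyl_complete.manifest.json"))
tx5 <- simulate_transcripts(g, per_gene = 34, divergence_levels = c(0, 5),
                            seed = seed + 1L)
write_fasta(tx5$transcripts, file.path(dir, "transcripts_d0_d5.fna"))
write_manifest(tx5$manifest, file.path(dir, "transcripts_d0_d5.manifest.json"))

for (preset in c("pyl_complete", "pyl_no_trna", "negative")) {
  m <- read_manifest(file.path(dir, paste0(preset, ".manifest.json")))
  cat(sprintf("%-13s %d implants, %d nt\n", preset, nrow(m$implants),
              m$background$length_nt))
}
cat(sprintf("transcripts: %d (0%% and 5%% divergence)\n",
            length(tx5$transcripts)))
cat("fixtures written to", dir, "\n")
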