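#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with the
# planted ground truth written alongside each dataset.
# Usage: Rscript analysis/01_simulate_data.R [seed]

suppressPackageStartupMessages(library(covadduct))
suppressPackageStartupMessages(library(jsonlite))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = seed)

# 4-vs-4 PSM table with 10 of 100 proteins enriched eightfold
psm <- gen_psm_table(cfg)
write_tsv_table(psm$psms, file.path(out, "psm_table.tsv"))
write_json(psm$truth, file.path(out, "psm_truth.json"), auto_unbox = TRUE)
cat(sprintf("PSM table: %d PSMs over %d proteins (%d enriched) -> %s\n",
            nrow(psm$psms), length(unique(psm$psms$protein_id)),
            length(psm$truth$enriched_protein_ids),
            file.path(out, "psm_table.tsv")))

# synthetic Shp2-like protein and crosslink spectra with planted bridges
prot <- shp2_like_sequence()
write_fasta(prot, file.path(out, "shp2_synthetic.fasta"))
sx <- gen_crosslink_spectra(prot, config = cfg)
write_mgf(sx$spectra, file.path(out, "spectra.mgf"))
write_tsv_table(sx$truth, file.path(out, "spectra_truth.tsv"))
cat(sprintf("Spectra: %d planted crosslink scans + %d decoys -> %s\n",
            nrow(sx$truth), cfg$n_decoy_spectra, file.path(out, "spectra.mgf")))

# SFX-01-style inhibition dose series
d <- gen_dose_response(cfg)
write_tsv_table(d, file.path(out, "dose_response.tsv"))
write_json(attr(d, "truth"), file.path(out, "dose_truth.json"), auto_unbox = TRUE)
cat(sprintf("Dose-response: %d doses, true k = %.3g /uM -> %s\n",
            nrow(d), attr(d, "truth")$k, file.path(out, "dose_response.tsv")))
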