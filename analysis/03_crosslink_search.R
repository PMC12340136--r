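#!/usr/bin/env Rscript
# Non-cleavable-linker crosslink search on the simulated spectra: tryptic
# digest of the Shp2-like sequence, dithiolethione bridge candidates over all
# cysteine pairs, MS1 precursor matching at 10 ppm and b/y fragment
# annotation at 20 ppm. Run analysis/01_simulate_data.R first.

suppressPackageStartupMessages(library(covadduct))

prot <- read_fasta("results/sim/shp2_synthetic.fasta")
spectra <- read_mgf("results/sim/spectra.mgf")
truth <- read_tsv_table("results/sim/spectra_truth.tsv")

report <- xl_search(prot, spectra)
write_tsv_table(report, "results/crosslink_report.tsv")

recov <- score_crosslink_recovery(report, truth)
cat(sprintf("Search: %d MS1 matches over %d spectra\n",
            nrow(report), length(spectra)))
cat(sprintf("Planted bridges recovered: %.0f%% (%d planted)\n",
            100 * recov, nrow(truth)))
if (nrow(report) > 0) {
  top <- report[1, ]
  cat(sprintf("Top hit: %s Cys%d-Cys%d, %.1f%% of fragments matched, %+.2f ppm\n",
              top$scan_id, top$cys_a, top$cys_b, 100 * top$score, top$ppm_error))
}
cat("Report written to results/crosslink_report.tsv\n")
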