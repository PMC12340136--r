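#!/usr/bin/env Rscript
# One-phase exponential decay fit of the simulated SFX-01 inhibition dose
# series: Y(c) = plateau + (y0 - plateau) * exp(-k c), nonlinear least
# squares with multi-start. Run analysis/01_simulate_data.R first.

suppressPackageStartupMessages(library(covadduct))
suppressPackageStartupMessages(library(jsonlite))

d <- read_tsv_table("results/sim/dose_response.tsv")
truth <- fromJSON("results/sim/dose_truth.json")

fit <- fit_one_phase_decay(d)
out <- data.frame(y0 = fit$y0, plateau = fit$plateau, k = fit$k, r2 = fit$r2)
write_tsv_table(out, "results/decay_fit.tsv")

cat(sprintf("Decay fit: y0 = %.2f, plateau = %.2f, k = %.3f /uM, r2 = %.4f\n",
            fit$y0, fit$plateau, fit$k, fit$r2))
cat(sprintf("Generating truth: y0 = %g, plateau = %g, k = %g (k error %.1f%%)\n",
            truth$y0, truth$plateau, truth$k,
            100 * abs(fit$k - truth$k) / truth$k))
cat("Parameters written to results/decay_fit.tsv\n")
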