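#!/usr/bin/env Rscript
# Stage 2: spectral binning and normalization.
#
# Reads the simulated cohort from stage 1, integrates each spectrum into
# 0.04-ppm bins over 0.6-8.6 ppm (excluding the residual-water window
# 4.64-5.2 and the noise region 5.28-6.6 ppm), normalizes each sample to
# percent total area, and serializes the samples x bins matrix.

library(epimetab)

spectra <- read_manifest("results/analysis/cohort/manifest.tsv")
grid <- build_bin_grid()
bm <- bin_cohort(spectra, grid)
write_bin_matrix(bm, "results/analysis/bin_matrix.tsv")

print(grid)
print(bm)
cat(sprintf("Row sums after percent normalization: %.6f .. %.6f\n",
            min(rowSums(bm$x)), max(rowSums(bm$x))))
cat("Wrote results/analysis/bin_matrix.tsv\n")
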