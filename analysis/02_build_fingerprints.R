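#!/usr/bin/env Rscript
# Step 2: load the simulated study from disk and build the co-possessing
# peak fingerprint matrices - one per detection wavelength plus the fused
# channel - via baseline subtraction, peak detection and cross-sample
# retention-time matching. Matrices are written under results/fingerprints/.

library(mwfp)

manifest <- "results/synthetic_study/manifest.csv"
if (!file.exists(manifest))
  stop("run analysis/01_simulate_study.R first")

study <- load_study(manifest)
mats <- build_fingerprints(study)

dir.create("results/fingerprints", recursive = TRUE, showWarnings = FALSE)
for (ch in names(mats)) {
  write_fingerprint_matrix(mats[[ch]],
                           sprintf("results/fingerprints/fingerprint_%s.csv", ch))
  cat(sprintf("%-6s %2d co-possessing peaks across %d samples\n",
              ch, length(mats[[ch]]$peak_rts), length(mats[[ch]]$sample_ids)))
}
cat("single channels see only the compound classes that absorb there;\n")
cat("the fused profile recovers the full constituent set.\n")
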