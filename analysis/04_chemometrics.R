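#!/usr/bin/env Rscript
# Step 4: multivariate analysis of the fused fingerprint matrix.
#
# Hierarchical clustering (between-groups linkage, squared Euclidean) on
# the normalised autoscaled matrix, PCA, and OPLS-DA with VIP scores to
# rank the peaks driving the origin separation.

library(mwfp)

fm_path <- "results/fingerprints/fingerprint_fused.csv"
if (!file.exists(fm_path)) stop("run analysis/02_build_fingerprints.R first")
fused <- read_fingerprint_matrix(fm_path, channel = "fused")
study <- load_study("results/synthetic_study/manifest.csv")
origin <- study$manifest$origin

tree <- hca(scale_columns(normalize_total(fused)))
cl <- cut_clusters(tree, 2)
mis <- cluster_misassignment(cl, origin)
write.csv(data.frame(sample_id = fused$sample_ids, origin = origin,
                     cluster = unname(cl)),
          "results/hca_clusters.csv", row.names = FALSE)
cat(sprintf("HCA 2-cluster cut misassigns %d of %d samples\n",
            mis, length(cl)))

pc <- pca(fused)
cat(sprintf("PCA explained variance: PC1 %.1f%%, PC2 %.1f%%\n",
            100 * pc$explained_variance[1], 100 * pc$explained_variance[2]))

op <- oplsda(fused, origin, n_orthogonal = 1)
vip_tab <- data.frame(peak_rt = fused$peak_rts, vip = unname(op$vip),
                      weight = op$weights)
vip_tab <- vip_tab[order(-vip_tab$vip), ]
write.csv(vip_tab, "results/opls_vip.csv", row.names = FALSE)
cat(sprintf("OPLS-DA R2Y = %.3f; %d of %d peaks have VIP > 1\n",
            op$r2y, sum(op$vip > 1), length(op$vip)))
cat("top discriminating retention times (min):",
    paste(sprintf("%.1f", head(vip_tab$peak_rt, 8)), collapse = ", "), "\n")
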