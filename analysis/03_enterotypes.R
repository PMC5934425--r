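#!/usr/bin/env Rscript
# Stage 3 — enterotypes and ordination.
#
# PAM clustering of the genus-level Jensen-Shannon distances with
# Calinski-Harabasz selection of the cluster number, agreement with the
# planted enterotype labels, and a centered PCA of the genus profile.

suppressPackageStartupMessages(library(gutimmune))

out <- "results"
gp <- read_profile(file.path(out, "profile_genus.tsv"),
                   kind = "relative", level = "genus")
truth <- jsonlite::read_json(file.path("results/data", "truth.json"))

et <- enterotype_samples(gp)
write.table(data.frame(sample_id = names(et$labels),
                       enterotype = et$labels,
                       silhouette = round(et$silhouette, 4)),
            file.path(out, "enterotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(k = names(et$ch_scores), ch = et$ch_scores),
            file.path(out, "ch_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

planted <- unlist(truth$enterotype_sample)[names(et$labels)]
ari <- if (requireNamespace("mclust", quietly = TRUE))
  mclust::adjustedRandIndex(et$labels, planted) else NA
message(sprintf("selected k = %d enterotypes (ARI vs planted labels: %s)",
                et$k, format(ari, digits = 3)))

ord <- pca_ordination(gp)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       round(ord$coordinates[, 1:4], 6)),
            file.path(out, "ordination.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PCA: PC1 %0.1f%%, PC2 %0.1f%% of variance",
                100 * ord$explained_variance[1],
                100 * ord$explained_variance[2]))
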