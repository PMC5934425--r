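#!/usr/bin/env Rscript
# Stage 6 — covariate effects and the species-immune-index network.
#
# Single-factor PERMANOVA (10,000 permutations) of group, timepoint, BMI
# and enterotype against the genus-level Jensen-Shannon distances, then a
# Spearman association network between species (mean relative abundance
# > 1e-7) and repertoire-derived immune indexes.

suppressPackageStartupMessages(library(gutimmune))

seed <- 42
out <- "results"
meta <- read.delim(file.path("results/data", "metadata.tsv"))
dm <- read_distance_matrix(file.path(out, "jsd_genus.tsv"))
meta <- meta[match(rownames(dm), meta$sample_id), ]
et <- read.delim(file.path(out, "enterotypes.tsv"))

covars <- list(group = meta$group, timepoint = meta$timepoint,
               bmi = meta$bmi,
               enterotype = factor(et$enterotype[match(rownames(dm),
                                                       et$sample_id)]))
perm <- do.call(rbind, lapply(names(covars), function(nm)
  permanova(dm, covars[[nm]], n_perm = 10000, seed = seed + 4, name = nm)))
write.table(perm, file.path(out, "permanova.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("PERMANOVA (10,000 permutations):")
for (i in seq_len(nrow(perm)))
  message(sprintf("  %-10s R2 = %0.3f, p = %0.4f", perm$covariate[i],
                  perm$R2[i], perm$p_perm[i]))

sp <- read_profile(file.path(out, "profile_species.tsv"),
                   kind = "relative", level = "species")
rs <- read.delim(file.path("results/data", "repertoire_summary.tsv"))
idx <- data.frame(sample_id = rs$sample_id,
                  bcr_diversity = rs$diversity_ratio,
                  bcr_d50 = rs$d50,
                  bcr_cdr3_len = rs$mean_cdr3_length)
net <- tryCatch(spearman_network(sp, idx),
                error = function(e) {
                  message("no network edges: ", conditionMessage(e))
                  data.frame()
                })
write.table(net, file.path(out, "network_edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("network: %d edges at p < 0.05 (%d positive, %d negative)",
                nrow(net), sum(net$sign == "positive"),
                sum(net$sign == "negative")))
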