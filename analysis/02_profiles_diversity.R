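#!/usr/bin/env Rscript
# Stage 2 — abundance profiles and diversity.
#
# Length-normalized relative gene abundances, aggregation to
# species/genus/phylum/KO, gene richness, Shannon alpha diversity, the
# genus-level Jensen-Shannon distance matrix, and within-subgroup beta
# diversity.

suppressPackageStartupMessages(library(gutimmune))

dat <- "results/data"
out <- "results"
catalog <- read.delim(file.path(dat, "catalog.tsv"))
counts <- read_profile(file.path(dat, "gene_counts.tsv"))
meta <- read.delim(file.path(dat, "metadata.tsv"))

rel <- relative_gene_abundance(counts, catalog)
profs <- lapply(setNames(nm = c("species", "genus", "phylum", "ko")),
                function(lv) aggregate_profile(rel, catalog, lv))
for (lv in names(profs))
  write_profile(profs[[lv]], file.path(out, paste0("profile_", lv, ".tsv")))

alpha <- data.frame(sample_id = colnames(rel),
                    gene_richness = richness(rel),
                    shannon_genus = shannon_index(profs$genus),
                    shannon_species = shannon_index(profs$species))
write.table(alpha, file.path(out, "alpha_diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("alpha diversity: genus Shannon %0.2f-%0.2f across %d samples",
                min(alpha$shannon_genus), max(alpha$shannon_genus),
                nrow(alpha)))

dm <- jsd_distance_matrix(profs$genus)
write_distance_matrix(dm, file.path(out, "jsd_genus.tsv"))

beta <- beta_diversity_within_group(
  dm, setNames(meta$subgroup, meta$sample_id))
beta_df <- data.frame(subgroup = rep(names(beta), lengths(beta)),
                      jsd = unlist(beta, use.names = FALSE))
write.table(beta_df, file.path(out, "beta_within_subgroup.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
med <- tapply(beta_df$jsd, beta_df$subgroup, median)
message("median within-subgroup genus JSD: ",
        paste(sprintf("%s=%0.3f", names(med), med), collapse = " "))
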