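#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Builds the synthetic stand-ins for the study's raw data: an annotated
# gene catalog, a 29-subject / two-timepoint metagenome cohort (15 study
# subjects switching to a lacto-ovo-vegetarian diet, 7 omnivorous and 7
# long-term vegetarian controls; subgroups A-F) with three enterotype
# components and a 4-fold diet effect planted on two species, plus paired
# BCR repertoires per subject. Everything downstream works from the TSVs
# written here.

suppressPackageStartupMessages(library(gutimmune))

seed <- 42
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

catalog <- simulate_catalog(n_genes = 2000, n_species = 60, n_genera = 25,
                            n_kos = 120, seed = seed)
write.table(catalog, file.path(out, "catalog.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# plant the diet effects on prevalent species (a probe run under the same
# seed identifies the two most abundant expected compositions)
probe <- simulate_metagenome_cohort(
  catalog, cohort_design(depth = 1e5, seed = seed + 1),
  mode = "frequency")
sp_mean <- rowMeans(sapply(probe$truth$component_means, identity))
targets <- probe$truth$species[order(-sp_mean)][1:2]
effects <- data.frame(feature_id = targets, level = "species",
                      multiplier = c(4, 0.25))
design <- cohort_design(diet_effects = effects, depth = 1e5,
                        seed = seed + 1)
cohort <- simulate_metagenome_cohort(catalog, design)

write_profile(cohort$profile, file.path(out, "gene_counts.tsv"))
write.table(cohort$metadata, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(enterotype_sample = as.list(cohort$truth$enterotype_sample),
       affected_features = cohort$truth$affected_features),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message("cohort: ", ncol(cohort$profile), " samples x ",
        nrow(cohort$profile), " genes; planted effects on ",
        paste(effects$feature_id, collapse = ", "))

# paired repertoires: one BCR pair per subject, moderate turnover
subjects <- unique(cohort$metadata$subject_id)
summaries <- list(); pairwise <- list()
for (i in seq_along(subjects)) {
  rd <- repertoire_design(n_clones = 2000, depth = 1e5, turnover = 0.8,
                          seed = seed + 100 + i)
  pair <- simulate_repertoire_pair(rd)
  for (tp in names(pair)) {
    tab <- pair[[tp]]
    attr(tab, "sample_id") <- paste0(subjects[i], "_", tp)
    summaries[[length(summaries) + 1L]] <- repertoire_summary(tab)
  }
  pairwise[[i]] <- data.frame(
    subject = subjects[i],
    delta_index = delta_index(pair$day0, pair$day91),
    shared_fraction = shared_cdr3_fraction(pair$day0, pair$day91))
}
write.table(do.call(rbind, summaries),
            file.path(out, "repertoire_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, pairwise),
            file.path(out, "repertoire_pairwise.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pw <- do.call(rbind, pairwise)
message(sprintf("repertoires: %d subjects; delta index %0.2f-%0.2f (median %0.2f)",
                length(subjects), min(pw$delta_index), max(pw$delta_index),
                median(pw$delta_index)))
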