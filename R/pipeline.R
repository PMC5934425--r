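#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates every stage on a simulated cohort and writes each stage's
#' TSV outputs plus a JSON run manifest (parameter values, seed, package
#' version, output checksums) to `outdir`. Given a fixed seed the run is
#' deterministic: re-running into a fresh directory reproduces every file
#' byte for byte.
#'
#' Stages: `simulate` (catalog, gene counts, metadata, truth),
#' `repstats` (per-subject repertoire summaries and delta indexes),
#' `profile` (species/genus/phylum/KO profiles), `diversity` (richness,
#' Shannon, genus JSD matrix, within-subgroup beta diversity),
#' `enterotype`, `diff` (paired day-0 vs day-91 differential abundance in
#' the study group), `reporter` (KO reporter scores, study vs control-1
#' post-diet samples), `permanova` (enterotype and group effects on the
#' genus profile) and `network` (species vs repertoire-derived immune
#' indexes).
#'
#' @param outdir output directory (created if absent).
#' @param seed master seed; stage seeds are derived from it.
#' @param catalog_args arguments for [simulate_catalog()].
#' @param design a [cohort_design()]; its `seed` is overridden by `seed`.
#' @param repertoire a [repertoire_design()] template for the per-subject
#'   repertoires.
#' @param n_pathways number of simulated pathways for the reporter stage.
#' @param n_perm PERMANOVA permutations (default 10000).
#' @param n_background reporter background sets (default 1000).
#' @param stages character vector of stage names to run (default all).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(outdir, seed = 1,
                         catalog_args = list(n_genes = 2000,
                                             n_species = 60,
                                             n_genera = 25, n_kos = 120),
                         design = cohort_design(),
                         repertoire = repertoire_design(n_clones = 2000,
                                                        depth = 1e5),
                         n_pathways = 20, n_perm = 10000,
                         n_background = 1000,
                         stages = c("simulate", "repstats", "profile",
                                    "diversity", "enterotype", "diff",
                                    "reporter", "permanova", "network")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(stage)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("gutimmune")),
                   parameters = list(
                     catalog = catalog_args,
                     depth = design$depth,
                     n_enterotypes = design$n_enterotypes,
                     concentration = design$concentration,
                     turnover = repertoire$turnover,
                     n0 = 1e7, top_m = 1000,
                     n_background = n_background, threshold = 1.96,
                     n_perm = n_perm, abundance_filter = 1e-7,
                     alpha = 0.05),
                   stages = stages)
  path <- function(f) file.path(outdir, f)

  log_stage("simulate")
  catalog <- do.call(simulate_catalog, c(catalog_args, list(seed = seed)))
  design$seed <- seed + 1L
  cohort <- simulate_metagenome_cohort(catalog, design)
  meta <- cohort$metadata
  if ("simulate" %in% stages) {
    utils::write.table(catalog, path("catalog.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_profile(cohort$profile, path("gene_counts.tsv"))
    utils::write.table(meta, path("metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(enterotype_sample = as.list(cohort$truth$enterotype_sample),
           affected_features = cohort$truth$affected_features),
      path("truth.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("repstats" %in% stages) {
    log_stage("repstats")
    subjects <- unique(meta$subject_id)
    rows <- list(); pairs <- list()
    for (i in seq_along(subjects)) {
      rd <- repertoire
      rd$seed <- seed + 100L + i
      rep_pair <- simulate_repertoire_pair(rd)
      for (tp in names(rep_pair)) {
        s <- rep_pair[[tp]]
        attr(s, "sample_id") <- paste0(subjects[i], "_", tp)
        rows[[length(rows) + 1L]] <- repertoire_summary(s)
      }
      pairs[[i]] <- data.frame(
        subject = subjects[i],
        delta_index = delta_index(rep_pair$day0, rep_pair$day91),
        shared_fraction = shared_cdr3_fraction(rep_pair$day0,
                                               rep_pair$day91),
        stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, rows), path("repertoire_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, pairs), path("repertoire_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_stage("profile")
  genes_rel <- if (profile_kind(cohort$profile) == "relative")
    cohort$profile else relative_gene_abundance(cohort$profile, catalog)
  profs <- lapply(stats::setNames(nm = c("species", "genus", "phylum",
                                         "ko")),
                  function(lv) aggregate_profile(genes_rel, catalog, lv))
  if ("profile" %in% stages)
    for (lv in names(profs))
      write_profile(profs[[lv]], path(paste0("profile_", lv, ".tsv")))

  dm_genus <- jsd_distance_matrix(profs$genus)
  if ("diversity" %in% stages) {
    log_stage("diversity")
    div <- data.frame(sample_id = colnames(genes_rel),
                      gene_richness = richness(genes_rel),
                      shannon_genus = shannon_index(profs$genus),
                      shannon_species = shannon_index(profs$species))
    utils::write.table(div, path("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_distance_matrix(dm_genus, path("jsd_genus.tsv"))
    beta <- beta_diversity_within_group(
      dm_genus, stats::setNames(meta$subgroup, meta$sample_id))
    beta_df <- data.frame(
      subgroup = rep(names(beta), lengths(beta)),
      jsd = unlist(beta, use.names = FALSE))
    utils::write.table(beta_df, path("beta_within_subgroup.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  et <- NULL
  if ("enterotype" %in% stages) {
    log_stage("enterotype")
    et <- enterotype_samples(profs$genus)
    utils::write.table(
      data.frame(sample_id = names(et$labels), enterotype = et$labels),
      path("enterotypes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(k = names(et$ch_scores), ch = et$ch_scores),
      path("ch_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    ord <- pca_ordination(profs$genus)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates),
                 ord$coordinates[, 1:min(4, ncol(ord$coordinates))]),
      path("ordination.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  if ("diff" %in% stages) {
    log_stage("diff")
    diff_res <- differential_abundance(profs$species, meta,
                                       groups = c("A", "B"),
                                       mode = "paired")
    utils::write.table(diff_res, path("differential_species.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("reporter" %in% stages) {
    log_stage("reporter")
    kos <- setdiff(rownames(profs$ko), "unannotated")
    map <- simulate_pathway_map(kos, n_pathways = n_pathways,
                                size_range = c(5, min(20, length(kos))),
                                seed = seed + 2L)
    sel <- meta$subgroup %in% c("B", "D")
    rep_res <- reporter_pipeline(
      profs$ko[kos, meta$sample_id[sel], drop = FALSE],
      groups = meta$subgroup[sel], map,
      n_background = n_background, seed = seed + 3L)
    utils::write.table(rep_res, path("reporter_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_pathway_map(map, path("pathway_map.tsv"))
  }

  if ("permanova" %in% stages) {
    log_stage("permanova")
    covars <- list(group = meta$group, timepoint = meta$timepoint,
                   bmi = meta$bmi)
    if (!is.null(et)) covars$enterotype <- factor(et$labels[meta$sample_id])
    perm <- do.call(rbind, lapply(names(covars), function(nm)
      permanova(dm_genus, covars[[nm]], n_perm = n_perm,
                seed = seed + 4L, name = nm)))
    utils::write.table(perm, path("permanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("network" %in% stages) {
    log_stage("network")
    rs_path <- path("repertoire_summary.tsv")
    if (!file.exists(rs_path))
      stop("network stage needs the repstats outputs; run 'repstats' first")
    rs <- utils::read.delim(rs_path)
    idx <- data.frame(sample_id = rs$sample_id,
                      bcr_diversity = rs$diversity_ratio,
                      bcr_d50 = rs$d50)
    net <- tryCatch(
      spearman_network(profs$species, idx),
      error = function(e) data.frame(species = character(),
                                     index = character(), rho = numeric(),
                                     p = numeric(), p_adj = numeric(),
                                     sign = character()))
    utils::write.table(net, path("network_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest$outputs <- as.list(tools::md5sum(outputs))
  names(manifest$outputs) <- basename(outputs)
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0,
                                              units = "secs"))
  mf <- manifest
  mf$elapsed_sec <- NULL  # keep manifest reproducible across runs
  jsonlite::write_json(mf, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
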