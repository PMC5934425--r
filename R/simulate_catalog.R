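#' Simulate a gene catalog
#'
#' Generates a synthetic stand-in for an annotated microbial gene catalog:
#' unique gene ids with lengths, a nested species/genus/phylum taxonomy
#' (each species under exactly one genus, each genus under one phylum,
#' every species holding at least one gene), and KO assignments for a
#' configurable fraction of genes.
#'
#' @param n_genes,n_species,n_genera number of genes, species, genera
#'   (`n_species <= n_genes`, `n_genera <= n_species`).
#' @param n_kos number of distinct KO labels to draw assignments from.
#' @param length_range gene length bounds in bp, within \[100, 50000\].
#' @param n_phyla number of phyla (default about one per three genera).
#' @param ko_missing_fraction fraction of genes left without a KO
#'   (default 0.2).
#' @param seed integer seed; the same seed reproduces the catalog exactly.
#' @return data.frame with columns `gene_id`, `length_bp`, `phylum`,
#'   `genus`, `species`, `ko` (NA when unassigned).
#' @export
simulate_catalog <- function(n_genes, n_species, n_genera, n_kos,
                             length_range = c(500, 5000), n_phyla = NULL,
                             ko_missing_fraction = 0.2, seed = NULL) {
  if (n_species > n_genes)
    stop("n_species must not exceed n_genes")
  if (n_genera > n_species)
    stop("n_genera must not exceed n_species")
  if (is.null(n_phyla)) n_phyla <- max(1L, ceiling(n_genera / 3))
  if (n_phyla > n_genera)
    stop("n_phyla must not exceed n_genera")
  if (min(n_genes, n_species, n_genera, n_kos, n_phyla) < 1)
    stop("all cardinalities must be at least 1")
  if (length_range[1] < 100 || length_range[2] > 50000 ||
      length_range[1] > length_range[2])
    stop("length_range must lie within [100, 50000]")
  if (ko_missing_fraction < 0 || ko_missing_fraction > 1)
    stop("ko_missing_fraction must lie in [0, 1]")
  with_seed(seed, {
    # every species gets one gene, the rest are spread uniformly
    sp_of_gene <- c(seq_len(n_species),
                    if (n_genes > n_species)
                      sample.int(n_species, n_genes - n_species,
                                 replace = TRUE))
    gen_of_sp <- c(seq_len(n_genera),
                   if (n_species > n_genera)
                     sample.int(n_genera, n_species - n_genera,
                                replace = TRUE))
    phy_of_gen <- c(seq_len(n_phyla),
                    if (n_genera > n_phyla)
                      sample.int(n_phyla, n_genera - n_phyla,
                                 replace = TRUE))
    length_bp <- sample(length_range[1]:length_range[2], n_genes,
                        replace = TRUE)
    ko <- sprintf("K%05d", sample.int(n_kos, n_genes, replace = TRUE))
    ko[sample.int(n_genes, round(ko_missing_fraction * n_genes))] <- NA
    data.frame(
      gene_id = sprintf("gene_%06d", seq_len(n_genes)),
      length_bp = length_bp,
      phylum = sprintf("phylum_%02d", phy_of_gen[gen_of_sp[sp_of_gene]]),
      genus = sprintf("genus_%03d", gen_of_sp[sp_of_gene]),
      species = sprintf("species_%04d", sp_of_gene),
      ko = ko,
      stringsAsFactors = FALSE)
  })
}

#' Validate gene-catalog invariants
#'
#' Checks gene-id uniqueness, positive lengths, and that the
#' species-to-genus and genus-to-phylum mappings are functions (no species
#' under two genera).
#'
#' @param catalog a catalog data.frame (see [simulate_catalog()]).
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_catalog <- function(catalog) {
  required <- c("gene_id", "length_bp", "phylum", "genus", "species")
  miss <- setdiff(required, names(catalog))
  if (length(miss) > 0)
    stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(catalog$gene_id) > 0)
    stop("duplicate gene ids")
  if (any(catalog$length_bp < 1))
    stop("gene lengths must be >= 1")
  if (anyDuplicated(unique(catalog[c("species", "genus")])$species) > 0)
    stop("a species maps to more than one genus")
  if (anyDuplicated(unique(catalog[c("genus", "phylum")])$genus) > 0)
    stop("a genus maps to more than one phylum")
  invisible(TRUE)
}

#' Simulate a pathway/module membership map
#'
#' Draws random KO member sets for a given number of pathways — synthetic
#' plumbing for exercising the reporter-score stage without the curated
#' KEGG hierarchy.
#'
#' @param kos character vector of available KO ids.
#' @param n_pathways number of pathways.
#' @param size_range inclusive bounds on members per pathway.
#' @param seed integer seed.
#' @return named list: pathway id -> member KO ids.
#' @export
simulate_pathway_map <- function(kos, n_pathways, size_range = c(5, 20),
                                 seed = NULL) {
  stopifnot(n_pathways >= 1, size_range[1] >= 1,
            size_range[2] <= length(kos))
  with_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    map <- lapply(sizes, function(s) sample(kos, s))
    names(map) <- sprintf("path_%03d", seq_len(n_pathways))
    map
  })
}
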