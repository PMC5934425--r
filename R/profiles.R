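#' Abundance profile container
#'
#' A feature-by-sample nonnegative matrix carrying its aggregation level
#' (gene, species, genus, phylum, ko) and kind (raw counts or relative
#' abundances). Relative profiles have columns summing to 1, unless the
#' `partial` flag marks a profile from which an "unannotated" bucket was
#' dropped.
#'
#' @param mat numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param kind `"counts"` or `"relative"`.
#' @param level `"gene"`, `"species"`, `"genus"`, `"phylum"` or `"ko"`.
#' @param partial logical; TRUE when relative columns deliberately sum to
#'   less than 1 (unannotated mass removed).
#' @return the matrix with class `abundance_profile` and attributes.
#' @export
abundance_profile <- function(mat, kind = c("counts", "relative"),
                              level = c("gene", "species", "genus",
                                        "phylum", "ko"),
                              partial = FALSE) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("abundance profile needs feature rownames and sample colnames")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("abundance values must be finite and nonnegative")
  if (kind == "relative" && !partial) {
    cs <- colSums(mat)
    if (any(abs(cs - 1) > 1e-9))
      stop("relative profile columns must sum to 1 (off by up to ",
           format(max(abs(cs - 1))), ")")
  }
  structure(mat, class = c("abundance_profile", "matrix", "array"),
            kind = kind, level = level, partial = partial)
}

profile_kind <- function(x) attr(x, "kind")
profile_level <- function(x) attr(x, "level")

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("Abundance profile: %d %s features x %d samples (%s)\n",
              nrow(x), profile_level(x), ncol(x), profile_kind(x)))
  invisible(x)
}

#' Length-normalized relative gene abundance
#'
#' Converts per-gene read counts to relative gene abundances by dividing
#' each count by the gene length and renormalizing per sample:
#' `a_i = (x_i / L_i) / sum_j (x_j / L_j)`. Length normalization corrects
#' for longer genes recruiting proportionally more reads; it can be
#' disabled for toy inputs.
#'
#' @param counts numeric matrix of read counts, genes in rows (rownames =
#'   gene ids), samples in columns; a named vector is treated as one sample.
#' @param catalog gene catalog (see [simulate_catalog()]) supplying
#'   `gene_id` and `length_bp`.
#' @param length_normalize divide by gene length before renormalizing
#'   (default TRUE).
#' @return gene-level relative [abundance_profile()].
#' @export
relative_gene_abundance <- function(counts, catalog, length_normalize = TRUE) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(counts), "sample"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must carry gene ids as rownames")
  unknown <- setdiff(rownames(counts), catalog$gene_id)
  if (length(unknown) > 0L)
    stop("gene id(s) absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  if (length_normalize) {
    len <- catalog$length_bp[match(rownames(counts), catalog$gene_id)]
    counts <- counts / len
  }
  rel <- sweep(counts, 2, colSums(counts), "/")
  abundance_profile(rel, kind = "relative", level = "gene")
}

#' Aggregate a gene profile to taxon or KO level
#'
#' Each output feature's abundance is the sum of its member genes'
#' abundances. Genes lacking the annotation (e.g. no KO assignment) are
#' pooled into an `"unannotated"` bucket, kept by default so that mass is
#' conserved; `drop_unannotated = TRUE` removes the bucket and renormalizes
#' columns to 1.
#'
#' @param genes gene-level relative [abundance_profile()].
#' @param catalog gene catalog with `species`, `genus`, `phylum`, `ko`.
#' @param level target level: `"species"`, `"genus"`, `"phylum"` or `"ko"`.
#' @param drop_unannotated drop the unannotated bucket and renormalize.
#' @return relative [abundance_profile()] at the requested level.
#' @export
aggregate_profile <- function(genes, catalog,
                              level = c("species", "genus", "phylum", "ko"),
                              drop_unannotated = FALSE) {
  level <- match.arg(level)
  if (!inherits(genes, "abundance_profile") || profile_kind(genes) != "relative" ||
      profile_level(genes) != "gene")
    stop("aggregate_profile expects a gene-level relative profile")
  lab <- as.character(catalog[[level]][match(rownames(genes), catalog$gene_id)])
  lab[is.na(lab) | !nzchar(lab)] <- "unannotated"
  agg <- rowsum(unclass(genes), group = lab, reorder = TRUE)
  if (drop_unannotated && "unannotated" %in% rownames(agg)) {
    agg <- agg[rownames(agg) != "unannotated", , drop = FALSE]
    agg <- sweep(agg, 2, colSums(agg), "/")
  }
  abundance_profile(agg, kind = "relative", level = level,
                    partial = FALSE)
}

#' Per-sample feature richness
#'
#' Number of features observed (abundance strictly positive) per sample.
#'
#' @param profile an [abundance_profile()].
#' @return named integer vector, one entry per sample.
#' @export
richness <- function(profile) {
  if (length(profile) == 0L) stop("profile is empty")
  colSums(unclass(profile) > 0)
}

#' Shannon alpha diversity
#'
#' `H = -sum(p_i * log(p_i))` over features with positive abundance, using
#' the natural logarithm by default. Count profiles are normalized per
#' sample first.
#'
#' @param profile an [abundance_profile()] (counts or relative).
#' @param base logarithm base (default `exp(1)`; use 2 for bits).
#' @return named numeric vector of per-sample Shannon indexes.
#' @export
shannon_index <- function(profile, base = exp(1)) {
  mat <- unclass(as.matrix(profile))
  cs <- colSums(mat)
  if (any(cs == 0))
    stop("sample(s) with all-zero abundance: ",
         paste(colnames(mat)[cs == 0], collapse = ", "))
  p <- sweep(mat, 2, cs, "/")
  apply(p, 2, function(col) {
    col <- col[col > 0]
    -sum(col * log(col, base = base))
  })
}
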