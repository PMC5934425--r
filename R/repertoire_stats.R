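#' Repertoire diversity ratio
#'
#' Diversity of a repertoire defined as the number of unique clones divided
#' by the total number of sequenced reads, in (0, 1]. A value near 1 means
#' almost every read is a distinct clone; low values indicate clonal
#' expansion.
#'
#' @param table a [clone_table()].
#' @param key a [clone_key()] defining clone identity.
#' @return fraction in (0, 1].
#' @export
diversity_ratio <- function(table, key = clone_key()) {
  if (is.null(table) || nrow(table) == 0L)
    stop("clone table is empty")
  counts <- collapse_clones(table, key)
  length(counts) / sum(counts)
}

#' D50 clonality statistic
#'
#' Percent of unique clones (ranked by read count, largest first) needed to
#' account for the cumulative 50% of total reads: `100 * X / Y` where `X` is
#' the smallest number of top clones whose cumulative count reaches at least
#' half the reads and `Y` is the number of unique clones. Low D50 indicates
#' a repertoire skewed by large clonal expansions; a perfectly even
#' repertoire with an even number of clones gives exactly 50.
#'
#' Ties at the 50% boundary are resolved deterministically: clones are
#' sorted by count descending, then lexicographically by clone key.
#'
#' @inheritParams diversity_ratio
#' @return percent in (0, 100].
#' @export
d50 <- function(table, key = clone_key()) {
  if (is.null(table) || nrow(table) == 0L)
    stop("clone table is empty")
  counts <- collapse_clones(table, key)
  ord <- order(-counts, names(counts), method = "radix")
  counts <- counts[ord]
  total <- sum(counts)
  x <- unname(which(cumsum(counts) >= 0.5 * total)[1L])
  100 * x / length(counts)
}

#' Delta index: repertoire turnover between two timepoints
#'
#' Per sample, clone counts are converted to frequencies (computationally
#' equivalent to normalizing each sample to `n0` reads and dividing by
#' `n0`). Over the union of clone keys the absolute frequency difference
#' `d_c = |f_a(c) - f_b(c)|` is computed, clones are ranked by the
#' configured basis, and the sum of `d_c` over the top
#' `min(top_m, |union|)` clones is returned. The result lies in `[0, 2]`:
#' 0 for identical samples, 2 for samples sharing no clones when the union
#' has at most `top_m` members.
#'
#' @param a,b [clone_table()]s for the two timepoints (same chain).
#' @param key a [clone_key()].
#' @param top_m number of top-ranked clones summed (default 1000).
#' @param n0 normalization read target kept for provenance (default 1e7);
#'   the computation uses exact fractions, which is equivalent.
#' @param rank_by ranking basis for "most common": `"difference"` (default;
#'   rank by `d_c` descending) or `"max_frequency"` (rank by the larger of
#'   the two frequencies).
#' @return value in \[0, 2\].
#' @export
delta_index <- function(a, b, key = clone_key(), top_m = 1000, n0 = 1e7,
                        rank_by = c("difference", "max_frequency")) {
  rank_by <- match.arg(rank_by)
  if (is.null(a) || nrow(a) == 0L || is.null(b) || nrow(b) == 0L)
    stop("clone tables must be non-empty")
  if (!identical(clone_chain(a), clone_chain(b)))
    stop("chain mismatch: ", clone_chain(a), " vs ", clone_chain(b))
  stopifnot(top_m >= 1, n0 > 0)
  fa <- collapse_clones(a, key); fa <- fa / sum(fa)
  fb <- collapse_clones(b, key); fb <- fb / sum(fb)
  keys <- union(names(fa), names(fb))
  f0 <- f1 <- stats::setNames(numeric(length(keys)), keys)
  f0[names(fa)] <- fa
  f1[names(fb)] <- fb
  d <- abs(f0 - f1)
  basis <- if (rank_by == "difference") d else pmax(f0, f1)
  ord <- order(-basis, keys, method = "radix")
  sum(d[ord][seq_len(min(top_m, length(keys)))])
}

#' Gene-usage frequency tables
#'
#' Share of distinct clone keys carried by each V gene, V-gene family, or
#' immunoglobulin isotype. V-gene and V-family usage is computed over
#' unique CDR3-V-J combinations; isotype usage over unique Ig-CDR3-C-J
#' combinations, so a CDR3 expressed with two isotypes contributes to both.
#' The V family is the gene label prefix before the first hyphen
#' (IGHV5-51 -> IGHV5). C-gene calls that do not resolve to
#' IgD/IgM/IgG/IgA/IgE are reported as `"unknown"`.
#'
#' @inheritParams diversity_ratio
#' @param by grouping level: `"v_gene"`, `"v_family"`, or `"isotype"`
#'   (isotype only meaningful for IGH).
#' @param key clone key; defaults to CDR3-V-J, or CDR3-C-J when
#'   `by = "isotype"`.
#' @return named numeric vector of frequencies summing to 1.
#' @export
usage_frequencies <- function(table, by = c("v_gene", "v_family", "isotype"),
                              key = NULL) {
  by <- match.arg(by)
  if (is.null(table) || nrow(table) == 0L)
    stop("clone table is empty")
  if (by == "isotype") {
    if (clone_chain(table) != "IGH")
      stop("isotype usage is only defined for IGH (BCR) tables")
    if (!"c_gene" %in% names(table))
      stop("isotype usage requires a c_gene column")
    if (is.null(key)) key <- clone_key(c("cdr3_aa", "c_gene", "j_gene"))
  } else if (is.null(key)) {
    key <- clone_key()
  }
  df <- as.data.frame(table)
  keep <- !duplicated(clone_ids(df, key))
  df <- df[keep, , drop = FALSE]
  label <- switch(by,
    v_gene = df$v_gene,
    v_family = sub("-.*$", "", df$v_gene),
    isotype = isotype_class(df$c_gene))
  tab <- table(label)
  freqs <- as.numeric(tab) / sum(tab)
  stats::setNames(freqs, names(tab))
}

# Map C-gene calls to isotype classes; anything unrecognized -> "unknown".
isotype_class <- function(c_gene) {
  c_gene <- toupper(as.character(c_gene))
  out <- rep("unknown", length(c_gene))
  out[startsWith(c_gene, "IGHD") | c_gene == "IGD"] <- "IgD"
  out[startsWith(c_gene, "IGHM") | c_gene == "IGM"] <- "IgM"
  out[startsWith(c_gene, "IGHG") | c_gene == "IGG"] <- "IgG"
  out[startsWith(c_gene, "IGHA") | c_gene == "IGA"] <- "IgA"
  out[startsWith(c_gene, "IGHE") | c_gene == "IGE"] <- "IgE"
  out
}

#' Fraction of clones shared between two repertoires
#'
#' Jaccard index over clone keys by default:
#' `|keys(a) intersect keys(b)| / |keys(a) union keys(b)|`. The
#' overlap coefficient (intersection over the smaller repertoire) is
#' available as an option.
#'
#' @inheritParams delta_index
#' @param method `"jaccard"` (default) or `"overlap"`.
#' @return fraction in \[0, 1\].
#' @export
shared_cdr3_fraction <- function(a, b, key = clone_key(),
                                 method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  if (is.null(a) || nrow(a) == 0L || is.null(b) || nrow(b) == 0L)
    stop("clone tables must be non-empty")
  if (!identical(clone_chain(a), clone_chain(b)))
    stop("chain mismatch: ", clone_chain(a), " vs ", clone_chain(b))
  ka <- unique(clone_ids(a, key))
  kb <- unique(clone_ids(b, key))
  inter <- length(intersect(ka, kb))
  denom <- switch(method,
    jaccard = length(union(ka, kb)),
    overlap = min(length(ka), length(kb)))
  inter / denom
}

#' Mean CDR3 length
#'
#' Arithmetic mean amino-acid length of the CDR3 region, either over
#' distinct clones (default) or weighted by read count.
#'
#' @inheritParams diversity_ratio
#' @param weighting `"by_clone"` (each distinct clone once) or `"by_read"`.
#' @return mean length in amino acids.
#' @export
mean_cdr3_length <- function(table, weighting = c("by_clone", "by_read"),
                             key = clone_key()) {
  weighting <- match.arg(weighting)
  if (is.null(table) || nrow(table) == 0L)
    stop("clone table is empty")
  df <- as.data.frame(table)
  if (anyNA(df$cdr3_aa) || any(!nzchar(df$cdr3_aa)))
    stop("cdr3_aa contains empty sequences")
  ids <- clone_ids(df, key)
  keep <- !duplicated(ids)
  len <- nchar(df$cdr3_aa[keep])
  if (weighting == "by_clone") {
    mean(len)
  } else {
    counts <- collapse_clones(df, key)[ids[keep]]
    sum(len * counts) / sum(counts)
  }
}

#' Per-sample repertoire summary
#'
#' One row of headline statistics for a clone table: total reads, unique
#' clones, diversity ratio, D50 and mean CDR3 length.
#'
#' @inheritParams diversity_ratio
#' @return one-row data.frame.
#' @export
repertoire_summary <- function(table, key = clone_key()) {
  counts <- collapse_clones(table, key)
  data.frame(
    sample_id = clone_sample_id(table),
    chain = clone_chain(table),
    total_reads = sum(counts),
    unique_clones = length(counts),
    diversity_ratio = diversity_ratio(table, key),
    d50 = d50(table, key),
    mean_cdr3_length = mean_cdr3_length(table, key = key),
    stringsAsFactors = FALSE)
}
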