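#' Construct a clone table
#'
#' A clone table is the unit of all repertoire statistics: one row per
#' observed clone (CDR3 sequence plus V/D/J and, for BCR heavy chains, the
#' constant-region gene call) with a read count. Clone identity for the
#' statistics is defined by a [clone_key()]; by default a clone is a unique
#' CDR3 amino-acid sequence combined with its V and J gene calls.
#'
#' @param x data.frame with at least columns `cdr3_aa`, `v_gene`, `j_gene`
#'   and `count`; `cdr3_nt`, `d_gene` and `c_gene` are optional. `count` may
#'   be fractional when the table stores exact clone frequencies rather than
#'   sampled reads (frequency mode of the simulator).
#' @param sample_id sample identifier, stored as an attribute.
#' @param chain receptor chain: `"IGH"` (BCR heavy) or `"TRB"` (TCR beta).
#' @return `x` with class `clone_table` and attributes `sample_id`, `chain`.
#' @examples
#' tab <- clone_table(data.frame(
#'   cdr3_aa = c("CARGW", "CASSL"), v_gene = c("IGHV3-23", "IGHV1-2"),
#'   j_gene = c("IGHJ4", "IGHJ6"), count = c(10, 5)))
#' diversity_ratio(tab)
#' @export
clone_table <- function(x, sample_id = "sample", chain = c("IGH", "TRB")) {
  chain <- match.arg(chain)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("cdr3_aa", "v_gene", "j_gene", "count")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L)
    stop("clone table lacks required column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L)
    stop("clone table is empty")
  if (!is.numeric(x$count) || anyNA(x$count) || any(!is.finite(x$count)) ||
      any(x$count <= 0))
    stop("clone counts must be positive and finite")
  structure(x,
            class = unique(c("clone_table", class(x))),
            sample_id = sample_id, chain = chain)
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf("Clone table '%s' (%s): %d clones, %s total reads\n",
              clone_sample_id(x), clone_chain(x), nrow(x),
              format(sum(x$count))))
  invisible(x)
}

clone_chain <- function(x) {
  ch <- attr(x, "chain")
  if (is.null(ch)) "IGH" else ch
}

clone_sample_id <- function(x) {
  id <- attr(x, "sample_id")
  if (is.null(id)) "sample" else id
}

#' Clone-identity key
#'
#' The tuple of columns that defines clone identity. The default
#' `c("cdr3_aa", "v_gene", "j_gene")` treats each unique CDR3-V-J
#' combination as one clone; isotype tables use
#' `c("cdr3_aa", "c_gene", "j_gene")` so that the same CDR3 expressed with
#' two isotypes counts once per Ig-CDR3-C-J combination. Nucleotide-level
#' identity is available by keying on `cdr3_nt`.
#'
#' @param columns character vector of clone-table column names.
#' @return the validated key (character vector, class `clone_key`).
#' @export
clone_key <- function(columns = c("cdr3_aa", "v_gene", "j_gene")) {
  stopifnot(is.character(columns), length(columns) >= 1L)
  structure(columns, class = "clone_key")
}

# One string id per row under the key; "\r" never occurs in gene labels
# or CDR3 sequences, so pasting is collision-free.
clone_ids <- function(table, key) {
  miss <- setdiff(unclass(key), names(table))
  if (length(miss) > 0L)
    stop("clone key column(s) absent from table: ", paste(miss, collapse = ", "))
  do.call(paste, c(unname(as.list(as.data.frame(table)[unclass(key)])),
                   sep = "\r"))
}

# Collapse counts over the clone key: named vector of per-clone counts.
collapse_clones <- function(table, key) {
  ids <- clone_ids(table, key)
  counts <- rowsum(table$count, group = ids, reorder = TRUE)
  stats::setNames(as.numeric(counts), rownames(counts))
}

#' Read a clone table from TSV
#'
#' Accepts the native header (`cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`,
#' `j_gene`, `c_gene`, `count`) as well as AIRR Rearrangement column names
#' (`junction`, `junction_aa`, `v_call`, `d_call`, `j_call`, `c_call`,
#' `duplicate_count`), which are renamed on input.
#'
#' @param path TSV file with a header row.
#' @inheritParams clone_table
#' @return a [clone_table()].
#' @export
read_clone_table <- function(path, sample_id = basename(path),
                             chain = c("IGH", "TRB")) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  airr <- c(junction = "cdr3_nt", junction_aa = "cdr3_aa", v_call = "v_gene",
            d_call = "d_gene", j_call = "j_gene", c_call = "c_gene",
            duplicate_count = "count")
  hit <- names(airr)[names(airr) %in% names(x)]
  names(x)[match(hit, names(x))] <- airr[hit]
  clone_table(x, sample_id = sample_id, chain = match.arg(chain))
}

#' Write a clone table to TSV
#' @param x a [clone_table()].
#' @param path output file.
#' @export
write_clone_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
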