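#' Jensen-Shannon distance between two composition vectors
#'
#' `d(p, q) = sqrt( KL(p||m)/2 + KL(q||m)/2 )` with `m = (p+q)/2`, natural
#' logarithm, and the convention `0 * log 0 = 0`. With no pseudocount the
#' computation is exact on sparse compositions and the distance is bounded
#' by `sqrt(log 2)`, attained for disjoint support. A small zero-replacement
#' value can be supplied to mimic protocols that smooth zeros before
#' computing the divergence.
#'
#' @param p,q nonnegative vectors of equal length, each summing to 1
#'   (tolerance 1e-9).
#' @param zero_replace optional small value substituted for zero entries
#'   (both vectors renormalized afterwards); default NULL (exact).
#' @return distance in `[0, sqrt(log 2)]`.
#' @export
jsd_distance <- function(p, q, zero_replace = NULL) {
  if (length(p) != length(q))
    stop("length mismatch: ", length(p), " vs ", length(q))
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("inputs must each sum to 1")
  if (any(p < 0) || any(q < 0))
    stop("inputs must be nonnegative")
  if (!is.null(zero_replace)) {
    p[p == 0] <- zero_replace
    q[q == 0] <- zero_replace
    p <- p / sum(p)
    q <- q / sum(q)
  }
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  d2 <- 0.5 * kl(p) + 0.5 * kl(q)
  sqrt(max(d2, 0))
}

#' Pairwise Jensen-Shannon distance matrix
#'
#' All pairwise [jsd_distance()] values between the samples (columns) of a
#' relative abundance profile; counts are normalized per sample first.
#'
#' @param profile an [abundance_profile()] or plain feature-by-sample
#'   matrix with at least 2 samples.
#' @param zero_replace passed to [jsd_distance()].
#' @return symmetric matrix with zero diagonal and sample ids as dimnames.
#' @export
jsd_distance_matrix <- function(profile, zero_replace = NULL) {
  mat <- unclass(as.matrix(profile))
  n <- ncol(mat)
  if (n < 2) stop("need at least 2 samples")
  mat <- sweep(mat, 2, colSums(mat), "/")
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <- jsd_distance(mat[, i], mat[, j],
                                         zero_replace = zero_replace)
    }
  }
  d
}

#' Within-group beta-diversity distributions
#'
#' For each group, the pairwise distances among its member samples — the
#' quantity summarized by per-subgroup beta-diversity violin plots. Groups
#' with fewer than 2 samples are excluded with a warning.
#'
#' @param dm symmetric distance matrix with sample ids as dimnames.
#' @param groups named vector (names = sample ids) or vector aligned with
#'   the matrix order, giving each sample's group.
#' @return named list: per group, the numeric vector of its
#'   `choose(n_g, 2)` within-group distances.
#' @export
beta_diversity_within_group <- function(dm, groups) {
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  if (!is.null(names(groups))) groups <- groups[ids]
  if (length(groups) != nrow(dm))
    stop("groups must align with the distance matrix")
  out <- list()
  for (g in unique(as.character(groups))) {
    idx <- which(as.character(groups) == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has fewer than 2 samples; excluded")
      next
    }
    sub <- dm[idx, idx, drop = FALSE]
    out[[g]] <- sub[lower.tri(sub)]
  }
  out
}

#' Write / read a square distance matrix as TSV
#' @param dm symmetric matrix with sample-id dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), as.data.frame(dm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
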