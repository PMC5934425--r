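#' Paired Wilcoxon signed-rank test (two-sided)
#'
#' Exact p after dropping zero differences: via the signed-rank
#' distribution when the absolute differences are untied (up to 49 pairs),
#' or by enumerating all 2^n sign patterns of the midranks when ties are
#' present and at most 12 pairs remain.
#' Larger samples use the normal approximation with Pratt handling of
#' zeros (zeros participate in ranking, their ranks are then discarded),
#' midrank tie correction, and continuity correction.
#'
#' @param before,after paired numeric vectors of equal length.
#' @return two-sided p-value.
#' @export
paired_signed_rank <- function(before, after) {
  if (length(before) != length(after))
    stop("before/after must have equal length")
  d <- after - before
  if (all(d == 0)) stop("all paired differences are zero")
  nz <- d[d != 0]
  n <- length(nz)
  untied <- anyDuplicated(abs(nz)) == 0
  if (n >= 2 && ((untied && n < 50) || (!untied && n <= 12))) {
    r <- rank(abs(nz))
    v <- sum(r[nz > 0])
    if (untied) {
      p <- 2 * min(stats::psignrank(v, n),
                   stats::psignrank(v - 1, n, lower.tail = FALSE))
    } else {
      # tied |d|: enumerate all 2^n sign assignments of the midranks
      sums <- 0
      for (ri in r) sums <- c(sums, sums + ri)
      p <- 2 * min(mean(sums <= v + 1e-12), mean(sums >= v - 1e-12))
    }
    return(min(1, p))
  }
  # Pratt: rank |d| including zeros, drop the zero ranks from V and the
  # moments.
  n0 <- sum(d == 0)
  N <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- (N * (N + 1) - n0 * (n0 + 1)) / 4
  tie_tab <- table(r[d != 0])
  tie_term <- sum(tie_tab^3 - tie_tab) / 48
  sigma2 <- N * (N + 1) * (2 * N + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 - tie_term
  if (sigma2 <= 0) stop("degenerate signed-rank variance")
  z <- v - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Differential abundance between two sample groups
#'
#' Per feature, a two-sided Wilcoxon test: the signed-rank test on
#' subject-matched pairs (e.g. day 0 vs day 91 within the diet group) or
#' the rank-sum test on independent groups (e.g. the two control groups).
#' Features constant across all used samples — and, in paired mode,
#' features whose paired differences are all zero — are excluded with a
#' warning. Raw p-values drive the `significant` flag (the conventional
#' p < alpha call); BH-adjusted p-values are reported alongside.
#'
#' @param profile feature-by-sample [abundance_profile()] (or matrix).
#' @param metadata data.frame with columns `sample_id`, `subject_id` and
#'   the grouping column.
#' @param groups length-2 character vector: the two values of `group_col`
#'   to compare (first = reference / "before" side in paired mode).
#' @param mode `"paired"` (signed-rank, subjects matched across the two
#'   groups) or `"unpaired"` (rank-sum).
#' @param group_col metadata column holding the group labels
#'   (default `"subgroup"`).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return data.frame sorted by p: `feature`, `level`, `test`, `p`,
#'   `p_adj`, `direction`, `median_1`, `median_2`, `significant`.
#' @export
differential_abundance <- function(profile, metadata, groups,
                                   mode = c("paired", "unpaired"),
                                   group_col = "subgroup", alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(groups) == 2)
  mat <- unclass(as.matrix(profile))
  level <- if (inherits(profile, "abundance_profile"))
    profile_level(profile) else "feature"
  md <- metadata[metadata[[group_col]] %in% groups, , drop = FALSE]
  if (!all(md$sample_id %in% colnames(mat)))
    stop("metadata sample(s) missing from profile: ",
         paste(setdiff(md$sample_id, colnames(mat)), collapse = ", "))
  s1 <- md$sample_id[md[[group_col]] == groups[1L]]
  s2 <- md$sample_id[md[[group_col]] == groups[2L]]
  if (length(s1) == 0 || length(s2) == 0)
    stop("group(s) not found in metadata: ", paste(groups, collapse = ", "))
  if (mode == "paired") {
    sub1 <- md$subject_id[match(s1, md$sample_id)]
    sub2 <- md$subject_id[match(s2, md$sample_id)]
    unmatched <- c(setdiff(sub1, sub2), setdiff(sub2, sub1))
    if (length(unmatched) > 0)
      stop("subject(s) without samples at both groups: ",
           paste(unique(unmatched), collapse = ", "))
    s2 <- s2[match(sub1, sub2)]
  }
  m1 <- mat[, s1, drop = FALSE]
  m2 <- mat[, s2, drop = FALSE]
  test_name <- if (mode == "paired") "signed_rank_paired" else
    "rank_sum_unpaired"
  res <- lapply(rownames(mat), function(f) {
    a <- m1[f, ]; b <- m2[f, ]
    if (diff(range(c(a, b))) == 0) return(NULL)            # constant feature
    if (mode == "paired") {
      if (all(b - a == 0)) return(NULL)                    # no paired signal
      p <- paired_signed_rank(a, b)
    } else {
      p <- suppressWarnings(stats::wilcox.test(
        a, b, exact = (length(a) + length(b) <= 12) &&
          anyDuplicated(c(a, b)) == 0)$p.value)
    }
    med1 <- stats::median(a); med2 <- stats::median(b)
    data.frame(feature = f, level = level, test = test_name, p = unname(p),
               direction = if (med2 > med1) groups[2L] else if (med2 < med1)
                 groups[1L] else "none",
               median_1 = med1, median_2 = med2, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " constant/zero-difference feature(s) excluded")
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no testable features")
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p < alpha
  res[order(res$p, res$feature), ]
}

#' Single-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for one covariate.
#' The squared distances are Gower-centered into the inner-product matrix
#' `G`; the covariate's hat matrix `H` (one-hot groups for a categorical
#' factor, centered column for a numeric covariate) gives
#' `pseudo-F = [tr(HGH)/(m-1)] / [tr((I-H)G(I-H))/(n-m)]` and
#' `R^2 = tr(HGH)/tr(G)`. The p-value is the permutation estimate
#' `(1 + #[F_perm >= F_obs]) / (1 + n_perm)`, never exactly zero.
#'
#' @param dm symmetric distance matrix (n >= 4 samples).
#' @param covariate vector aligned with the matrix: factor/character
#'   (categorical) or numeric.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed for the permutation stream (NULL = current
#'   RNG state).
#' @param name covariate name carried into the result.
#' @return one-row data.frame: `covariate`, `pseudo_F`, `R2`, `p_perm`,
#'   `n_perm`.
#' @export
permanova <- function(dm, covariate, n_perm = 10000, seed = NULL,
                      name = deparse(substitute(covariate))) {
  d <- as.matrix(dm)
  n <- nrow(d)
  if (n < 4) stop("need at least 4 samples")
  if (length(covariate) != n)
    stop("covariate must align with the distance matrix")
  if (length(unique(covariate)) < 2) stop("covariate is constant")
  A <- -0.5 * d^2
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  tr_g <- sum(diag(G))
  if (tr_g <= 0) stop("degenerate distance matrix (no dispersion)")
  categorical <- is.factor(covariate) || is.character(covariate) ||
    is.logical(covariate)
  if (categorical) {
    covariate <- factor(covariate)
    m <- nlevels(covariate)
    tr_hg <- function(idx) {
      g <- as.integer(covariate[idx])
      sums <- rowsum(G, group = g, reorder = TRUE)        # m x n
      gsums <- rowsum(t(sums), group = g, reorder = TRUE) # m x m
      sum(diag(as.matrix(gsums)) / tabulate(g, nbins = m))
    }
  } else {
    m <- 2
    tr_hg <- function(idx) {
      xc <- covariate[idx] - mean(covariate)
      drop(crossprod(xc, G %*% xc)) / sum(xc^2)
    }
  }
  df1 <- m - 1
  df2 <- n - m
  if (df2 <= 0) stop("not enough residual degrees of freedom")
  f_of <- function(idx) {
    hg <- tr_hg(idx)
    (hg / df1) / ((tr_g - hg) / df2)
  }
  f_obs <- f_of(seq_len(n))
  ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) f_of(sample.int(n)) >= f_obs, logical(1)))
  })
  data.frame(covariate = name,
             pseudo_F = f_obs,
             R2 = tr_hg(seq_len(n)) / tr_g,
             p_perm = (1 + ge) / (1 + n_perm),
             n_perm = n_perm,
             stringsAsFactors = FALSE)
}

#' Spearman species-immune-index association network
#'
#' Tests every species whose across-sample mean relative abundance exceeds
#' `abundance_filter` against every numeric immune index, using Spearman
#' rank correlation with midranks (exact permutation p for n <= 9 without
#' ties, t-approximation otherwise). Edges with raw p below `alpha` are
#' returned with their sign; BH-adjusted p-values are reported alongside.
#'
#' @param species_profile species-by-sample relative [abundance_profile()].
#' @param indexes data.frame of immune indexes: a `sample_id` column (or
#'   rownames) plus numeric index columns.
#' @param abundance_filter minimum mean relative abundance for a species
#'   to enter the network (default 1e-7).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @return data.frame of edges: `species`, `index`, `rho`, `p`, `p_adj`,
#'   `sign`.
#' @export
spearman_network <- function(species_profile, indexes,
                             abundance_filter = 1e-7, alpha = 0.05) {
  mat <- unclass(as.matrix(species_profile))
  if ("sample_id" %in% names(indexes)) {
    rownames(indexes) <- indexes$sample_id
    indexes$sample_id <- NULL
  }
  shared <- intersect(colnames(mat), rownames(indexes))
  if (length(shared) < 4)
    stop("need at least 4 shared samples (got ", length(shared), ")")
  mat <- mat[, shared, drop = FALSE]
  indexes <- indexes[shared, , drop = FALSE]
  keep <- rowMeans(mat) > abundance_filter
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) stop("no species pass the abundance filter")
  n <- length(shared)
  edges <- list()
  for (ix in names(indexes)) {
    v <- indexes[[ix]]
    if (!is.numeric(v)) next
    if (diff(range(v)) == 0) {
      warning("index '", ix, "' is constant across samples; skipped")
      next
    }
    for (sp in rownames(mat)) {
      a <- mat[sp, ]
      if (diff(range(a)) == 0) next
      ct <- suppressWarnings(stats::cor.test(
        a, v, method = "spearman", exact = n <= 9))
      edges[[length(edges) + 1L]] <- data.frame(
        species = sp, index = ix, rho = unname(ct$estimate),
        p = unname(ct$p.value), stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0L) stop("no testable species-index pairs")
  res <- do.call(rbind, edges)
  res$p_adj <- bh_adjust(res$p)
  res$sign <- ifelse(res$rho > 0, "positive", "negative")
  res <- res[res$p < alpha, , drop = FALSE]
  rownames(res) <- NULL
  res[order(res$p), ]
}
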