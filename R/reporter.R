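#' One-tailed Wilcoxon rank-sum test
#'
#' Rank-sum test of whether the second group (`y`) is stochastically
#' greater (or less) than the first. Exact p-values (via the Wilcoxon
#' distribution) when both groups have fewer than 50 observations and there
#' are no ties; otherwise the normal approximation with midrank tie
#' correction and continuity correction.
#'
#' @param x,y numeric observations for the two groups (each >= 2 values).
#' @param alternative `"greater"` tests enrichment in `y`, `"less"` tests
#'   enrichment in `x`.
#' @return one-tailed p-value.
#' @export
wilcoxon_ranksum_onetail <- function(x, y,
                                     alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 observations")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) < 50 && length(y) < 50 && !ties
  fit <- suppressWarnings(
    stats::wilcox.test(y, x, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  unname(fit$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min(1, min_{j>=i} p_(j) * m / j)`, returned
#' in the original order.
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Inverse-normal transform of an adjusted p-value
#'
#' `z = qnorm(1 - p)` after clamping `p` to `[1e-15, 1 - 1e-15]` so the
#' result stays finite (|z| <= ~7.94) at the boundaries.
#'
#' @param p (adjusted) p-values in \[0, 1\].
#' @return z-scores.
#' @export
z_from_p <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::qnorm(p, lower.tail = FALSE)
}

#' Reporter-score significance rule
#'
#' A pathway is called significantly altered when its final reporter score
#' exceeds the threshold in magnitude: `|z_adjusted| > threshold`
#' (strictly; a score of exactly 1.96 is not flagged).
#'
#' @param z_adjusted final (background-corrected) reporter scores.
#' @param threshold detection threshold (default 1.96).
#' @return logical vector.
#' @export
reporter_significant <- function(z_adjusted, threshold = 1.96) {
  abs(z_adjusted) > threshold
}

#' Reporter score for pathways/modules
#'
#' Aggregates per-KO z-scores over each pathway's k member KOs as
#' `z_raw = sum(z) / sqrt(k)` and standardizes against a randomized
#' background: the mean and standard deviation of the same aggregate over
#' `n_background` random k-subsets of all scored KOs,
#' `z_adjusted = (z_raw - mu_k) / sigma_k`. Pathways with
#' `|z_adjusted| > threshold` are flagged significant.
#'
#' When every KO in the pool carries an identical z (a fully degenerate
#' null), the background has zero spread and the adjusted score is defined
#' as 0; any other zero-spread background raises an error naming the
#' pathway.
#'
#' @param z named numeric vector of per-KO z-scores.
#' @param map named list: pathway/module id -> character vector of member
#'   KO ids.
#' @param n_background number of random KO sets per pathway size
#'   (default 1000).
#' @param seed integer seed for the background sampler (one seeded
#'   generator for the whole call), or NULL to use the current RNG state.
#' @param aggregation `"sqrt_k"` (default, `sum(z)/sqrt(k)`) or `"k"`
#'   (`mean(z)`), kept for sensitivity analysis.
#' @param threshold significance threshold on `|z_adjusted|`
#'   (default 1.96).
#' @return data.frame: `pathway`, `k`, `z_raw`, `mu_k`, `sigma_k`,
#'   `z_adjusted`, `significant`. Pathways with no member KO in `z` are
#'   skipped with a warning.
#' @export
pathway_reporter <- function(z, map, n_background = 1000, seed = NULL,
                             aggregation = c("sqrt_k", "k"),
                             threshold = 1.96) {
  aggregation <- match.arg(aggregation)
  if (is.null(names(z))) stop("z must be named by KO id")
  agg <- function(v, k) if (aggregation == "sqrt_k") sum(v) / sqrt(k)
                        else sum(v) / k
  members <- lapply(map, function(kos) intersect(kos, names(z)))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("pathway(s) with no scored member KO skipped: ",
            paste(names(map)[empty], collapse = ", "))
    members <- members[!empty]
  }
  if (length(members) == 0L) stop("no scorable pathways")
  ks <- lengths(members)
  if (max(ks) >= length(z))
    stop("KO pool must be larger than the largest pathway")
  degenerate_pool <- diff(range(z)) == 0
  with_seed(seed, {
    # one background per distinct pathway size, shared across pathways
    bg <- lapply(sort(unique(ks)), function(k) {
      if (degenerate_pool) return(c(mu = agg(rep(z[1L], k), k), sigma = 0))
      sets <- vapply(seq_len(n_background),
                     function(i) agg(z[sample.int(length(z), k)], k),
                     numeric(1))
      c(mu = mean(sets), sigma = stats::sd(sets))
    })
    names(bg) <- sort(unique(ks))
    res <- lapply(names(members), function(pw) {
      k <- ks[[pw]]
      z_raw <- agg(z[members[[pw]]], k)
      mu <- bg[[as.character(k)]][["mu"]]
      sigma <- bg[[as.character(k)]][["sigma"]]
      if (sigma == 0) {
        if (degenerate_pool) {
          z_adj <- 0  # all scores identical: no spread, no signal
        } else {
          stop("zero background spread for pathway ", pw)
        }
      } else {
        z_adj <- (z_raw - mu) / sigma
      }
      data.frame(pathway = pw, k = k, z_raw = z_raw, mu_k = mu,
                 sigma_k = sigma, z_adjusted = z_adj,
                 significant = reporter_significant(z_adj, threshold),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
}

#' Full reporter-score pipeline on a KO profile
#'
#' For a two-group comparison: one-tailed rank-sum tests per KO in both
#' directions, per-direction Benjamini-Hochberg adjustment, inverse-normal
#' transform, pathway aggregation and randomized-background correction.
#' The consensus score is signed so that positive values mean enrichment in
#' the second group.
#'
#' @param ko_profile KO-by-sample [abundance_profile()] (or matrix).
#' @param groups factor (or vector) with exactly two levels, aligned with
#'   the profile's samples; the second level is "group 2".
#' @param map pathway membership list (see [read_pathway_map()]).
#' @param n_background,seed,aggregation,threshold passed to
#'   [pathway_reporter()].
#' @return data.frame with per-pathway `k`, per-direction adjusted scores
#'   (`z_adjusted_g1`, `z_adjusted_g2`), `consensus` and `significant`.
#' @export
reporter_pipeline <- function(ko_profile, groups, map, n_background = 1000,
                              seed = NULL, aggregation = "sqrt_k",
                              threshold = 1.96) {
  mat <- unclass(as.matrix(ko_profile))
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("reporter_pipeline requires exactly two groups")
  if (length(groups) != ncol(mat))
    stop("groups must align with the profile's samples")
  g1 <- levels(groups)[1L]
  g2 <- levels(groups)[2L]
  x <- mat[, groups == g1, drop = FALSE]
  y <- mat[, groups == g2, drop = FALSE]
  p_g2 <- vapply(seq_len(nrow(mat)), function(i)
    wilcoxon_ranksum_onetail(x[i, ], y[i, ], "greater"), numeric(1))
  p_g1 <- vapply(seq_len(nrow(mat)), function(i)
    wilcoxon_ranksum_onetail(x[i, ], y[i, ], "less"), numeric(1))
  z_g2 <- stats::setNames(z_from_p(bh_adjust(p_g2)), rownames(mat))
  z_g1 <- stats::setNames(z_from_p(bh_adjust(p_g1)), rownames(mat))
  seeds <- if (is.null(seed)) list(NULL, NULL) else list(seed, seed + 1L)
  r_g2 <- pathway_reporter(z_g2, map, n_background = n_background,
                           seed = seeds[[1L]], aggregation = aggregation,
                           threshold = threshold)
  r_g1 <- pathway_reporter(z_g1, map, n_background = n_background,
                           seed = seeds[[2L]], aggregation = aggregation,
                           threshold = threshold)
  stopifnot(identical(r_g1$pathway, r_g2$pathway))
  consensus <- ifelse(r_g2$z_adjusted >= r_g1$z_adjusted,
                      r_g2$z_adjusted, -r_g1$z_adjusted)
  data.frame(
    pathway = r_g2$pathway, k = r_g2$k,
    z_raw_g1 = r_g1$z_raw, z_raw_g2 = r_g2$z_raw,
    mu_k = r_g2$mu_k, sigma_k = r_g2$sigma_k,
    z_adjusted_g1 = r_g1$z_adjusted, z_adjusted_g2 = r_g2$z_adjusted,
    consensus = consensus,
    direction = ifelse(consensus >= 0, g2, g1),
    significant = reporter_significant(consensus, threshold),
    stringsAsFactors = FALSE)
}
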