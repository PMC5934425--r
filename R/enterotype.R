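#' Partitioning-around-medoids clustering of a distance matrix
#'
#' Classic PAM (BUILD initialization followed by SWAP until no improving
#' single medoid swap remains), as used for enterotype identification on
#' Jensen-Shannon distances. Deterministic for a given distance matrix and
#' k.
#'
#' @param dm symmetric distance matrix (sample ids as dimnames).
#' @param k number of clusters, `2 <= k < n`.
#' @return list with `labels` (named integer vector in 1..k), `medoids`
#'   (sample id per cluster) and `cost` (total distance to assigned
#'   medoid).
#' @export
pam_cluster <- function(dm, k) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (k < 2 || k >= n)
    stop("k must satisfy 2 <= k < n_samples (got k=", k, ", n=", n, ")")
  fit <- cluster::pam(stats::as.dist(dm), k = k, diss = TRUE)
  labels <- stats::setNames(as.integer(fit$clustering), rownames(dm))
  medoids <- fit$medoids
  cost <- sum(dm[cbind(seq_len(n), match(medoids[labels], rownames(dm)))])
  list(labels = labels, medoids = medoids, cost = cost)
}

# Sum-of-squares decomposition of a distance matrix under a partition:
# SS_total = (1/n) sum_{i<j} d_ij^2,
# SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2.
distance_ss <- function(dm, labels) {
  dm2 <- as.matrix(dm)^2
  n <- nrow(dm2)
  ss_total <- sum(dm2[lower.tri(dm2)]) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- dm2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  list(total = ss_total, within = ss_within,
       between = ss_total - ss_within)
}

#' Calinski-Harabasz index from a distance matrix
#'
#' `CH = (SS_between / (k-1)) / (SS_within / (n-k))` with the sums of
#' squares obtained from the pairwise-distance decomposition. Returns `Inf`
#' when the within-cluster sum of squares is (numerically) zero, e.g. for
#' duplicated samples perfectly separated by the partition.
#'
#' @param dm symmetric distance matrix.
#' @param labels cluster assignment aligned with the matrix.
#' @return the CH score (may be `Inf` for a perfect partition).
#' @export
calinski_harabasz <- function(dm, labels) {
  k <- length(unique(labels))
  n <- nrow(as.matrix(dm))
  ss <- distance_ss(dm, labels)
  if (ss$within <= 1e-12) return(Inf)
  (ss$between / (k - 1)) / (ss$within / (n - k))
}

#' Choose the number of enterotype clusters
#'
#' Runs [pam_cluster()] for each candidate k and scores the partition with
#' the Calinski-Harabasz index; returns the argmax, breaking ties toward
#' smaller k (parsimony).
#'
#' @param dm symmetric distance matrix, `n >= 4` samples.
#' @param k_range candidate cluster numbers (default `2:min(10, n-1)`).
#' @return list with `k` (chosen), `ch_scores` (named by k), `labels` and
#'   `medoids` of the chosen partition.
#' @export
select_k <- function(dm, k_range = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 4) stop("need at least 4 samples to select k")
  if (all(dm == 0)) stop("degenerate distance matrix (all zero)")
  if (is.null(k_range)) k_range <- 2:min(10, n - 1)
  fits <- lapply(k_range, function(k) pam_cluster(dm, k))
  ch <- vapply(fits, function(f) calinski_harabasz(dm, f$labels), numeric(1))
  names(ch) <- k_range
  best <- which(ch == max(ch))[1L]  # ties -> smaller k
  list(k = k_range[best], ch_scores = ch,
       labels = fits[[best]]$labels, medoids = fits[[best]]$medoids)
}

#' Enterotype a genus-level profile
#'
#' End-to-end enterotyping: Jensen-Shannon distance matrix, PAM clustering
#' over a range of k, Calinski-Harabasz model selection, and per-sample
#' silhouette diagnostics.
#'
#' @param profile genus-level (or other) relative [abundance_profile()].
#' @param k_range candidate cluster numbers (see [select_k()]).
#' @return list with `k`, `labels`, `medoids`, `ch_scores`, `silhouette`
#'   (per-sample silhouette width) and `dm` (the JSD matrix).
#' @export
enterotype_samples <- function(profile, k_range = NULL) {
  dm <- jsd_distance_matrix(profile)
  sel <- select_k(dm, k_range = k_range)
  sil <- cluster::silhouette(sel$labels, dmatrix = dm)
  sel$silhouette <- stats::setNames(sil[, "sil_width"], names(sel$labels))
  sel$dm <- dm
  sel
}

#' PCA ordination of an abundance profile
#'
#' Centered (per feature), unscaled principal component analysis of the
#' sample-by-feature matrix — the ordination classically drawn alongside
#' enterotype assignments. Optional transforms: feature scaling,
#' `log(x + eps)`, or the Hellinger square-root transform.
#'
#' @param profile an [abundance_profile()] with >= 2 samples and >= 2
#'   features.
#' @param transform `"none"` (default), `"scale"`, `"log"` or
#'   `"hellinger"`.
#' @param log_eps pseudocount for the log transform.
#' @return list with `coordinates` (samples x components), `loadings`
#'   (features x components) and `explained_variance` (nonincreasing
#'   fractions summing to 1).
#' @export
pca_ordination <- function(profile,
                           transform = c("none", "scale", "log", "hellinger"),
                           log_eps = 1e-6) {
  transform <- match.arg(transform)
  mat <- t(unclass(as.matrix(profile)))  # samples x features
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("need at least 2 samples and 2 features")
  mat <- switch(transform,
    none = mat,
    scale = scale(mat),
    log = log(mat + log_eps),
    hellinger = sqrt(sweep(mat, 1, rowSums(mat), "/")))
  if (all(abs(sweep(mat, 2, colMeans(mat))) < 1e-12))
    stop("profile is constant across samples; PCA undefined")
  fit <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  list(coordinates = fit$x,
       loadings = fit$rotation,
       explained_variance = ev / sum(ev))
}
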