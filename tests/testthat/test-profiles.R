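toy_catalog <- function(lengths, species = NULL, ko = NULL) {
  n <- length(lengths)
  data.frame(gene_id = paste0("g", seq_len(n)), length_bp = lengths,
             phylum = "p1", genus = "ge1",
             species = if (is.null(species)) paste0("sp", seq_len(n))
                       else species,
             ko = if (is.null(ko)) rep(NA_character_, n) else ko,
             stringsAsFactors = FALSE)
}

counts_mat <- function(x, genes = paste0("g", seq_along(x))) {
  matrix(x, ncol = 1, dimnames = list(genes, "s1"))
}

test_that("relative gene abundance is the length-normalized share", {
  cat_ <- toy_catalog(c(100, 200))
  rel <- relative_gene_abundance(counts_mat(c(10, 10)), cat_)
  expect_equal(as.numeric(rel), c(2 / 3, 1 / 3))
  expect_equal(as.numeric(relative_gene_abundance(
    counts_mat(5, "g1"), toy_catalog(150))), 1)
  rel0 <- relative_gene_abundance(counts_mat(c(0, 5)), cat_)
  expect_equal(as.numeric(rel0), c(0, 1))
})

test_that("gene abundance errors name bad samples and unknown genes", {
  cat_ <- toy_catalog(c(100, 200))
  m <- matrix(c(1, 1, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(relative_gene_abundance(m, cat_), "empty")
  bad <- counts_mat(c(1, 1), genes = c("g1", "gX"))
  expect_error(relative_gene_abundance(bad, cat_), "gX")
})

test_that("gene abundance is invariant to per-sample count rescaling", {
  cat_ <- toy_catalog(c(120, 340, 990, 500))
  x <- counts_mat(c(3, 9, 1, 7))
  a <- relative_gene_abundance(x, cat_)
  b <- relative_gene_abundance(x * 50, cat_)
  expect_equal(unclass(a), unclass(b))
})

test_that("aggregation sums member genes and keeps unannotated mass", {
  cat_ <- toy_catalog(c(100, 100, 100),
                      species = c("spA", "spA", "spB"),
                      ko = c("K1", NA, NA))
  rel <- abundance_profile(
    matrix(c(0.2, 0.3, 0.5), 3, 1,
           dimnames = list(paste0("g", 1:3), "s1")),
    kind = "relative", level = "gene")
  sp <- aggregate_profile(rel, cat_, "species")
  expect_equal(as.numeric(sp[c("spA", "spB"), 1]), c(0.5, 0.5))
  kop <- aggregate_profile(rel, cat_, "ko")
  expect_equal(as.numeric(kop["unannotated", 1]), 0.8)
  expect_equal(sum(kop), 1)
  dropped <- aggregate_profile(rel, cat_, "ko", drop_unannotated = TRUE)
  expect_equal(as.numeric(dropped["K1", 1]), 1)
})

test_that("each-gene-its-own-species aggregation is the identity", {
  cat_ <- toy_catalog(c(100, 200, 300))
  rel <- relative_gene_abundance(counts_mat(c(5, 5, 5)), cat_)
  sp <- aggregate_profile(rel, cat_, "species")
  expect_equal(sort(as.numeric(sp)), sort(as.numeric(rel)))
})

test_that("aggregation conserves per-sample mass at every level", {
  set.seed(31)
  for (i in 1:10) {
    cat_ <- simulate_catalog(n_genes = sample(50:200, 1),
                             n_species = sample(5:20, 1),
                             n_genera = sample(2:5, 1), n_kos = 10,
                             seed = i)
    counts <- matrix(rpois(nrow(cat_) * 3, 30), ncol = 3,
                     dimnames = list(cat_$gene_id, paste0("s", 1:3)))
    counts[1, ] <- counts[1, ] + 1  # no all-zero sample
    rel <- relative_gene_abundance(counts, cat_)
    for (lv in c("species", "genus", "phylum", "ko")) {
      agg <- aggregate_profile(rel, cat_, lv)
      expect_equal(colSums(agg), colSums(rel), tolerance = 1e-9)
    }
  }
})

test_that("richness counts strictly positive features", {
  m <- toy_profile(matrix(c(0.5, 0, 0.5, 0, 0, 0, 0.4, 0.6), 4, 2))
  r <- richness(m)
  expect_equal(as.numeric(r), c(2, 2))
  z <- matrix(c(1, 1, 0, 0), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(as.numeric(colSums(z > 0)), c(2, 0))
})

test_that("Shannon index matches closed forms and vegan", {
  one <- toy_profile(matrix(1, 1, 1))
  expect_equal(as.numeric(shannon_index(one)), 0)
  unif <- toy_profile(matrix(rep(0.25, 4), 4, 1))
  expect_equal(as.numeric(shannon_index(unif)), log(4))
  mix <- toy_profile(matrix(c(0.5, 0.25, 0.25), 3, 1))
  expect_equal(as.numeric(shannon_index(mix)), 1.03972, tolerance = 1e-5)
  set.seed(13)
  m <- matrix(runif(40), 8, 5,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  m <- sweep(m, 2, colSums(m), "/")
  expect_equal(as.numeric(shannon_index(toy_profile(m))),
               as.numeric(vegan::diversity(t(m), index = "shannon")),
               tolerance = 1e-12)
})

test_that("Shannon index is maximal for the uniform distribution", {
  set.seed(17)
  n <- 6
  h_unif <- log(n)
  for (i in 1:25) {
    p <- rgamma(n, 0.5)
    p <- p / sum(p)
    p[p == 0] <- 1e-12
    h <- -sum(p * log(p))
    expect_lte(h, h_unif + 1e-9)
  }
})

test_that("JSD matches its closed forms", {
  p <- c(0.3, 0.3, 0.4)
  expect_equal(jsd_distance(p, p), 0)
  expect_equal(jsd_distance(c(1, 0), c(0, 1)), sqrt(log(2)),
               tolerance = 1e-12)
  expect_equal(jsd_distance(c(0.5, 0.5), c(0.25, 0.75)), 0.18391,
               tolerance = 1e-4)
  expect_error(jsd_distance(c(1, 0), c(0.2, 0.3, 0.5)), "length")
  expect_error(jsd_distance(c(0.7, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("JSD zero replacement mode smooths disjoint support", {
  d <- jsd_distance(c(1, 0), c(0, 1), zero_replace = 1e-6)
  expect_lt(d, sqrt(log(2)))
  expect_gt(d, 0.8)
})

test_that("JSD behaves as a metric on random composition triples", {
  set.seed(41)
  for (i in 1:100) {
    p <- rgamma(10, 0.5); p <- p / sum(p)
    q <- rgamma(10, 0.5); q <- q / sum(q)
    r <- rgamma(10, 0.5); r <- r / sum(r)
    dpq <- jsd_distance(p, q)
    expect_equal(dpq, jsd_distance(q, p))
    expect_lte(dpq, jsd_distance(p, r) + jsd_distance(r, q) + 1e-12)
  }
})

test_that("distance matrix matches a brute-force pairwise loop", {
  set.seed(53)
  m <- matrix(rgamma(100, 0.7), 20, 5,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:5)))
  m <- sweep(m, 2, colSums(m), "/")
  dm <- jsd_distance_matrix(toy_profile(m))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), setNames(rep(0, 5), colnames(m)))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dm[i, j], jsd_distance(m[, i], m[, j]))
  dup <- toy_profile(cbind(m[, c(1, 1, 2)]))
  colnames(dup) <- c("a", "b", "c")
  dmd <- jsd_distance_matrix(dup)
  expect_equal(dmd["a", "b"], 0)
})

test_that("within-group beta diversity enumerates pairwise distances", {
  m <- matrix(abs(rnorm(24)) + 0.1, 4, 6,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  m <- sweep(m, 2, colSums(m), "/")
  dm <- jsd_distance_matrix(toy_profile(m))
  groups <- setNames(c("g1", "g1", "g2", "g2", "g2", "g2"), colnames(m))
  beta <- beta_diversity_within_group(dm, groups)
  expect_length(beta$g1, 1)
  expect_length(beta$g2, 6)
  groups2 <- setNames(c("g1", "g1", "g1", "g1", "g1", "lone"), colnames(m))
  expect_warning(b2 <- beta_diversity_within_group(dm, groups2), "lone")
  expect_named(b2, "g1")
  ident <- toy_profile(cbind(m[, c(2, 2, 2)]))
  colnames(ident) <- c("x", "y", "z")
  bi <- beta_diversity_within_group(jsd_distance_matrix(ident),
                                    setNames(rep("g", 3), c("x", "y", "z")))
  expect_equal(bi$g, rep(0, 3))
})

test_that("profiles round-trip through TSV", {
  m <- toy_profile(matrix(c(0.4, 0.6, 0.9, 0.1), 2, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(m, path)
  back <- read_profile(path, kind = "relative", level = "genus")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
})
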