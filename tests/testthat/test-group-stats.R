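test_that("paired signed-rank test matches the exact enumeration", {
  # uniform positive shift, n = 6: the most extreme of 2^6 sign patterns
  expect_equal(paired_signed_rank(c(1, 2, 3, 4, 5, 6) + 0.5,
                                  c(1, 2, 3, 4, 5, 6) + 3.6),
               2 / 64, tolerance = 1e-12)
  # perfectly balanced +d/-d differences
  expect_equal(paired_signed_rank(c(0, 0, 10, 10), c(1, 2, 9, 8)), 1.0)
  expect_error(paired_signed_rank(c(1, 2), c(1, 2)), "zero")
  set.seed(109)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    b <- sample.int(1e6, n)
    a <- sample.int(1e6, n)
    expect_equal(paired_signed_rank(b, a), enum_signrank_p(b, a),
                 tolerance = 1e-9)
  }
})

test_that("signed-rank approximation agrees with wilcox.test", {
  set.seed(113)
  b <- rnorm(60)
  a <- b + rnorm(60, 0.3)
  expect_equal(paired_signed_rank(b, a),
               suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-9)
})

make_md <- function(n_sub, groups = c("A", "B")) {
  data.frame(sample_id = c(paste0("s", 1:n_sub, "_1"),
                           paste0("s", 1:n_sub, "_2")),
             subject_id = rep(paste0("s", 1:n_sub), 2),
             subgroup = rep(groups, each = n_sub),
             stringsAsFactors = FALSE)
}

test_that("paired differential abundance recovers a planted fold change", {
  cat_ <- simulate_catalog(300, 30, 10, 20, seed = 121)
  probe <- cohort_design(n_subjects = c(study = 15, control1 = 2,
                                        control2 = 2),
                         n_enterotypes = 1, concentration = 1,
                         depth = 1e5, seed = 5)
  base <- simulate_metagenome_cohort(cat_, probe, mode = "frequency")
  driver <- base$truth$species[which.max(base$truth$component_means[[1]])]
  fx <- data.frame(feature_id = driver, level = "species", multiplier = 4)
  des <- cohort_design(n_subjects = c(study = 15, control1 = 2,
                                      control2 = 2),
                       n_enterotypes = 1, concentration = 1,
                       diet_effects = fx, depth = 1e5, seed = 5)
  ch <- simulate_metagenome_cohort(cat_, des, mode = "frequency")
  study <- ch$metadata[ch$metadata$group == "study", ]
  sp <- aggregate_profile(ch$profile, cat_, "species")
  res <- suppressWarnings(differential_abundance(
    sp, study, groups = c("A", "B"), mode = "paired"))
  hit <- res[res$feature == driver, ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "B")
  expect_equal(hit$test, "signed_rank_paired")
})

test_that("null differential abundance flags about alpha of features", {
  set.seed(127)
  rates <- replicate(50, {
    m <- matrix(rlnorm(40 * 20), 40, 20,
                dimnames = list(paste0("f", 1:40),
                                c(paste0("s", 1:10, "_1"),
                                  paste0("s", 1:10, "_2"))))
    md <- make_md(10)
    res <- differential_abundance(m, md, groups = c("A", "B"),
                                  mode = "unpaired")
    mean(res$significant)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.05)
})

test_that("constant features are excluded with a warning", {
  m <- matrix(rlnorm(3 * 8), 3, 8,
              dimnames = list(c("f1", "f2", "const"),
                              c(paste0("s", 1:4, "_1"),
                                paste0("s", 1:4, "_2"))))
  m["const", ] <- 0.25
  md <- make_md(4)
  expect_warning(res <- differential_abundance(m, md, groups = c("A", "B"),
                                               mode = "paired"),
                 "excluded")
  expect_false("const" %in% res$feature)
})

test_that("paired mode demands subject-matched samples", {
  m <- matrix(rlnorm(2 * 7), 2, 7,
              dimnames = list(c("f1", "f2"),
                              c(paste0("s", 1:4, "_1"),
                                paste0("s", 1:3, "_2"))))
  md <- make_md(4)[-8, ]  # drop subject 4's day-91 sample
  expect_error(differential_abundance(m, md, groups = c("A", "B"),
                                      mode = "paired"), "s4")
})

test_that("PERMANOVA pseudo-F equals the group-decomposition formula", {
  set.seed(131)
  for (i in 1:20) {
    X <- matrix(runif(8 * 5), 8, 5)
    d <- as.matrix(dist(X))
    dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
    g <- factor(sample(rep(c("a", "b"), 4)))
    res <- permanova(d, g, n_perm = 9, seed = 1, name = "g")
    d2 <- d^2
    sst <- sum(d2[lower.tri(d2)]) / 8
    ssw <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      sub <- d2[idx, idx]
      ssw <- ssw + sum(sub[lower.tri(sub)]) / length(idx)
    }
    f_classic <- (sst - ssw) / (ssw / (8 - 2))
    expect_equal(res$pseudo_F, f_classic, tolerance = 1e-9)
    expect_equal(res$R2, (sst - ssw) / sst, tolerance = 1e-9)
    # R2 + residual share = 1
    expect_equal(res$R2 + ssw / sst, 1, tolerance = 1e-9)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on F and R2", {
  set.seed(137)
  X <- matrix(rnorm(12 * 6), 12, 6)
  d <- as.matrix(dist(X))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  g <- factor(rep(c("a", "b", "c"), 4))
  res <- permanova(d, g, n_perm = 99, seed = 3, name = "g")
  va <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, va$F[1], tolerance = 1e-9)
  expect_equal(res$R2, va$R2[1], tolerance = 1e-9)
  # numeric covariates use the centered-column hat matrix
  x <- rnorm(12)
  resn <- permanova(d, x, n_perm = 99, seed = 3, name = "x")
  van <- vegan::adonis2(as.dist(d) ~ x, permutations = 99)
  expect_equal(resn$pseudo_F, van$F[1], tolerance = 1e-9)
})

test_that("PERMANOVA permutation p-values are floored and deterministic", {
  d <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  d[1:3, 4:6] <- 1
  d[4:6, 1:3] <- 1
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(d, g, n_perm = 999, seed = 5, name = "g")
  # only permutations recreating the exact partition reach the observed F:
  # 3! * 3! * 2 / 6! = 10% of labelings
  expect_equal(res$p_perm, 0.1, tolerance = 0.3)
  expect_gte(res$p_perm, 1 / 1000)
  expect_gt(res$R2, 0.9)
  r2 <- permanova(d, g, n_perm = 999, seed = 5, name = "g")
  expect_identical(res, r2)
  expect_error(permanova(d, rep("a", 6), name = "g"), "constant")
})

test_that("Spearman network respects rank invariance and the filter", {
  set.seed(139)
  m <- matrix(rgamma(5 * 10, 2), 5, 10,
              dimnames = list(paste0("sp", 1:5), paste0("s", 1:10)))
  m <- sweep(m, 2, colSums(m), "/")
  m["sp5", ] <- m["sp5", ] * 1e-8 / mean(m["sp5", ])  # below the filter
  m <- sweep(m, 2, colSums(m), "/")
  idx <- data.frame(sample_id = colnames(m),
                    mono = as.numeric(m["sp1", ]),
                    anti = exp(-as.numeric(m["sp2", ])),
                    flat = rep(1, 10))
  expect_warning(net <- spearman_network(m, idx), "flat")
  e1 <- net[net$species == "sp1" & net$index == "mono", ]
  expect_equal(e1$rho, 1)
  expect_equal(e1$sign, "positive")
  e2 <- net[net$species == "sp2" & net$index == "anti", ]
  expect_equal(e2$rho, -1)
  expect_equal(e2$sign, "negative")
  expect_false("sp5" %in% net$species)
})

test_that("Spearman edges require enough shared samples", {
  m <- matrix(runif(4), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  idx <- data.frame(sample_id = c("s1", "s2"), v = c(1, 2))
  expect_error(spearman_network(m, idx), "shared samples")
})
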