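test_that("catalog generation honors cardinalities and invariants", {
  cat1 <- simulate_catalog(10, 10, 5, 3, seed = 1)
  expect_equal(nrow(cat1), 10)
  expect_equal(length(unique(cat1$species)), 10)  # one gene per species
  expect_silent(validate_catalog(cat1))

  cat2 <- simulate_catalog(1000, 50, 12, 40, seed = 2)
  expect_equal(sum(table(cat2$species)), 1000)
  expect_equal(length(unique(cat2$species)), 50)
  expect_true(all(table(cat2$species) >= 1))
  # nested taxonomy: each species under exactly one genus
  expect_silent(validate_catalog(cat2))
  frac_na <- mean(is.na(cat2$ko))
  expect_equal(frac_na, 0.2, tolerance = 0.01)
})

test_that("catalog generation is deterministic and rejects impossible designs", {
  a <- simulate_catalog(200, 30, 8, 10, seed = 99)
  b <- simulate_catalog(200, 30, 8, 10, seed = 99)
  expect_identical(a, b)
  expect_error(simulate_catalog(10, 20, 5, 3, seed = 1), "n_species")
  expect_error(simulate_catalog(10, 5, 8, 3, seed = 1), "n_genera")
  expect_error(simulate_catalog(10, 5, 2, 3, length_range = c(10, 50),
                                seed = 1), "length_range")
})

test_that("cohort design validates depth, multipliers and weights", {
  expect_error(cohort_design(depth = 0), "depth")
  expect_error(cohort_design(diet_effects = data.frame(
    feature_id = "x", level = "species", multiplier = -1)), "multiplier")
  expect_error(cohort_design(enterotype_weights = c(0.5, 0.2),
                             n_enterotypes = 2), "sum to 1")
})

test_that("simulated read counts conserve the design depth per sample", {
  ch <- quick_cohort(seed = 4, depth = 12345)
  expect_true(all(colSums(ch$profile) == 12345))
  expect_equal(attr(ch$profile, "kind"), "counts")
  # metadata mirrors the A-F subgroup layout
  expect_setequal(unique(ch$metadata$subgroup),
                  c("A", "B", "C", "D", "E", "F"))
  expect_equal(nrow(ch$metadata), 2 * 10)
})

test_that("truth carries no planted effects when none are designed", {
  ch <- quick_cohort(seed = 5)
  expect_equal(nrow(ch$truth$affected_features), 0)
})

test_that("planted diet effects must exist in the catalog", {
  fx <- data.frame(feature_id = "species_9999", level = "species",
                   multiplier = 4)
  expect_error(quick_cohort(seed = 6, diet_effects = fx),
               "absent from catalog")
})

test_that("cohort simulation is reproducible under a fixed seed", {
  a <- quick_cohort(seed = 7)
  b <- quick_cohort(seed = 7)
  expect_identical(unclass(a$profile), unclass(b$profile))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$enterotype_sample, b$truth$enterotype_sample)
})

test_that("planted enterotype components separate in JSD space", {
  ch <- quick_cohort(seed = 8, n_species = 40, n_genes = 400,
                     n_subjects = c(study = 8, control1 = 8, control2 = 8),
                     n_enterotypes = 2, concentration = 0.1, depth = 5e4)
  day0 <- ch$metadata$sample_id[ch$metadata$timepoint == "day0"]
  rel <- relative_gene_abundance(ch$profile[, day0], ch$catalog)
  gp <- aggregate_profile(rel, ch$catalog, "genus")
  dm <- jsd_distance_matrix(gp)
  lab <- ch$truth$enterotype_sample[day0]
  same <- outer(lab, lab, "==")
  off <- lower.tri(dm)
  within_mean <- mean(dm[off & same])
  between_mean <- mean(dm[off & !same])
  expect_lt(within_mean, between_mean)
})

test_that("repertoire design validates turnover and usage vectors", {
  expect_error(repertoire_design(turnover = 1.5), "turnover")
  expect_error(repertoire_design(v_usage = c(A = 0.5, B = 0.4)),
               "sum to 1")
})

test_that("frequency-mode repertoire pairs hit the delta-index bounds", {
  d1 <- repertoire_design(n_clones = 400, turnover = 1,
                          mode = "frequency", seed = 1)
  p1 <- simulate_repertoire_pair(d1)
  expect_identical(delta_index(p1$day0, p1$day91), 0)
  d0 <- repertoire_design(n_clones = 400, turnover = 0,
                          mode = "frequency", seed = 1)
  p0 <- simulate_repertoire_pair(d0)
  expect_identical(delta_index(p0$day0, p0$day91), 2)
})

test_that("delta index decreases strictly in the turnover parameter", {
  deltas <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(rho) {
    d <- repertoire_design(n_clones = 400, turnover = rho,
                           mode = "frequency", seed = 3)
    p <- simulate_repertoire_pair(d)
    delta_index(p$day0, p$day91)
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("sampled repertoires conserve depth and respect the seed", {
  d <- repertoire_design(n_clones = 500, depth = 20000, seed = 12)
  p <- simulate_repertoire_pair(d)
  expect_equal(sum(p$day0$count), 20000)
  expect_equal(sum(p$day91$count), 20000)
  p2 <- simulate_repertoire_pair(d)
  expect_identical(as.data.frame(p$day0), as.data.frame(p2$day0))
  # log-normal clone-size law is available
  dl <- repertoire_design(n_clones = 300, clone_law = "log_normal",
                          seed = 5)
  pl <- simulate_repertoire_pair(dl)
  expect_s3_class(pl$day0, "clone_table")
})

test_that("a 4-fold planted species effect is recovered in most cohorts", {
  hits <- 0
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    cat_ <- simulate_catalog(300, 30, 10, 20, seed = 3000 + s)
    probe <- cohort_design(n_subjects = c(study = 10, control1 = 10,
                                          control2 = 1),
                           n_enterotypes = 1, concentration = 1,
                           depth = 1e5, seed = s)
    base <- simulate_metagenome_cohort(cat_, probe, mode = "frequency")
    driver <- base$truth$species[which.max(base$truth$component_means[[1]])]
    fx <- data.frame(feature_id = driver, level = "species",
                     multiplier = 4)
    des <- cohort_design(n_subjects = c(study = 10, control1 = 10,
                                        control2 = 1),
                         n_enterotypes = 1, concentration = 1,
                         diet_effects = fx, depth = 1e5, seed = s)
    ch <- simulate_metagenome_cohort(cat_, des)
    d91 <- ch$metadata[ch$metadata$timepoint == "day91" &
                         ch$metadata$group != "control2", ]
    rel <- relative_gene_abundance(ch$profile[, d91$sample_id], cat_)
    sp <- aggregate_profile(rel, cat_, "species")
    res <- suppressWarnings(differential_abundance(
      sp, d91, groups = c("control1", "study"), mode = "unpaired",
      group_col = "group"))
    hit <- res[res$feature == driver, ]
    hits <- hits + (nrow(hit) == 1 && hit$significant)
  }
  expect_gte(hits / n_seeds, 0.7)  # planted-recovery target 0.8 +/- 0.1
})

test_that("frequency mode yields exact relative abundances", {
  ch <- quick_cohort(seed = 9, mode = "frequency")
  expect_equal(attr(ch$profile, "kind"), "relative")
  expect_true(all(abs(colSums(ch$profile) - 1) < 1e-9))
})
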