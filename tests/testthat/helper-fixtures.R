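# Shared fixtures and independent oracles used across test files.

# Minimal clone table from parallel vectors; gene calls default to one
# V/J pair so clone identity is carried by the CDR3 alone.
toy_clones <- function(cdr3, count, v = "IGHV3-23", j = "IGHJ4",
                       c_gene = NULL, sample_id = "s", chain = "IGH") {
  df <- data.frame(cdr3_aa = cdr3, v_gene = v, j_gene = j, count = count,
                   stringsAsFactors = FALSE)
  if (!is.null(c_gene)) df$c_gene <- c_gene
  clone_table(df, sample_id = sample_id, chain = chain)
}

# Random clone table for property tests.
random_clones <- function(n, sample_id = "r") {
  toy_clones(cdr3 = paste0("C", replicate(n, paste(
    sample(LETTERS[1:20], 8, replace = TRUE), collapse = "")), "W"),
    count = sample.int(500, n, replace = TRUE), sample_id = sample_id)
}

# Small relative profile (features x samples) with named dims.
toy_profile <- function(mat, level = "genus") {
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  abundance_profile(mat, kind = "relative", level = level)
}

# Exhaustive-enumeration oracle for the one-tailed rank-sum test: all
# C(n, ny) assignments of the pooled midranks to group y.
enum_ranksum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(pooled)
  ny <- length(y)
  r <- rank(pooled)
  obs <- sum(r[(length(x) + 1):n])
  stats_ <- apply(utils::combn(n, ny), 2, function(idx) sum(r[idx]))
  if (alternative == "greater") mean(stats_ >= obs) else mean(stats_ <= obs)
}

# Exhaustive sign-flip oracle for the two-sided signed-rank test
# (zero differences dropped, as in the implementation's exact mode).
enum_signrank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  flips <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- flips %*% r
  min(1, 2 * min(mean(vs >= v), mean(vs <= v)))
}

# Brute-force Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Simulate a cohort and return the pieces most tests need.
quick_cohort <- function(seed, n_genes = 300, n_species = 30,
                         n_genera = 10, n_kos = 20,
                         n_subjects = c(study = 4, control1 = 3,
                                        control2 = 3),
                         concentration = 1, n_enterotypes = 1,
                         depth = 2e4, diet_effects = NULL,
                         mode = "sampling") {
  cat_ <- simulate_catalog(n_genes, n_species, n_genera, n_kos,
                           seed = seed + 50000)
  des <- cohort_design(n_subjects = n_subjects,
                       n_enterotypes = n_enterotypes,
                       concentration = concentration,
                       diet_effects = diet_effects, depth = depth,
                       seed = seed)
  c(list(catalog = cat_, design = des),
    simulate_metagenome_cohort(cat_, des, mode = mode))
}
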