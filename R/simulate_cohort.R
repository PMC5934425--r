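#' Cohort design for the metagenome simulator
#'
#' Describes a diet-intervention cohort: three groups sampled at two
#' timepoints (subgroups A/B = study day 0/91, C/D = omnivorous control,
#' E/F = long-term vegetarian control), a mixture of enterotype components
#' for the between-subject species composition, and optional planted diet
#' effects applied to the post-diet samples of the study group.
#'
#' The default 15/7/7 subjects per group and the day-0/day-91 timepoints
#' are the cohort layout of the intervention design this pipeline targets.
#' `concentration` is the mean per-species Dirichlet parameter: subject
#' compositions are drawn from `Dirichlet(concentration * S * m)` around
#' their component's mean `m` over `S` species, so smaller values give
#' noisier, more individual microbiomes.
#'
#' @param n_subjects named integer vector: subjects per group
#'   (`study`, `control1`, `control2`).
#' @param timepoints two timepoint labels (first = baseline).
#' @param n_enterotypes number of enterotype mixture components.
#' @param concentration mean per-species Dirichlet parameter (> 0).
#' @param enterotype_weights mixture weights (default uniform; must sum
#'   to 1).
#' @param diet_effects NULL or data.frame with columns `feature_id`,
#'   `level` (`"species"`, `"genus"` or `"ko"`), `multiplier` (> 0): fold
#'   changes applied multiplicatively to the named feature's abundance in
#'   post-diet study samples, before renormalization.
#' @param depth sequencing depth (reads per sample, >= 1).
#' @param seed integer seed.
#' @return validated design list (class `cohort_design`).
#' @export
cohort_design <- function(n_subjects = c(study = 15, control1 = 7,
                                         control2 = 7),
                          timepoints = c("day0", "day91"),
                          n_enterotypes = 3, concentration = 0.3,
                          enterotype_weights = NULL, diet_effects = NULL,
                          depth = 1e5, seed = 1) {
  stopifnot(length(n_subjects) == 3, all(n_subjects >= 1),
            length(timepoints) == 2, n_enterotypes >= 1,
            concentration > 0)
  if (depth < 1) stop("depth must be >= 1")
  if (is.null(enterotype_weights))
    enterotype_weights <- rep(1 / n_enterotypes, n_enterotypes)
  if (length(enterotype_weights) != n_enterotypes ||
      abs(sum(enterotype_weights) - 1) > 1e-9)
    stop("enterotype mixture weights must sum to 1")
  if (!is.null(diet_effects)) {
    stopifnot(all(c("feature_id", "level", "multiplier") %in%
                    names(diet_effects)))
    if (any(diet_effects$multiplier <= 0))
      stop("diet-effect multipliers must be > 0")
  }
  if (is.null(names(n_subjects)))
    names(n_subjects) <- c("study", "control1", "control2")
  structure(list(n_subjects = n_subjects, timepoints = timepoints,
                 n_enterotypes = n_enterotypes,
                 concentration = concentration,
                 enterotype_weights = enterotype_weights,
                 diet_effects = diet_effects, depth = depth, seed = seed),
            class = "cohort_design")
}

#' Simulate a metagenome cohort with planted ground truth
#'
#' Per subject, an enterotype component is drawn from the design's mixture
#' and a species composition from that component's Dirichlet; each
#' component's mean has one distinct dominant driver species, mirroring
#' classic enterotype structure. The expected read share of a gene is
#' proportional to its species' abundance times the gene's length share
#' within the species, with diet-effect multipliers applied to post-diet
#' samples of study-group subjects before renormalization. Read counts are
#' multinomial at the design depth; frequency mode skips sampling and
#' returns exact expected relative gene abundances for analytic tests.
#'
#' @param catalog gene catalog (see [simulate_catalog()]).
#' @param design a [cohort_design()].
#' @param mode `"sampling"` (multinomial read counts) or `"frequency"`
#'   (exact expected relative abundances, no sampling noise).
#' @return list with `profile` (gene-by-sample [abundance_profile()]:
#'   counts, or relative in frequency mode), `metadata` (sample_id,
#'   subject_id, group, timepoint, subgroup, age, sex, bmi) and `truth`
#'   (enterotype per subject and per sample, affected features, component
#'   mean compositions).
#' @export
simulate_metagenome_cohort <- function(catalog, design,
                                       mode = c("sampling", "frequency")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "cohort_design"))
  if (nrow(catalog) == 0) stop("catalog is empty")
  validate_catalog(catalog)
  species <- sort(unique(catalog$species))
  S <- length(species)
  fx <- design$diet_effects
  if (!is.null(fx)) {
    for (i in seq_len(nrow(fx))) {
      lv <- fx$level[i]
      pool <- switch(lv, species = catalog$species, genus = catalog$genus,
                     ko = catalog$ko,
                     stop("unsupported diet-effect level: ", lv))
      if (!fx$feature_id[i] %in% pool)
        stop("diet-effect feature absent from catalog: ", fx$feature_id[i])
    }
  }
  # per-gene species index and length share within species
  sp_idx <- match(catalog$species, species)
  len_tot <- rowsum(as.numeric(catalog$length_bp), group = sp_idx,
                    reorder = TRUE)
  len_share <- catalog$length_bp / len_tot[sp_idx]
  with_seed(design$seed, {
    K <- design$n_enterotypes
    drivers <- sample.int(S, min(K, S))
    comp_means <- vapply(seq_len(K), function(k) {
      base <- rdirichlet1(rep(1, S))
      boost <- numeric(S)
      boost[drivers[min(k, length(drivers))]] <- 3
      (base + boost) / (1 + 3)
    }, numeric(S))
    groups <- rep(names(design$n_subjects), design$n_subjects)
    n_sub <- length(groups)
    subjects <- sprintf("subj_%02d", seq_len(n_sub))
    sub_comp <- sample.int(K, n_sub, replace = TRUE,
                           prob = design$enterotype_weights)
    theta <- design$concentration * S
    sub_species <- vapply(seq_len(n_sub), function(i)
      rdirichlet1(theta * comp_means[, sub_comp[i]]), numeric(S))
    meta <- expand.grid(timepoint = design$timepoints,
                        subject_id = subjects,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta <- meta[, c("subject_id", "timepoint")]
    meta$group <- groups[match(meta$subject_id, subjects)]
    sub_letters <- matrix(c("A", "B", "C", "D", "E", "F"), nrow = 2,
                          dimnames = list(design$timepoints,
                                          names(design$n_subjects)))
    meta$subgroup <- sub_letters[cbind(meta$timepoint, meta$group)]
    meta$sample_id <- paste0(meta$subject_id, "_", meta$timepoint)
    meta$age <- rep(sample(20:60, n_sub, replace = TRUE),
                    each = 2)
    meta$sex <- rep(sample(c("F", "M"), n_sub, replace = TRUE), each = 2)
    meta$bmi <- rep(round(stats::rnorm(n_sub, 23, 2.5), 1), each = 2)
    meta <- meta[, c("sample_id", "subject_id", "group", "timepoint",
                     "subgroup", "age", "sex", "bmi")]
    prof <- vapply(seq_len(nrow(meta)), function(r) {
      i <- match(meta$subject_id[r], subjects)
      p_sp <- sub_species[, i]
      post <- meta$timepoint[r] == design$timepoints[2]
      affected <- post && meta$group[r] == "study" && !is.null(fx)
      if (affected) {
        for (e in seq_len(nrow(fx))) {
          if (fx$level[e] == "species") {
            hit <- species == fx$feature_id[e]
            p_sp[hit] <- p_sp[hit] * fx$multiplier[e]
          } else if (fx$level[e] == "genus") {
            hit <- species %in%
              unique(catalog$species[catalog$genus == fx$feature_id[e]])
            p_sp[hit] <- p_sp[hit] * fx$multiplier[e]
          }
        }
        p_sp <- p_sp / sum(p_sp)
      }
      r_gene <- p_sp[sp_idx] * len_share
      if (affected && any(fx$level == "ko")) {
        for (e in which(fx$level == "ko")) {
          hit <- !is.na(catalog$ko) & catalog$ko == fx$feature_id[e]
          r_gene[hit] <- r_gene[hit] * fx$multiplier[e]
        }
      }
      r_gene <- r_gene / sum(r_gene)
      if (mode == "sampling") {
        as.numeric(stats::rmultinom(1, size = design$depth, prob = r_gene))
      } else {
        a <- (r_gene / catalog$length_bp)
        a / sum(a)
      }
    }, numeric(nrow(catalog)))
    dimnames(prof) <- list(catalog$gene_id, meta$sample_id)
    truth <- list(
      enterotype_subject = stats::setNames(sub_comp, subjects),
      enterotype_sample = stats::setNames(
        sub_comp[match(meta$subject_id, subjects)], meta$sample_id),
      affected_features = if (is.null(fx))
        data.frame(feature_id = character(), level = character(),
                   multiplier = numeric()) else fx,
      component_means = stats::setNames(
        as.data.frame(comp_means), paste0("component_", seq_len(K))),
      species = species)
    list(profile = abundance_profile(
           prof, kind = if (mode == "sampling") "counts" else "relative",
           level = "gene"),
         metadata = meta, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
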