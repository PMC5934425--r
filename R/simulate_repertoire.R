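#' Repertoire design for the clone-table simulator
#'
#' Describes a paired (day-0 / day-91) immune repertoire: number of
#' clones, clone-size law (rank-frequency power law `p_r ~ r^-alpha`,
#' default `alpha = 1.5`, typical of observed repertoires; or log-normal),
#' V/J/isotype usage probabilities, the turnover parameter `rho` (fraction
#' of day-0 clone mass persisting to day 91), and sequencing depth.
#'
#' @param n_clones number of clones at each timepoint (>= 1).
#' @param clone_law `"power_law"` or `"log_normal"`.
#' @param alpha power-law exponent (> 1).
#' @param meanlog,sdlog log-normal parameters (used when
#'   `clone_law = "log_normal"`).
#' @param turnover rho in \[0, 1\]: 1 = identical repertoire at day 91,
#'   0 = complete replacement by novel clones.
#' @param depth reads per sample in sampling mode.
#' @param chain `"IGH"` or `"TRB"`.
#' @param v_usage,j_usage,isotype_usage named probability vectors (must
#'   sum to 1 within 1e-9); defaults cover common human gene segments.
#' @param mode `"sampling"` (multinomial read counts) or `"frequency"`
#'   (clone tables carry exact frequencies, for analytic tests).
#' @param seed integer seed.
#' @return validated design list (class `repertoire_design`).
#' @export
repertoire_design <- function(n_clones = 10000,
                              clone_law = c("power_law", "log_normal"),
                              alpha = 1.5, meanlog = 0, sdlog = 1.5,
                              turnover = 0.8, depth = 1e6,
                              chain = c("IGH", "TRB"),
                              v_usage = NULL, j_usage = NULL,
                              isotype_usage = NULL,
                              mode = c("sampling", "frequency"),
                              seed = 1) {
  clone_law <- match.arg(clone_law)
  chain <- match.arg(chain)
  mode <- match.arg(mode)
  stopifnot(n_clones >= 1, alpha > 1, depth >= 1)
  if (turnover < 0 || turnover > 1)
    stop("turnover must lie in [0, 1]")
  if (is.null(v_usage)) {
    v_usage <- if (chain == "IGH") {
      c(`IGHV1-2` = 0.08, `IGHV1-69` = 0.07, `IGHV3-7` = 0.10,
        `IGHV3-23` = 0.20, `IGHV3-30` = 0.15, `IGHV4-34` = 0.12,
        `IGHV4-39` = 0.10, `IGHV5-51` = 0.10, `IGHV6-1` = 0.08)
    } else {
      c(`TRBV5-1` = 0.15, `TRBV6-5` = 0.12, `TRBV7-9` = 0.13,
        `TRBV12-3` = 0.12, `TRBV19` = 0.16, `TRBV20-1` = 0.17,
        `TRBV28` = 0.15)
    }
  }
  if (is.null(j_usage)) {
    j_usage <- if (chain == "IGH") {
      c(IGHJ1 = 0.05, IGHJ2 = 0.08, IGHJ3 = 0.12, IGHJ4 = 0.45,
        IGHJ5 = 0.12, IGHJ6 = 0.18)
    } else {
      c(`TRBJ1-1` = 0.18, `TRBJ1-2` = 0.15, `TRBJ2-1` = 0.20,
        `TRBJ2-3` = 0.17, `TRBJ2-7` = 0.30)
    }
  }
  if (is.null(isotype_usage) && chain == "IGH")
    isotype_usage <- c(IGHM = 0.40, IGHD = 0.05, IGHG1 = 0.20,
                       IGHG3 = 0.05, IGHA1 = 0.22, IGHA2 = 0.06,
                       IGHE = 0.02)
  for (u in list(v_usage, j_usage, isotype_usage)) {
    if (!is.null(u) && abs(sum(u) - 1) > 1e-9)
      stop("usage probability vectors must sum to 1")
  }
  structure(list(n_clones = n_clones, clone_law = clone_law, alpha = alpha,
                 meanlog = meanlog, sdlog = sdlog, turnover = turnover,
                 depth = depth, chain = chain, v_usage = v_usage,
                 j_usage = j_usage, isotype_usage = isotype_usage,
                 mode = mode, seed = seed),
            class = "repertoire_design")
}

# Random unique CDR3 amino-acid sequences, C...W framed, lengths centred
# around 15 aa.
random_cdr3 <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(8:24, n, replace = TRUE,
                 prob = stats::dnorm(8:24, mean = 15, sd = 3))
  seqs <- vapply(lens, function(L)
    paste0("C", paste(sample(aa, L - 2, replace = TRUE), collapse = ""),
           "W"), character(1))
  while (anyDuplicated(seqs) > 0) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(lens[dup], function(L)
      paste0("C", paste(sample(aa, L - 2, replace = TRUE), collapse = ""),
             "W"), character(1))
  }
  seqs
}

clone_frequencies <- function(design, n) {
  f <- switch(design$clone_law,
    power_law = seq_len(n)^(-design$alpha),
    log_normal = sort(stats::rlnorm(n, design$meanlog, design$sdlog),
                      decreasing = TRUE))
  f / sum(f)
}

#' Simulate a paired day-0 / day-91 repertoire
#'
#' Day-0 clone frequencies follow the design's clone-size law. Day-91
#' frequencies mix the persistent day-0 clones, carrying total mass `rho`
#' with unchanged relative sizes, with novel clones carrying mass
#' `1 - rho`. In sampling mode both tables hold multinomial read counts at
#' the design depth (clones receiving zero reads are dropped); in
#' frequency mode the `count` column holds the exact frequencies.
#'
#' @param design a [repertoire_design()].
#' @return list with [clone_table()]s `day0` and `day91`.
#' @export
simulate_repertoire_pair <- function(design) {
  stopifnot(inherits(design, "repertoire_design"))
  rho <- design$turnover
  with_seed(design$seed, {
    n <- design$n_clones
    f0 <- clone_frequencies(design, n)
    g <- clone_frequencies(design, n)
    cdr3 <- random_cdr3(2 * n)
    v <- sample(names(design$v_usage), 2 * n, replace = TRUE,
                prob = design$v_usage)
    j <- sample(names(design$j_usage), 2 * n, replace = TRUE,
                prob = design$j_usage)
    c_gene <- if (design$chain == "IGH")
      sample(names(design$isotype_usage), 2 * n, replace = TRUE,
             prob = design$isotype_usage) else rep(NA_character_, 2 * n)
    build <- function(idx, freq, sample_id) {
      if (design$mode == "frequency") {
        counts <- freq
        keep <- counts > 0
      } else {
        counts <- as.numeric(stats::rmultinom(1, design$depth, freq))
        keep <- counts > 0
      }
      clone_table(data.frame(
        cdr3_aa = cdr3[idx][keep], v_gene = v[idx][keep],
        j_gene = j[idx][keep], c_gene = c_gene[idx][keep],
        count = counts[keep], stringsAsFactors = FALSE),
        sample_id = sample_id, chain = design$chain)
    }
    day0 <- build(seq_len(n), f0, "day0")
    idx91 <- c(seq_len(n), n + seq_len(n))
    f91 <- c(rho * f0, (1 - rho) * g)
    day91 <- build(idx91[f91 > 0], f91[f91 > 0], "day91")
    list(day0 = day0, day91 = day91)
  })
}
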