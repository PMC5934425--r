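# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. seed = NULL leaves the
# global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Dirichlet draw via normalized gammas; alpha entries must be positive.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1  # guard underflow at tiny alpha
  x / sum(x)
}

#' Write an abundance profile as TSV
#'
#' First column `feature_id`, one column per sample.
#' @param profile an [abundance_profile()] or matrix.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(feature_id = rownames(profile),
                   as.data.frame(unclass(as.matrix(profile))),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance profile from TSV
#' @param path TSV written by [write_profile()].
#' @inheritParams abundance_profile
#' @export
read_profile <- function(path, kind = "counts", level = "gene") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_profile(m, kind = kind, level = level)
}

#' Read a pathway/module membership map from TSV
#'
#' Two columns (`pathway_id`, `ko_id`), one membership per row.
#' @param path TSV file.
#' @return named list: pathway id -> character vector of member KO ids.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("pathway map needs two columns (pathway_id, ko_id)")
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a pathway map as TSV
#' @param map named list, pathway id -> member KO ids.
#' @param path output file.
#' @export
write_pathway_map <- function(map, path) {
  df <- data.frame(pathway_id = rep(names(map), lengths(map)),
                   ko_id = unlist(map, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
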