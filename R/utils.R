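#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjustment of the Rand index; 1 for identical partitions
#' (up to label permutation), ~0 for independent ones.
#'
#' @param a,b vectors of cluster labels over the same items.
#' @return numeric in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Read a pipeline configuration file
#'
#' YAML (.yaml/.yml) or JSON; returns a named list of thresholds and paths.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
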