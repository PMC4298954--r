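#' Build a ranked gene list
#'
#' Orders scores descending; ties are broken by a stable sort on gene symbol
#' so the ranking is deterministic.
#'
#' @param scores named numeric vector (gene symbol -> ranking score, e.g.
#'   Spearman rho or a log2 fold-change).
#' @return named numeric vector sorted in descending score order
#'   (a `RankedList`).
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named with unique gene symbols")
  scores <- scores[!is.na(scores)]
  scores[order(-scores, names(scores), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom keeping a running sum: a gene in the
#' set (a hit) increments by |score|^weight normalized by the set's total;
#' a miss decrements by 1 / (N - n_set). The enrichment score (ES) is the
#' signed extremum of the running sum. With `weight = 0` this is the classic
#' Kolmogorov-Smirnov statistic.
#'
#' @param ranked a `RankedList` from [ranked_list()].
#' @param gene_set character vector of symbols.
#' @param weight exponent on |score| for hit increments (default 1).
#' @return list: `es`, `running_sum` (length N, starts/ends consistent with
#'   zero net sum), `hit_positions`, `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  hit <- genes %in% gene_set
  n <- length(genes); n_hit <- sum(hit)
  if (n_hit == 0) stop("gene set is disjoint from the ranked list")
  if (n_hit == n) {
    # degenerate: every gene a hit, so the miss decrement is undefined;
    # use the uniform baseline i/N instead, which keeps the profile inside
    # a one-step envelope and returns it to zero
    inc <- abs(ranked)^weight
    rs <- cumsum(inc / sum(inc)) - seq_len(n) / n
    i_ext <- which.max(abs(rs))
    return(list(es = rs[i_ext], running_sum = rs,
                hit_positions = which(hit), leading_edge = genes))
  }
  w <- abs(ranked)^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / (n - n_hit))
  rs <- cumsum(inc)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  le <- if (es >= 0) genes[hit & seq_len(n) <= i_ext]
        else genes[hit & seq_len(n) > i_ext]
  list(es = es, running_sum = rs, hit_positions = which(hit),
       leading_edge = le)
}

# ES for a given hit indicator over a fixed weighted score vector; used in
# the permutation loop where only positions change.
.es_fast <- function(w_abs, hit, n) {
  n_hit <- sum(hit)
  inc <- rep(-1 / (n - n_hit), n)
  inc[hit] <- w_abs[hit] / sum(w_abs[hit])
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Preranked gene set enrichment analysis
#'
#' For every set within the size bounds, computes the weighted running-sum
#' enrichment score on the ranked list and assesses significance by
#' gene-label permutation: set positions are redrawn uniformly `n_perm`
#' times with the score vector fixed (preranked mode; the input is a
#' ranking, not a sample matrix, so phenotype permutation is not
#' applicable). The nominal p is the +1-corrected fraction of same-sign
#' permuted scores at least as extreme. FDR q follows the normalized-ES
#' procedure: observed and permuted ES are divided by the mean same-sign
#' permuted |ES| of their set, and q compares the pooled permuted NES tail
#' with the observed NES tail.
#'
#' @param ranked a `RankedList`.
#' @param sets a `GeneSetCollection` (named list of symbol vectors).
#' @param n_perm number of permutations (default 1000).
#' @param min_size,max_size inclusive bounds on (set ∩ list) size
#'   (defaults 15 and 500).
#' @param weight hit-increment exponent (default 1).
#' @param seed integer RNG seed for reproducible permutations.
#' @return data.frame: one row per retained set with `set`, `size`, `es`,
#'   `nes`, `p_value`, `fdr_q`, `leading_edge` (comma-joined).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, min_size = 15,
                           max_size = 500, weight = 1, seed = 1) {
  genes <- names(ranked)
  n <- length(genes)
  sizes <- vapply(sets, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no gene set within the size bounds")
  if (any(!keep))
    message(sprintf("preranked_gsea: %d set(s) outside size bounds [%d, %d] excluded",
                    sum(!keep), min_size, max_size))
  sets <- sets[keep]; sizes <- sizes[keep]
  w_abs <- abs(ranked)^weight
  set.seed(seed)
  res <- vector("list", length(sets))
  perm_nes_all <- list()
  for (si in seq_along(sets)) {
    es_obs <- enrichment_score(ranked, sets[[si]], weight)
    k <- sizes[si]
    es_perm <- numeric(n_perm)
    for (j in seq_len(n_perm)) {
      hit <- logical(n)
      hit[sample.int(n, k)] <- TRUE
      es_perm[j] <- .es_fast(w_abs, hit, n)
    }
    same <- sign(es_perm) == sign(es_obs$es)
    p <- (1 + sum(same & abs(es_perm) >= abs(es_obs$es))) / (1 + sum(same))
    mean_pos <- mean(es_perm[es_perm > 0])
    mean_neg <- mean(abs(es_perm[es_perm < 0]))
    norm_one <- function(e) {
      ifelse(e >= 0,
             if (is.finite(mean_pos) && mean_pos > 0) e / mean_pos else NA_real_,
             if (is.finite(mean_neg) && mean_neg > 0) e / mean_neg else NA_real_)
    }
    nes <- norm_one(es_obs$es)
    perm_nes_all[[si]] <- vapply(es_perm, norm_one, numeric(1))
    res[[si]] <- data.frame(
      set = names(sets)[si], size = k, es = es_obs$es, nes = nes,
      p_value = p,
      leading_edge = paste(es_obs$leading_edge, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  pooled <- unlist(perm_nes_all)
  out$fdr_q <- vapply(out$nes, function(nv) {
    if (is.na(nv)) return(NA_real_)
    if (nv >= 0) {
      num_d <- sum(pooled >= 0, na.rm = TRUE)
      num <- if (num_d > 0) sum(pooled >= nv, na.rm = TRUE) / num_d else 0
      den_d <- sum(out$nes >= 0, na.rm = TRUE)
      den <- if (den_d > 0) sum(out$nes >= nv, na.rm = TRUE) / den_d else 1
    } else {
      num_d <- sum(pooled < 0, na.rm = TRUE)
      num <- if (num_d > 0) sum(pooled <= nv, na.rm = TRUE) / num_d else 0
      den_d <- sum(out$nes < 0, na.rm = TRUE)
      den <- if (den_d > 0) sum(out$nes <= nv, na.rm = TRUE) / den_d else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))
  rownames(out) <- NULL
  out[, c("set", "size", "es", "nes", "p_value", "fdr_q", "leading_edge")]
}
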