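#' First-principal-component signature score per sample
#'
#' Rows (genes) are z-scored, then the per-sample projection on the first
#' right singular vector of the standardized matrix is returned. The sign is
#' oriented so the anchor gene's loading is positive (default CDH1); if the
#' anchor is absent, the gene with the largest |loading| anchors instead,
#' with a message. Scores have zero mean across samples.
#'
#' @param expr_sub numeric matrix, signature genes x samples (>= 2 genes,
#'   >= 3 samples).
#' @param anchor_gene symbol fixing the sign convention.
#' @param standardize z-score genes before the decomposition (default TRUE).
#' @return a `SignatureScore` list: `scores` (named per sample),
#'   `loadings` (named per gene), `explained_variance_fraction`,
#'   `orientation_anchor`.
#' @export
pc1_score <- function(expr_sub, anchor_gene = "CDH1", standardize = TRUE) {
  stopifnot(nrow(expr_sub) >= 2, ncol(expr_sub) >= 3)
  x <- expr_sub
  if (standardize) {
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      x <- x[sds > 0, , drop = FALSE]
      message(sprintf("pc1_score: %d constant gene(s) dropped", sum(sds == 0)))
    }
    x <- t(scale(t(x)))
  } else {
    x <- x - rowMeans(x)
  }
  # rows are centered across samples, so scores (linear combinations of
  # rows) automatically average 0 across samples
  sv <- svd(x)
  loadings <- stats::setNames(sv$u[, 1], rownames(x))
  scores <- stats::setNames(sv$v[, 1] * sv$d[1], colnames(x))
  anchor <- anchor_gene
  if (!anchor %in% names(loadings)) {
    anchor <- names(loadings)[which.max(abs(loadings))]
    message(sprintf("pc1_score: anchor '%s' absent; orienting on '%s'",
                    anchor_gene, anchor))
  }
  if (loadings[anchor] < 0) {
    loadings <- -loadings
    scores <- -scores
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = sv$d[1]^2 / sum(sv$d^2),
                 orientation_anchor = anchor),
            class = "SignatureScore")
}

#' Compare a per-sample quantity between two groups
#'
#' Two-sided comparison of scores (or any per-sample values, e.g.
#' log10 IC50) between two groups by Wilcoxon rank-sum (exact for small
#' groups, see [wilcoxon_ranksum_p()]) or Welch t-test.
#'
#' @param values named numeric vector per sample.
#' @param groups named two-level factor or character vector per sample.
#' @param test "ranksum" or "t".
#' @return list: `group_levels`, `n`, `means`, `medians`, `difference`
#'   (level2 - level1, of means for "t", medians for "ranksum"), `p_value`.
#' @export
compare_groups <- function(values, groups, test = c("ranksum", "t")) {
  test <- match.arg(test)
  common <- intersect(names(values), names(groups))
  v <- values[common]; g <- as.character(groups[common])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("grouping must have exactly two levels")
  v1 <- v[g == lev[1]]; v2 <- v[g == lev[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop("both groups need at least 2 samples")
  p <- if (test == "ranksum") wilcoxon_ranksum_p(v1, v2) else
    stats::t.test(v1, v2)$p.value
  diff <- if (test == "ranksum")
    stats::median(v2) - stats::median(v1) else mean(v2) - mean(v1)
  list(group_levels = lev,
       n = c(length(v1), length(v2)),
       means = c(mean(v1), mean(v2)),
       medians = c(stats::median(v1), stats::median(v2)),
       difference = diff,
       p_value = p,
       test = test)
}
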