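#' Hierarchical clustering of samples on SRAM methylation
#'
#' Agglomerative clustering of samples with distance 1 - Pearson correlation
#' (computed across probes) and average linkage by default. Deterministic
#' given input order and configuration. The dendrogram is also serialized in
#' Newick.
#'
#' @param beta_sub numeric matrix, probes x samples (usually the SRAM rows).
#' @param k number of clusters to cut (>= 2).
#' @param distance "pearson" (1 - correlation) or any method accepted by
#'   [stats::dist()].
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `labels` (named integer cluster ids), `hclust`,
#'   `newick`.
#' @export
cluster_samples <- function(beta_sub, k = 2, distance = "pearson",
                            linkage = "average") {
  stopifnot(nrow(beta_sub) >= 2, ncol(beta_sub) >= 2, k >= 2)
  if (k > ncol(beta_sub))
    stop("k exceeds the number of samples")
  d <- if (distance == "pearson") {
    stats::as.dist(1 - stats::cor(beta_sub))
  } else {
    stats::dist(t(beta_sub), method = distance)
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = k)
  newick <- ape::write.tree(ape::as.phylo(hc))
  list(labels = labels, hclust = hc, newick = newick)
}

#' Assign epithelial / mesenchymal labels to samples
#'
#' Primary rule: a sample is epithelial (E) when its E-cadherin protein level
#' (RPPA) is at or above the panel median, else mesenchymal (M); used when
#' `ecad_level` is present for at least 80% of samples. Fallback rule: the
#' sign of (CDH1 expression z-score minus the mean z-score of the mesenchymal
#' markers), positive = E. Samples with no usable evidence get NA.
#'
#' @param sample_annot data.frame with `sample_id` and optionally
#'   `ecad_level`.
#' @param expr gene x sample log2 expression matrix (for the fallback).
#' @param epithelial_marker epithelial marker gene (default CDH1).
#' @param mesenchymal_markers mesenchymal marker genes.
#' @return list with `labels` (named character vector, "E"/"M"/NA) and
#'   `rule` ("ecad_median" or "marker_sign" per sample).
#' @export
assign_em_labels <- function(sample_annot, expr = NULL,
                             epithelial_marker = "CDH1",
                             mesenchymal_markers = c("ZEB1", "VIM", "TWIST1",
                                                     "FN1", "CDH2")) {
  samples <- sample_annot$sample_id
  labels <- stats::setNames(rep(NA_character_, length(samples)), samples)
  rule <- stats::setNames(rep(NA_character_, length(samples)), samples)
  ecad <- if ("ecad_level" %in% names(sample_annot))
    sample_annot$ecad_level else rep(NA_real_, length(samples))
  use_rppa <- mean(!is.na(ecad)) >= 0.8
  if (use_rppa) {
    med <- stats::median(ecad, na.rm = TRUE)
    ok <- !is.na(ecad)
    labels[ok] <- ifelse(ecad[ok] >= med, "E", "M")
    rule[ok] <- "ecad_median"
  }
  need <- is.na(labels)
  if (any(need) && !is.null(expr)) {
    mes <- intersect(mesenchymal_markers, rownames(expr))
    if (epithelial_marker %in% rownames(expr) && length(mes) > 0) {
      z <- t(scale(t(expr[c(epithelial_marker, mes), , drop = FALSE])))
      score <- z[epithelial_marker, ] -
        colMeans(z[mes, , drop = FALSE])
      idx <- samples[need][samples[need] %in% colnames(expr)]
      labels[idx] <- ifelse(score[idx] > 0, "E", "M")
      rule[idx] <- "marker_sign"
    }
  }
  if (any(is.na(labels)))
    message(sprintf("assign_em_labels: %d sample(s) unlabeled (no usable evidence)",
                    sum(is.na(labels))))
  list(labels = labels, rule = rule)
}

#' Two-sided Wilcoxon rank-sum p-value, exact for small groups
#'
#' Exact when both groups have at most `exact_max` observations: without ties
#' via the exact null distribution; with ties via full enumeration of all
#' group assignments of the pooled mid-ranks. Larger groups use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_max per-group size bound for the exact path (default 12).
#' @return two-sided p-value in (0, 1\].
#' @export
wilcoxon_ranksum_p <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  pooled <- c(x, y)
  if (stats::sd(pooled) == 0) return(1)
  small <- n1 <= exact_max && n2 <= exact_max
  has_ties <- anyDuplicated(pooled) > 0
  if (small && !has_ties) {
    return(suppressWarnings(
      stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value))
  }
  if (small && has_ties) {
    r <- rank(pooled)
    w_obs <- sum(r[seq_len(n1)])
    combos <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    mu <- n1 * (n1 + n2 + 1) / 2
    return(mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
  }
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
}

#' Call EMT-SRAMs: SRAM probes differentially methylated between E and M
#'
#' Per probe, a two-sided Wilcoxon rank-sum test of beta values between the
#' epithelial and mesenchymal groups; probes with p below `p_cutoff`
#' (unadjusted, default 0.001) are EMT-SRAMs. Direction is the sign of
#' (median beta in M minus median beta in E): positive means methylated in
#' mesenchymal cells (M-SRAM), negative methylated in epithelial cells
#' (E-SRAM). A probe constant across all samples gets p = 1. Benjamini-
#' Hochberg adjusted p-values are reported alongside when `bh = TRUE`.
#'
#' @param beta_sub numeric matrix, SRAM probes x samples.
#' @param labels named character vector of "E"/"M" per sample; NAs excluded.
#' @param p_cutoff unadjusted p-value threshold (default 0.001).
#' @param bh also report BH-adjusted p-values.
#' @return an `EmtCall` list: `sample_labels`, and `table` with `probe_id`,
#'   `wilcoxon_p`, `is_emt_sram`, `direction` ("M-SRAM"/"E-SRAM", NA for
#'   non-EMT-SRAMs), optionally `p_bh`.
#' @export
call_emt_srams <- function(beta_sub, labels, p_cutoff = 0.001, bh = FALSE) {
  labels <- labels[colnames(beta_sub)]
  use <- !is.na(labels)
  beta_use <- beta_sub[, use, drop = FALSE]
  lab <- labels[use]
  if (sum(lab == "E") < 3 || sum(lab == "M") < 3)
    stop("need at least 3 samples per group")
  e_idx <- lab == "E"; m_idx <- lab == "M"
  p <- numeric(nrow(beta_use))
  dirn <- character(nrow(beta_use))
  for (i in seq_len(nrow(beta_use))) {
    xe <- beta_use[i, e_idx]; xm <- beta_use[i, m_idx]
    p[i] <- wilcoxon_ranksum_p(xm, xe)
    dirn[i] <- if (stats::median(xm) >= stats::median(xe)) "M-SRAM" else "E-SRAM"
  }
  tab <- data.frame(probe_id = rownames(beta_sub),
                    wilcoxon_p = p,
                    is_emt_sram = p < p_cutoff,
                    direction = ifelse(p < p_cutoff, dirn, NA_character_),
                    stringsAsFactors = FALSE)
  if (bh) tab$p_bh <- stats::p.adjust(p, method = "BH")
  structure(list(sample_labels = labels, table = tab), class = "EmtCall")
}

#' Summarize an EMT-SRAM call at probe and gene level
#'
#' Collapses EMT-SRAM probes to unique genes; a gene's direction is taken
#' from its most significant probe (smallest Wilcoxon p, ties broken by probe
#' id).
#'
#' @param call an `EmtCall`.
#' @param probe_to_gene named character vector probe id -> gene symbol.
#' @return list: `n_probes`, `n_genes`, `n_m_genes`, `n_e_genes`,
#'   `gene_table`.
#' @export
summarize_emt_call <- function(call, probe_to_gene) {
  tab <- call$table[call$table$is_emt_sram, , drop = FALSE]
  tab$gene_symbol <- probe_to_gene[tab$probe_id]
  tab <- tab[!is.na(tab$gene_symbol), , drop = FALSE]
  tab <- tab[order(tab$gene_symbol, tab$wilcoxon_p, tab$probe_id,
                   method = "radix"), , drop = FALSE]
  genes <- tab[!duplicated(tab$gene_symbol), , drop = FALSE]
  list(n_probes = nrow(tab),
       n_genes = nrow(genes),
       n_m_genes = sum(genes$direction == "M-SRAM"),
       n_e_genes = sum(genes$direction == "E-SRAM"),
       gene_table = genes)
}

#' Build an EMT gene set from E/M differential expression
#'
#' Membership by group-mean log2 difference: genes with
#' |mean(E) - mean(M)| >= log2(fold_cutoff) (default 4-fold, i.e. 2 log2
#' units, boundary inclusive). Fold-changes are reported signed as
#' mean(E) - mean(M).
#'
#' @param expr gene x sample log2 expression matrix.
#' @param labels named "E"/"M" vector per sample.
#' @param fold_cutoff linear fold-change threshold (default 4).
#' @return an `EmtGeneSet` list: `members`, `log2_fc` (named, members only),
#'   `fold_cutoff`.
#' @export
build_emt_gene_set <- function(expr, labels, fold_cutoff = 4) {
  labels <- labels[colnames(expr)]
  e_idx <- !is.na(labels) & labels == "E"
  m_idx <- !is.na(labels) & labels == "M"
  if (!any(e_idx) || !any(m_idx)) stop("both groups must be non-empty")
  lfc <- rowMeans(expr[, e_idx, drop = FALSE]) -
    rowMeans(expr[, m_idx, drop = FALSE])
  keep <- abs(lfc) >= log2(fold_cutoff)
  structure(list(members = rownames(expr)[keep],
                 log2_fc = lfc[keep],
                 fold_cutoff = fold_cutoff),
            class = "EmtGeneSet")
}

#' Hypergeometric overlap between two gene sets
#'
#' One-sided (enrichment) hypergeometric tail probability of observing at
#' least the seen overlap when |set_a| genes are drawn from the universe of
#' which |set_b| are marked. The overlap fraction is reported relative to
#' `set_a`.
#'
#' @param set_a,set_b character vectors of gene symbols, subsets of
#'   `universe`.
#' @param universe character vector of all eligible symbols.
#' @return list: `overlap` (count), `fraction` (|A ∩ B| / |A|),
#'   `p_value`, `overlap_genes`.
#' @export
signature_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0 || length(set_b) == 0)
    stop("gene sets must be non-empty")
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  ov <- intersect(set_a, set_b)
  k <- length(ov)
  p <- stats::phyper(k - 1, length(set_b),
                     length(universe) - length(set_b),
                     length(set_a), lower.tail = FALSE)
  list(overlap = k, fraction = k / length(set_a), p_value = p,
       overlap_genes = ov)
}
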