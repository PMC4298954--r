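#' Collapse multi-probe expression measurements to one row per gene
#'
#' For a gene measured by several expression probes, the probes whose pairwise
#' Pearson correlations all reach `r_min` are averaged per sample; when more
#' than one such mutually-correlated subset exists, the largest is taken
#' (ties broken by higher mean expression, then probe-id order, for
#' determinism). A gene with no correlated pair keeps its single most highly
#' expressed probe. Single-probe genes pass through unchanged. Constant
#' (zero-variance) probes cannot enter the correlation screen and are set
#' aside with a warning; they are used only if the gene has no other probe.
#'
#' @param raw_expr numeric matrix, probes x samples.
#' @param probe_to_gene named character vector mapping probe id -> gene
#'   symbol, covering all rows of `raw_expr`.
#' @param r_min minimum pairwise Pearson correlation for averaging
#'   (default 0.4).
#' @return numeric matrix, genes x samples.
#' @export
collapse_expression_probes <- function(raw_expr, probe_to_gene, r_min = 0.4) {
  stopifnot(is.matrix(raw_expr), ncol(raw_expr) >= 2)
  probes <- rownames(raw_expr)
  if (is.null(probes)) stop("raw_expr must have probe-id rownames")
  if (!all(probes %in% names(probe_to_gene)))
    stop("probe_to_gene does not cover all probes")
  genes <- probe_to_gene[probes]
  keep <- !is.na(genes) & nzchar(genes)
  raw_expr <- raw_expr[keep, , drop = FALSE]
  genes <- genes[keep]
  by_gene <- split(seq_along(genes), genes)
  out <- matrix(NA_real_, nrow = length(by_gene), ncol = ncol(raw_expr),
                dimnames = list(names(by_gene), colnames(raw_expr)))
  for (gi in seq_along(by_gene)) {
    idx <- by_gene[[gi]]
    if (length(idx) == 1) {
      out[gi, ] <- raw_expr[idx, ]
      next
    }
    sub <- raw_expr[idx, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("gene '%s': %d constant probe(s) excluded from correlation screening",
                      names(by_gene)[gi], sum(sds == 0)))
      if (all(sds == 0)) {           # nothing to correlate; keep first probe
        out[gi, ] <- sub[1, ]
        next
      }
      sub <- sub[sds > 0, , drop = FALSE]
    }
    if (nrow(sub) == 1) {
      out[gi, ] <- sub[1, ]
      next
    }
    cm <- stats::cor(t(sub))
    out[gi, ] <- .collapse_one_gene(sub, cm, r_min)
  }
  out
}

# Pick the largest mutually-correlated probe subset (max clique of the
# thresholded correlation graph); fall back to the highest-mean probe.
.collapse_one_gene <- function(sub, cm, r_min) {
  adj <- cm >= r_min
  diag(adj) <- FALSE
  if (!any(adj)) {
    return(sub[which.max(rowMeans(sub)), ])
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::largest_cliques(g)
  if (length(cliques) > 1) {
    score <- vapply(cliques, function(cl) mean(sub[as.integer(cl), ]),
                    numeric(1))
    cliques <- cliques[order(-score,
                             vapply(cliques,
                                    function(cl) min(as.integer(cl)),
                                    numeric(1)))]
  }
  colMeans(sub[as.integer(cliques[[1]]), , drop = FALSE])
}

#' Spearman correlation with average ranks and a two-sided test
#'
#' Computes rho on mid-ranks (ties get average ranks). The p-value of the
#' two-sided test of rho = 0 uses the t approximation for n >= 10 complete
#' pairs and exact enumeration over all n! rank permutations for n < 10.
#'
#' @param x,y numeric vectors; pairs with any NA are dropped.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.na(rho))
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  if (n >= 10) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  } else {
    perms <- .all_permutations(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p_value = min(p, 1), n = n)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0
  for (pos in seq_len(n)) {     # insert symbol n at each position
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Screen every methylation probe for association with expression
#'
#' For each probe in the panel, looks up the collapsed expression row of the
#' probe's gene and computes Spearman rho (inverse association means negative
#' rho: promoter methylation represses expression) with its two-sided
#' p-value. Probes whose gene is absent from the expression matrix, with
#' fewer than `min_pairs` complete pairs, or with zero variance are reported
#' untested. A probe annotated to several genes (comma/semicolon separated
#' symbols) is tested once per mapped gene and flagged multi-mapped.
#'
#' @param panel an `OmicsPanel` whose `expr` matrix is gene-level (one row
#'   per symbol; see [collapse_expression_probes()]).
#' @param min_pairs minimum complete pairs per probe (default 5).
#' @return an `SramTable` data.frame: one row per (probe, mapped gene) with
#'   `probe_id`, `gene_symbol`, `rho`, `p_value`, `n_pairs`, `tested`,
#'   `multi_mapped`, `cpg_island`, `tss_distance`.
#' @export
spearman_screen <- function(panel, min_pairs = 5) {
  validate_panel(panel)
  pa <- panel$probe_annot
  pa <- pa[match(rownames(panel$beta), pa$probe_id), , drop = FALSE]
  rows <- list()
  n_unmapped <- 0L
  for (i in seq_len(nrow(panel$beta))) {
    syms <- pa$gene_symbol[i]
    syms <- if (is.na(syms)) character(0) else
      strsplit(syms, "[,;] *")[[1]]
    multi <- length(syms) > 1
    if (length(syms) == 0) {
      n_unmapped <- n_unmapped + 1L
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = pa$probe_id[i], gene_symbol = NA_character_,
        rho = NA_real_, p_value = NA_real_, n_pairs = 0L, tested = FALSE,
        multi_mapped = FALSE, cpg_island = pa$cpg_island[i],
        tss_distance = pa$tss_distance[i], stringsAsFactors = FALSE)
      next
    }
    for (sym in syms) {
      if (!sym %in% rownames(panel$expr)) {
        rows[[length(rows) + 1]] <- data.frame(
          probe_id = pa$probe_id[i], gene_symbol = sym,
          rho = NA_real_, p_value = NA_real_, n_pairs = 0L, tested = FALSE,
          multi_mapped = multi, cpg_island = pa$cpg_island[i],
          tss_distance = pa$tss_distance[i], stringsAsFactors = FALSE)
        next
      }
      st <- spearman_test(panel$beta[i, ], panel$expr[sym, ])
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = pa$probe_id[i], gene_symbol = sym,
        rho = st$rho, p_value = st$p_value, n_pairs = st$n,
        tested = !is.na(st$rho) && st$n >= min_pairs,
        multi_mapped = multi, cpg_island = pa$cpg_island[i],
        tss_distance = pa$tss_distance[i], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$rho[!tab$tested] <- NA_real_
  tab$p_value[!tab$tested] <- NA_real_
  n_untested <- sum(!tab$tested)
  if (n_untested > 0)
    message(sprintf("spearman_screen: %d probe-gene pair(s) untested (%d unmapped probes)",
                    n_untested, n_unmapped))
  class(tab) <- c("SramTable", "data.frame")
  tab
}

#' Fit a beta-uniform mixture to a p-value distribution
#'
#' Maximum-likelihood fit of f(p) = lambda + (1 - lambda) * a * p^(a - 1),
#' the mixture of a Uniform(0,1) null component and a Beta(a, 1) signal
#' component with a in (0, 1]. Returns the mixing weight `lambda_hat`, shape
#' `a_hat`, and the standard upper bound on the null proportion
#' pi0 <= lambda + (1 - lambda) * a (the fitted density's value at p = 1).
#'
#' @param p p-values in (0, 1]; values of exactly 0 are clamped to the
#'   machine minimum with a warning; at least 100 required.
#' @return a `BumFit` list: `lambda_hat`, `a_hat`, `pi0_upper`, `log_lik`,
#'   `n`.
#' @export
fit_bum <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) stop("fit_bum needs at least 100 p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of exactly 0 clamped to the machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  # unconstrained parameterization: lambda = plogis(u), a = plogis(v),
  # keeping lambda in (0,1) and a in (0,1); Nelder-Mead is robust to the
  # flat ridges this likelihood has near the pure-null boundary
  nll <- function(par) {
    lambda <- stats::plogis(par[1]); a <- stats::plogis(par[2])
    -sum(log(lambda + (1 - lambda) * a * p^(a - 1)))
  }
  starts <- list(c(0, 0), c(2, -2), c(-2, 2), c(4, 0), c(0, -4))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$convergence != 0)
    stop(sprintf("fit_bum: optimizer failed to converge (best nll %.4f)",
                 if (is.null(best)) NA_real_ else best$value))
  lambda <- stats::plogis(best$par[1]); a <- stats::plogis(best$par[2])
  structure(list(lambda_hat = lambda, a_hat = a,
                 pi0_upper = lambda + (1 - lambda) * a,
                 log_lik = -best$value, n = length(p)),
            class = "BumFit")
}

#' Estimated FDR of the rejection region p <= tau under a BUM fit
#'
#' Pounds-Morris construction: FDR(tau) = pi0_upper * tau / F(tau) with
#' F(tau) = lambda * tau + (1 - lambda) * tau^a, capped at 1. Monotone
#' increasing in tau for a < 1.
#'
#' @param bum a `BumFit`.
#' @param tau p-value threshold(s) in (0, 1].
#' @return FDR estimate(s) in \[0, 1\].
#' @export
bum_fdr <- function(bum, tau) {
  stopifnot(inherits(bum, "BumFit"))
  Ftau <- bum$lambda_hat * tau + (1 - bum$lambda_hat) * tau^bum$a_hat
  pmin(1, bum$pi0_upper * tau / Ftau)
}

#' Call SRAMs from a screened table
#'
#' A probe is a SRAM (its gene Significantly Repressed in Association with
#' Methylation) when its Spearman rho is at most `rho_cutoff` and its
#' BUM-estimated FDR at its own p-value is at most `fdr_cutoff` (defaults
#' rho <= -0.5, FDR <= 0.005). `fdr_only = TRUE` drops the rho criterion.
#'
#' @param table an `SramTable` from [spearman_screen()].
#' @param bum a `BumFit` of the table's tested p-values.
#' @param rho_cutoff,fdr_cutoff call thresholds.
#' @param fdr_only ignore the rho criterion.
#' @return the table with `fdr` and `is_sram` columns added.
#' @export
call_srams <- function(table, bum, rho_cutoff = -0.5, fdr_cutoff = 0.005,
                       fdr_only = FALSE) {
  stopifnot(inherits(bum, "BumFit"))
  table$fdr <- NA_real_
  table$fdr[table$tested] <- bum_fdr(bum, table$p_value[table$tested])
  pass_fdr <- !is.na(table$fdr) & table$fdr <= fdr_cutoff
  pass_rho <- !is.na(table$rho) & table$rho <= rho_cutoff
  table$is_sram <- if (fdr_only) pass_fdr else pass_fdr & pass_rho
  table
}

#' Collapse an SramTable to unique genes
#'
#' One row per gene symbol, keeping the probe with the most negative rho
#' (NA rho sorts last). Used to report unique-gene counts for probe-level
#' calls.
#'
#' @param table an `SramTable`; typically pre-filtered, e.g.
#'   `table[table$is_sram, ]`.
#' @return the collapsed data.frame, one row per gene.
#' @export
collapse_sram_genes <- function(table) {
  table <- table[!is.na(table$gene_symbol), , drop = FALSE]
  ord <- order(table$gene_symbol, table$rho, method = "radix")
  table <- table[ord, , drop = FALSE]
  table[!duplicated(table$gene_symbol), , drop = FALSE]
}

#' Summarize the rho distribution against a Gaussian reference
#'
#' Per CpG-island stratum: a histogram of rho; a Gaussian reference with the
#' stratum's observed mean and SD; the crossing point below which observed
#' bin counts exceed the Gaussian expectation (first sign change scanning
#' from -1 upward); the observed-minus-expected excess count at
#' rho <= `rho_cutoff` with a one-sided binomial p-value against the Gaussian
#' tail mass; and a two-proportion test comparing SRAM fractions between the
#' strata.
#'
#' @param table an `SramTable` (after [call_srams()] if SRAM fractions are to
#'   use calls; otherwise the rho <= `rho_cutoff` rule stands in).
#' @param rho_cutoff left-tail threshold (default -0.5).
#' @param n_bins histogram bins over \[-1, 1\].
#' @return list with one entry per stratum (`cpgi`, `non_cpgi`) plus
#'   `stratum_comparison`.
#' @export
rho_distribution_report <- function(table, rho_cutoff = -0.5, n_bins = 40) {
  tab <- table[table$tested & !is.na(table$rho), , drop = FALSE]
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  is_sram <- if ("is_sram" %in% names(tab)) tab$is_sram else
    tab$rho <= rho_cutoff
  out <- list()
  for (stratum in c(TRUE, FALSE)) {
    nm <- if (stratum) "cpgi" else "non_cpgi"
    rho <- tab$rho[tab$cpg_island == stratum]
    if (length(rho) == 0) {
      warning(sprintf("stratum '%s' empty; omitted", nm))
      next
    }
    mu <- mean(rho); sdv <- stats::sd(rho); n <- length(rho)
    h <- graphics::hist(rho, breaks = breaks, plot = FALSE)
    expected <- n * diff(stats::pnorm(breaks, mu, sdv))
    # crossing point: scanning upward from -1 starting at the first occupied
    # bin, the first break where the observed-minus-expected count changes
    # sign (the left-tail excess region ends there)
    diffc <- h$counts - expected
    first_occ <- which(h$counts > 0)[1]
    crossing <- NA_real_
    if (!is.na(first_occ) && diffc[first_occ] > 0) {
      after <- which(diffc <= 0 & seq_along(diffc) > first_occ)
      if (length(after) > 0) crossing <- breaks[after[1]]
    }
    tail_mass <- stats::pnorm(rho_cutoff, mu, sdv)
    obs_tail <- sum(rho <= rho_cutoff)
    excess <- obs_tail - n * tail_mass
    p_excess <- stats::pbinom(obs_tail - 1, n, tail_mass, lower.tail = FALSE)
    out[[nm]] <- list(
      n = n, mean = mu, sd = sdv,
      breaks = breaks, counts = h$counts, expected = expected,
      crossing_point = crossing,
      observed_at_cutoff = obs_tail,
      expected_at_cutoff = n * tail_mass,
      excess_at_cutoff = excess,
      binomial_p = p_excess)
  }
  k1 <- sum(is_sram & tab$cpg_island)
  k2 <- sum(is_sram & !tab$cpg_island)
  n1 <- sum(tab$cpg_island); n2 <- sum(!tab$cpg_island)
  if (n1 > 0 && n2 > 0) {
    pt <- suppressWarnings(
      stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
    out$stratum_comparison <- list(
      sram_fraction_cpgi = k1 / n1, sram_fraction_non_cpgi = k2 / n2,
      p_value = pt$p.value)
  }
  out
}

#' Fraction of SRAM probes near the transcription start site
#'
#' @param table an `SramTable` with SRAM calls.
#' @param window_bp half-width of the TSS window in bp (default 500).
#' @return fraction of called SRAM probes with |tss_distance| <= window_bp;
#'   probes with missing distance are excluded from the denominator and
#'   counted in a message.
#' @export
tss_proximity_fraction <- function(table, window_bp = 500) {
  if (!"is_sram" %in% names(table)) stop("run call_srams first")
  sub <- table[table$is_sram, , drop = FALSE]
  if (nrow(sub) == 0) stop("no SRAM calls in table")
  miss <- is.na(sub$tss_distance)
  if (any(miss))
    message(sprintf("tss_proximity_fraction: %d SRAM probe(s) with missing tss_distance excluded",
                    sum(miss)))
  sub <- sub[!miss, , drop = FALSE]
  mean(abs(sub$tss_distance) <= window_bp)
}
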