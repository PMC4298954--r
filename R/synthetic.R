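#' Configuration for the synthetic panel generator
#'
#' Defaults emulate the study conditions the pipeline assumes: a ~70-sample
#' cell-line panel in which ~3% of methylation probes are planted SRAMs with
#' realized Spearman rho near -0.7, a fifth of SRAM genes additionally
#' differentially methylated between two latent epithelial/mesenchymal
#' groups (beta difference ~0.4, with an 80% majority methylated in the
#' mesenchymal group), and 85% of SRAM probes within 500 bp of the TSS.
#'
#' `noise_sd = NULL` calibrates the expression noise from `sram_rho_target`
#' via the bivariate-normal rank-correlation identity
#' rho_S = (6/pi) asin(r/2): the Pearson correlation r on the latent scale
#' is 2 sin(pi |rho_S| / 6) and the noise SD is sqrt(1/r^2 - 1).
#'
#' @param n_samples number of cell lines (>= 6; default 70).
#' @param n_probes methylation probes (default 4000).
#' @param n_genes expression genes, including all probe-mapped genes
#'   (default 3200).
#' @param sram_fraction fraction of probes planted as SRAMs (default 0.03);
#'   0 gives a fully null panel.
#' @param sram_rho_target planted Spearman correlation (default -0.7).
#' @param em_fraction_of_srams fraction of SRAM genes that are
#'   group-differential (default 0.2).
#' @param m_sram_share share of group-differential SRAM genes methylated in
#'   the mesenchymal group (default 0.8).
#' @param tss_inside_fraction fraction of SRAM probes within +-500 bp of the
#'   TSS (default 0.85).
#' @param noise_sd expression noise SD on the standardized latent scale;
#'   NULL = calibrate from `sram_rho_target`.
#' @param seed integer; fixes all randomness end-to-end.
#' @return a `GeneratorConfig` list.
#' @export
generator_config <- function(n_samples = 70, n_probes = 4000, n_genes = 3200,
                             sram_fraction = 0.03, sram_rho_target = -0.7,
                             em_fraction_of_srams = 0.2, m_sram_share = 0.8,
                             tss_inside_fraction = 0.85, noise_sd = NULL,
                             seed = 1) {
  stopifnot(n_samples >= 6,
            sram_fraction >= 0, sram_fraction <= 1,
            em_fraction_of_srams >= 0, em_fraction_of_srams <= 1,
            m_sram_share >= 0, m_sram_share <= 1,
            tss_inside_fraction >= 0, tss_inside_fraction <= 1,
            sram_rho_target >= -1, sram_rho_target <= 0)
  if (sram_fraction > 0 && sram_fraction * n_probes < 1)
    stop("infeasible config: sram_fraction * n_probes < 1")
  if (is.null(noise_sd)) {
    r <- 2 * sin(pi * abs(sram_rho_target) / 6)
    noise_sd <- sqrt(1 / r^2 - 1)
  }
  structure(list(n_samples = n_samples, n_probes = n_probes,
                 n_genes = n_genes, sram_fraction = sram_fraction,
                 sram_rho_target = sram_rho_target,
                 em_fraction_of_srams = em_fraction_of_srams,
                 m_sram_share = m_sram_share,
                 tss_inside_fraction = tss_inside_fraction,
                 noise_sd = noise_sd, seed = seed),
            class = "GeneratorConfig")
}

# Derive independent sub-seeds from the master seed so components can be
# regenerated without disturbing each other's streams.
.sub_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Generate a synthetic methylation/expression panel with planted truth
#'
#' Two latent sample groups (E and M, half each). Non-SRAM probes have beta
#' values independent of expression (stable logit-normal probes). Each SRAM
#' gene carries one or two probes driven by a shared latent logit
#' methylation trajectory; its expression is a baseline minus the
#' standardized latent signal plus calibrated noise, so the realized
#' Spearman correlation is close to `sram_rho_target`. A configured subset
#' of SRAM genes is additionally group-differential in beta (difference
#' ~0.4 on the beta scale), methylated in M for `m_sram_share` of them.
#' TSS distances place `tss_inside_fraction` of SRAM probes within
#' +-500 bp. E-cadherin RPPA tracks the E label, erlotinib IC50 is shifted
#' upward in the methylated (M) cluster, and canonical marker genes
#' (CDH1 and mesenchymal markers) are expressed consistently with the
#' labels.
#'
#' @param cfg a `GeneratorConfig`.
#' @return list: `panel` (a validated `OmicsPanel`) and `truth` with
#'   `probe_truth` (per probe: `is_sram`, `is_em_differential`,
#'   `em_direction`), `sample_labels`, `sram_genes`, `m_sram_genes`,
#'   `e_sram_genes`.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  seeds <- .sub_seeds(cfg$seed, 4)
  n <- cfg$n_samples
  set.seed(seeds[1])

  samples <- sprintf("CL%03d", seq_len(n))
  labels <- stats::setNames(rep(c("E", "M"), length.out = n), samples)
  labels <- labels[order(names(labels))]          # deterministic
  is_m <- labels == "M"

  n_sram_probes <- round(cfg$sram_fraction * cfg$n_probes)
  # ~25% of SRAM genes carry two probes, mirroring multi-probe promoters
  n_sram_genes <- if (n_sram_probes == 0) 0 else
    max(1, round(n_sram_probes / 1.25))
  probes_per_gene <- rep(1L, n_sram_genes)
  extra <- n_sram_probes - n_sram_genes
  if (extra > 0) probes_per_gene[seq_len(extra)] <- 2L

  sram_genes <- if (n_sram_genes > 0) sprintf("SG%04d", seq_len(n_sram_genes))
    else character(0)
  n_bg_genes <- cfg$n_genes - n_sram_genes
  bg_genes <- sprintf("BG%04d", seq_len(n_bg_genes))

  # EM-differential SRAM genes
  n_em <- round(cfg$em_fraction_of_srams * n_sram_genes)
  em_genes <- if (n_em > 0) sample(sram_genes, n_em) else character(0)
  n_m_dir <- round(cfg$m_sram_share * n_em)
  m_genes <- if (n_m_dir > 0) sample(em_genes, n_m_dir) else character(0)
  e_genes <- setdiff(em_genes, m_genes)

  # latent logit methylation per SRAM gene
  set.seed(seeds[2])
  sigma_eps <- cfg$noise_sd
  beta_rows <- list(); probe_ids <- character(0)
  probe_gene <- character(0); probe_sram <- logical(0)
  expr <- matrix(NA_real_, nrow = cfg$n_genes + 6, ncol = n,
                 dimnames = list(c(sram_genes, bg_genes,
                                   c("CDH1", "VIM", "ZEB1", "TWIST1",
                                     "FN1", "CDH2")), samples))
  pid <- 0L
  for (gi in seq_len(n_sram_genes)) {
    g <- sram_genes[gi]
    if (g %in% m_genes) {
      mu <- ifelse(is_m, 0.85, -0.85)
      m_lat <- mu + stats::rnorm(n, 0, 0.8)
    } else if (g %in% e_genes) {
      mu <- ifelse(is_m, -0.85, 0.85)
      m_lat <- mu + stats::rnorm(n, 0, 0.8)
    } else {
      m_lat <- stats::rnorm(n, stats::rnorm(1, 0, 0.5), 1)
    }
    z <- if (stats::sd(m_lat) > 0) as.numeric(scale(m_lat)) else m_lat
    base <- stats::rnorm(1, 8, 1.5)
    # slope 1.5 log2 units per latent SD puts group-differential SRAM genes
    # past the 4-fold expression criterion; scaling signal and noise
    # together leaves the rank correlation at the calibrated target
    expr[g, ] <- base - 1.5 * z + (if (sigma_eps > 0)
      stats::rnorm(n, 0, 1.5 * sigma_eps) else 0)
    for (k in seq_len(probes_per_gene[gi])) {
      pid <- pid + 1L
      zz <- m_lat + (if (probes_per_gene[gi] > 1)
        stats::rnorm(n, 0, 0.3) else 0)
      beta_rows[[pid]] <- stats::plogis(zz)
      probe_ids[pid] <- sprintf("cg%06d", pid)
      probe_gene[pid] <- g
      probe_sram[pid] <- TRUE
    }
  }
  # null probes: stable, independent of expression
  n_null <- cfg$n_probes - n_sram_probes
  null_gene_pool <- if (n_bg_genes > 0) bg_genes else sram_genes
  for (j in seq_len(n_null)) {
    pid <- pid + 1L
    mu <- stats::rnorm(1, 0, 2)
    beta_rows[[pid]] <- stats::plogis(mu + stats::rnorm(n, 0, 0.5))
    probe_ids[pid] <- sprintf("cg%06d", pid)
    probe_gene[pid] <- null_gene_pool[((j - 1) %% length(null_gene_pool)) + 1]
    probe_sram[pid] <- FALSE
  }
  beta <- do.call(rbind, beta_rows)
  dimnames(beta) <- list(probe_ids, samples)

  # background gene expression, independent of any probe
  set.seed(seeds[3])
  for (g in bg_genes)
    expr[g, ] <- stats::rnorm(1, 8, 2) + stats::rnorm(n, 0, 1)
  # EMT marker genes consistent with the latent labels
  expr["CDH1", ]   <- ifelse(is_m, 6, 10)  + stats::rnorm(n, 0, 0.5)
  expr["VIM", ]    <- ifelse(is_m, 10, 6)  + stats::rnorm(n, 0, 0.5)
  expr["ZEB1", ]   <- ifelse(is_m, 9, 5.5) + stats::rnorm(n, 0, 0.5)
  expr["TWIST1", ] <- ifelse(is_m, 8.5, 6) + stats::rnorm(n, 0, 0.5)
  expr["FN1", ]    <- ifelse(is_m, 11, 8)  + stats::rnorm(n, 0, 0.5)
  expr["CDH2", ]   <- ifelse(is_m, 9, 6.5) + stats::rnorm(n, 0, 0.5)

  # probe annotation
  set.seed(seeds[4])
  tss <- integer(cfg$n_probes)
  inside <- stats::runif(cfg$n_probes) < ifelse(probe_sram,
                                                cfg$tss_inside_fraction, 0.5)
  tss[inside] <- as.integer(round(stats::runif(sum(inside), -500, 500)))
  sgn <- sample(c(-1, 1), sum(!inside), replace = TRUE)
  tss[!inside] <- as.integer(sgn * round(stats::runif(sum(!inside), 501, 1500)))
  cpgi <- stats::runif(cfg$n_probes) < 0.5
  probe_annot <- data.frame(probe_id = probe_ids, gene_symbol = probe_gene,
                            cpg_island = cpgi, tss_distance = tss,
                            stringsAsFactors = FALSE)

  ecad <- ifelse(is_m, -1, 1) + stats::rnorm(n, 0, 0.5)
  ic50 <- 10^(ifelse(is_m, 0.8, 0) + stats::rnorm(n, 0, 0.4))
  sample_annot <- data.frame(
    sample_id = samples,
    ecad_level = ecad,
    egfr_status = sample(c("WT", "mutant"), n, replace = TRUE,
                         prob = c(0.8, 0.2)),
    kras_status = sample(c("WT", "mutant"), n, replace = TRUE,
                         prob = c(0.75, 0.25)),
    erlotinib_ic50 = ic50,
    stringsAsFactors = FALSE)

  panel <- omics_panel(beta, expr, probe_annot, sample_annot)
  probe_truth <- data.frame(
    probe_id = probe_ids, gene_symbol = probe_gene, is_sram = probe_sram,
    is_em_differential = probe_gene %in% em_genes,
    em_direction = ifelse(probe_gene %in% m_genes, "M",
                          ifelse(probe_gene %in% e_genes, "E",
                                 NA_character_)),
    stringsAsFactors = FALSE)
  list(panel = panel,
       truth = list(probe_truth = probe_truth, sample_labels = labels,
                    sram_genes = sram_genes, em_genes = em_genes,
                    m_sram_genes = m_genes, e_sram_genes = e_genes))
}

#' Generate a gene network with a planted hub-proximity structure
#'
#' Builds a sparse random background graph over the non-hub nodes, wires the
#' hubs to each other and to a dedicated pool of first neighbors, then
#' places exactly `round(frac_within_2 * n_signature)` signature genes at
#' distance 1 or 2 from a hub; the remaining signature genes attach only to
#' background nodes at distance >= 2 from every hub, so their hub distance
#' is at least 3. Citation counts are elevated on hubs, their neighbor pool
#' and the near-hub signature genes against a low background rate.
#'
#' @param n_nodes total node count.
#' @param hubs character vector of hub symbols (will be nodes).
#' @param signature character vector of signature symbols (will be nodes).
#' @param frac_within_2 planted fraction of signature genes within 2 hops.
#' @param seed integer seed.
#' @param background_rate background cited-gene fraction (default 0.028).
#' @param enriched_rate cited fraction on the hub-proximal part
#'   (default 0.25).
#' @return list: `network` (a `GeneNetwork` with citation counts),
#'   `within_2_genes` (the planted near-hub signature genes).
#' @export
generate_network <- function(n_nodes, hubs, signature, frac_within_2 = 0.7,
                             seed = 1, background_rate = 0.028,
                             enriched_rate = 0.25) {
  stopifnot(frac_within_2 >= 0, frac_within_2 <= 1)
  if (anyDuplicated(c(hubs, signature)))
    stop("hubs and signature must be disjoint, duplicate-free symbol sets")
  set.seed(seed)
  n_bg <- n_nodes - length(hubs) - length(signature)
  if (n_bg < 20) stop("n_nodes too small for the requested hub/signature sets")
  bg <- sprintf("N%05d", seq_len(n_bg))
  nodes <- c(hubs, signature, bg)

  edges <- list()
  # background: sparse random graph (mean degree ~4)
  n_bg_edges <- 2 * n_bg
  e_bg <- cbind(sample(bg, n_bg_edges, replace = TRUE),
                sample(bg, n_bg_edges, replace = TRUE))
  e_bg <- e_bg[e_bg[, 1] != e_bg[, 2], , drop = FALSE]
  edges[[1]] <- e_bg
  # hubs: clique-ish interconnection + dedicated first-neighbor pool
  if (length(hubs) > 1)
    edges[[length(edges) + 1]] <- t(utils::combn(hubs, 2))
  pool_size <- max(5, length(hubs) * 3)
  pool <- sample(bg, pool_size)
  edges[[length(edges) + 1]] <- cbind(sample(hubs, pool_size, replace = TRUE),
                                      pool)
  n_in <- round(frac_within_2 * length(signature))
  within <- if (n_in > 0) sample(signature, n_in) else character(0)
  far <- setdiff(signature, within)
  for (g in within) {
    if (stats::runif(1) < 0.5) {
      edges[[length(edges) + 1]] <- cbind(g, sample(hubs, 1))       # dist 1
    } else {
      edges[[length(edges) + 1]] <- cbind(g, sample(pool, 1))       # dist 2
    }
  }
  # far signature genes: attach only to background nodes not adjacent to a
  # hub (distance >= 2 from every hub), keeping their own distance >= 3
  non_adjacent <- setdiff(bg, pool)
  for (g in far)
    edges[[length(edges) + 1]] <- cbind(g, sample(non_adjacent, 2))
  em <- do.call(rbind, edges)

  cited_pool <- c(hubs, pool, within)
  cc <- stats::setNames(integer(length(nodes)), nodes)
  bg_cited <- stats::runif(length(nodes)) < background_rate
  cc[bg_cited] <- stats::rpois(sum(bg_cited), 1.5) + 1L
  en_cited <- cited_pool[stats::runif(length(cited_pool)) < enriched_rate]
  cc[en_cited] <- stats::rpois(length(en_cited), 3) + 1L

  net <- gene_network(em, nodes = nodes, hub_genes = hubs,
                      citation_counts = cc)
  list(network = net, within_2_genes = within)
}

#' Generate a paired pre/post hypomethylating-treatment expression panel
#'
#' Selects mesenchymal and epithelial cell lines from a synthetic panel and
#' simulates post-treatment expression: genes planted as methylated in the
#' cell line's own type (M-SRAM genes in M cells, E-SRAM genes in E cells)
#' are induced by at least one log2 unit-plus-exponential with the
#' type-specific probability; all other genes fluctuate symmetrically.
#'
#' @param panel_truth the list returned by [generate_panel()].
#' @param induction_prob_m probability an M-methylated gene is re-expressed
#'   in an M cell (default 0.5).
#' @param induction_prob_e same for E-methylated genes in E cells
#'   (default 0.5).
#' @param n_m_cells,n_e_cells cell lines per type (defaults 4 and 3).
#' @param seed integer seed.
#' @param fluctuation_sd SD of the symmetric background log2 change
#'   (default 0.35).
#' @return an `AzaPanel` list: `pre`, `post` (gene x cell line),
#'   `cell_type` (named "E"/"M").
#' @export
generate_aza <- function(panel_truth, induction_prob_m = 0.5,
                         induction_prob_e = 0.5, n_m_cells = 4,
                         n_e_cells = 3, seed = 1, fluctuation_sd = 0.35) {
  stopifnot(induction_prob_m >= 0, induction_prob_m <= 1,
            induction_prob_e >= 0, induction_prob_e <= 1)
  set.seed(seed)
  truth <- panel_truth$truth
  expr <- panel_truth$panel$expr
  labs <- truth$sample_labels
  m_cells <- sample(names(labs)[labs == "M"], n_m_cells)
  e_cells <- sample(names(labs)[labs == "E"], n_e_cells)
  cells <- c(m_cells, e_cells)
  cell_type <- stats::setNames(c(rep("M", n_m_cells), rep("E", n_e_cells)),
                               cells)
  pre <- expr[, cells, drop = FALSE]
  post <- pre
  for (cl in cells) {
    delta <- stats::rnorm(nrow(pre), 0, fluctuation_sd)
    planted <- if (cell_type[[cl]] == "M") truth$m_sram_genes else
      truth$e_sram_genes
    pr <- if (cell_type[[cl]] == "M") induction_prob_m else induction_prob_e
    idx <- which(rownames(pre) %in% planted)
    fire <- idx[stats::runif(length(idx)) < pr]
    delta[fire] <- 1 + stats::rexp(length(fire), 2)
    post[, cl] <- pre[, cl] + delta
  }
  list(pre = pre, post = post, cell_type = cell_type)
}
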