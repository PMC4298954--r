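#' Construct and validate an omics panel
#'
#' An `OmicsPanel` bundles the four aligned tables the pipeline consumes: a
#' probe-by-sample matrix of methylation beta values (fraction methylated,
#' in \[0,1\]), a gene-by-sample matrix of log2 expression, a per-probe
#' annotation (gene symbol, CpG-island flag, signed distance to the
#' transcription start site) and a per-sample annotation (E-cadherin protein
#' level, mutation status, erlotinib IC50 where available).
#'
#' @param beta numeric matrix, probes x samples, values in \[0,1\].
#' @param expr numeric matrix, genes x samples, log2 scale.
#' @param probe_annot data.frame with columns `probe_id`, `gene_symbol`,
#'   `cpg_island` (logical), `tss_distance` (signed bp).
#' @param sample_annot data.frame with column `sample_id`; optional columns
#'   `ecad_level`, `egfr_status`, `kras_status`, `erlotinib_ic50`.
#' @return an object of class `OmicsPanel`.
#' @export
omics_panel <- function(beta, expr, probe_annot, sample_annot) {
  panel <- structure(
    list(beta = beta, expr = expr,
         probe_annot = probe_annot, sample_annot = sample_annot),
    class = "OmicsPanel")
  validate_panel(panel)
  panel
}

#' Validate an OmicsPanel
#'
#' Checks every structural invariant: beta bounds, identical ordered sample
#' columns in both matrices, no duplicated probe or sample ids, and that each
#' probe carries a gene symbol (empty symbols are tolerated only when the
#' probe is flagged unmapped by an NA symbol).
#'
#' @param panel an `OmicsPanel`.
#' @return the panel, invisibly; errors name the offending record.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "OmicsPanel"))
  beta <- panel$beta; expr <- panel$expr
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix")
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s' (%.4g)",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]],
                 beta[bad[1, 1], bad[1, 2]]))
  }
  if (!identical(colnames(beta), colnames(expr)))
    stop("sample columns of beta and expression matrices differ or are ordered differently")
  if (anyDuplicated(rownames(beta)))
    stop(sprintf("duplicated probe_id '%s'",
                 rownames(beta)[duplicated(rownames(beta))][1]))
  if (anyDuplicated(colnames(beta)))
    stop(sprintf("duplicated sample_id '%s'",
                 colnames(beta)[duplicated(colnames(beta))][1]))
  pa <- panel$probe_annot
  need <- c("probe_id", "gene_symbol", "cpg_island", "tss_distance")
  if (!all(need %in% names(pa)))
    stop("probe_annot must have columns: ", paste(need, collapse = ", "))
  empty <- !is.na(pa$gene_symbol) & !nzchar(pa$gene_symbol)
  if (any(empty))
    stop(sprintf("probe '%s' has an empty gene_symbol (use NA to flag unmapped)",
                 pa$probe_id[which(empty)[1]]))
  if (!"sample_id" %in% names(panel$sample_annot))
    stop("sample_annot must have a sample_id column")
  invisible(panel)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  # %.17g round-trips IEEE doubles exactly
  chr <- matrix(ifelse(is.na(m), "NA", sprintf("%.17g", m)),
                nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read an aligned methylation/expression panel from TSV files
#'
#' Matrices are TSV with a header row of sample ids and the feature id in the
#' first column. Samples are aligned by id intersection (never by column
#' order) and reordered to the common set; dropped samples are reported via
#' message. A `log2_transform = TRUE` flag applies log2(x + 1) to the
#' expression matrix for raw-scale inputs.
#'
#' @param beta_path,expr_path,probe_annot_path,sample_annot_path file paths.
#' @param log2_transform apply log2(x + 1) to expression on load.
#' @return a validated `OmicsPanel`.
#' @export
read_panel <- function(beta_path, expr_path, probe_annot_path,
                       sample_annot_path, log2_transform = FALSE) {
  beta <- read_matrix_tsv(beta_path)
  expr <- read_matrix_tsv(expr_path)
  if (log2_transform) expr <- log2(expr + 1)
  common <- intersect(colnames(beta), colnames(expr))
  if (length(common) == 0)
    stop("empty sample intersection between beta and expression matrices")
  dropped <- setdiff(union(colnames(beta), colnames(expr)), common)
  if (length(dropped) > 0)
    message(sprintf("read_panel: dropped %d sample(s) absent from one matrix: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  beta <- beta[, common, drop = FALSE]
  expr <- expr[, common, drop = FALSE]
  pa <- utils::read.delim(probe_annot_path, stringsAsFactors = FALSE)
  pa$cpg_island <- as.logical(pa$cpg_island)
  sa <- utils::read.delim(sample_annot_path, stringsAsFactors = FALSE)
  sa <- sa[match(common, sa$sample_id), , drop = FALSE]
  sa$sample_id <- common
  rownames(sa) <- NULL
  omics_panel(beta, expr, pa, sa)
}

#' Write an OmicsPanel to TSV files
#'
#' Inverse of [read_panel()]; round-trips matrices at full double precision
#' (values are printed with 17 significant digits).
#'
#' @param panel an `OmicsPanel`.
#' @param beta_path,expr_path,probe_annot_path,sample_annot_path output paths.
#' @export
write_panel <- function(panel, beta_path, expr_path, probe_annot_path,
                        sample_annot_path) {
  validate_panel(panel)
  write_matrix_tsv(panel$beta, beta_path, "probe_id")
  write_matrix_tsv(panel$expr, expr_path, "gene_symbol")
  utils::write.table(panel$probe_annot, probe_annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(panel$sample_annot, sample_annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(panel)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' name, description, member genes. Duplicate members within a set are
#' deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need at least 3", i, length(f)))
    nm[i] <- f[1]
    descs[i] <- f[2]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicated member(s) deduplicated", f[1]))
      members <- unique(members)
    }
    sets[[i]] <- members
  }
  names(sets) <- nm
  names(descs) <- nm
  attr(sets, "descriptions") <- descs
  class(sets) <- c("GeneSetCollection", "list")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors (a `GeneSetCollection`).
#' @param path output path.
#' @param descriptions optional per-set descriptions; defaults to the
#'   collection's stored descriptions or "na".
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Construct a gene interaction network
#'
#' Undirected simple graph over gene symbols with an optional designated hub
#' set and per-gene citation counts. Self-loops and duplicate edges are
#' removed.
#'
#' @param edges two-column character matrix or data.frame of symbol pairs.
#' @param nodes optional full node set (isolated nodes allowed).
#' @param hub_genes optional character vector, must be a subset of nodes.
#' @param citation_counts optional named non-negative integer vector.
#' @return a `GeneNetwork` (an igraph graph with metadata attributes).
#' @export
gene_network <- function(edges, nodes = NULL, hub_genes = character(0),
                         citation_counts = NULL) {
  em <- as.matrix(edges)
  storage.mode(em) <- "character"
  if (is.null(nodes)) nodes <- unique(as.vector(em))
  if (nrow(em) > 0 && !all(as.vector(em) %in% nodes))
    stop("edges reference nodes absent from the node set")
  g <- igraph::graph_from_data_frame(
    as.data.frame(em, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!all(hub_genes %in% nodes))
    stop("hub_genes must be a subset of network nodes")
  g$hub_genes <- unique(hub_genes)
  cc <- stats::setNames(rep(0L, length(nodes)), nodes)
  if (!is.null(citation_counts)) {
    if (any(citation_counts < 0)) stop("citation counts must be non-negative")
    cc[names(citation_counts)[names(citation_counts) %in% nodes]] <-
      citation_counts[names(citation_counts) %in% nodes]
  }
  g$citation_counts <- cc
  class(g) <- c("GeneNetwork", class(g))
  g
}

#' Read an interaction network in SIF format
#'
#' SIF dialect: whitespace-separated `source interaction_type target...`, one
#' or more targets per line. Interaction types are discarded; the graph is
#' undirected and simple (duplicate edges collapsed, self-loops dropped with
#' a warning). A line with a source but no interaction/targets contributes an
#' isolated node.
#'
#' @param path SIF file path.
#' @param hub_genes,citation_counts passed to [gene_network()].
#' @return a `GeneNetwork`.
#' @export
read_sif <- function(path, hub_genes = character(0), citation_counts = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  edges <- list()
  nodes <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) == 1) {            # isolated node
      nodes <- c(nodes, f)
      next
    }
    if (length(f) == 2)
      stop(sprintf("SIF line %d: source and interaction type but no target", i))
    src <- f[1]
    tg <- f[-(1:2)]
    if (any(tg == src)) {
      warning(sprintf("SIF line %d: self-loop on '%s' dropped", i, src))
      tg <- tg[tg != src]
    }
    if (length(tg) > 0)
      edges[[length(edges) + 1]] <- cbind(src, tg)
    nodes <- c(nodes, src, tg)
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2)
  gene_network(em, nodes = unique(nodes), hub_genes = hub_genes,
               citation_counts = citation_counts)
}

#' Write a GeneNetwork in SIF format
#'
#' Each edge emitted once as `a <type> b` with a constant interaction type.
#'
#' @param net a `GeneNetwork`.
#' @param path output path.
#' @param type interaction-type token written on every line.
#' @export
write_sif <- function(net, path, type = "interacts") {
  el <- igraph::as_edgelist(net)
  lines <- if (nrow(el)) paste(el[, 1], type, el[, 2]) else character(0)
  iso <- setdiff(igraph::V(net)$name, unique(as.vector(el)))
  writeLines(c(lines, iso), path)
  invisible(net)
}

#' Write / read an SramTable as TSV
#'
#' Plain TSV serialization of the per-probe screen table (probe id, gene
#' symbol, rho, p-value, FDR, SRAM flag, CpG-island flag, TSS distance, and
#' any extra columns present).
#'
#' @param table an `SramTable` data.frame.
#' @param path output path.
#' @export
write_sram_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(table)
}

#' @rdname write_sram_table
#' @return `read_sram_table` returns the table with `SramTable` class.
#' @export
read_sram_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(tab)))
    stop("not an SramTable TSV: needs probe_id and gene_symbol columns")
  class(tab) <- c("SramTable", "data.frame")
  tab
}
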