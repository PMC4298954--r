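#' Shortest-path profile of target genes against hub genes
#'
#' Unit-weight shortest paths (Dijkstra degenerating to breadth-first
#' search) from every mapped target to its nearest hub. Unreachable targets
#' are reported with infinite distance and excluded from the denominator of
#' the <= 2-hop summary fraction; targets absent from the network are listed
#' separately.
#'
#' @param net a `GeneNetwork`.
#' @param hubs character vector of hub gene symbols.
#' @param targets character vector of target symbols (e.g. EMT-SRAM genes).
#' @return list: `min_distance` (named, mapped targets; Inf if
#'   unreachable), `unmapped` (targets absent from the network),
#'   `n_mapped`, `fraction_within_2` (reachable mapped targets at distance
#'   <= 2 over reachable mapped targets).
#' @export
shortest_path_profile <- function(net, hubs, targets) {
  nodes <- igraph::V(net)$name
  hubs_in <- intersect(hubs, nodes)
  if (length(hubs_in) == 0) stop("no hub gene maps into the network")
  mapped <- intersect(targets, nodes)
  if (length(mapped) == 0) stop("no target gene maps into the network")
  unmapped <- setdiff(targets, nodes)
  d <- igraph::distances(net, v = hubs_in, to = mapped, weights = NA)
  min_d <- apply(d, 2, min)
  reach <- is.finite(min_d)
  list(min_distance = min_d,
       unmapped = unmapped,
       n_mapped = length(mapped),
       n_reachable = sum(reach),
       fraction_within_2 = if (any(reach)) mean(min_d[reach] <= 2) else NA_real_)
}

#' Hypergeometric linking-gene filter
#'
#' A candidate is any network gene adjacent to at least one gene of the
#' signature-or-hub set without belonging to it. For each candidate with
#' degree d and x neighbors inside the set, the one-sided hypergeometric
#' tail p-value of drawing at least x marked genes in d draws from the
#' network node universe is computed; candidates with p <= alpha are the
#' linking genes.
#'
#' @param net a `GeneNetwork`.
#' @param hubs,signature character vectors of symbols.
#' @param alpha retention threshold (default 0.05).
#' @return data.frame `gene`, `degree`, `neighbors_in_set`, `p_value`,
#'   restricted to retained genes, ordered by p.
#' @export
linking_gene_filter <- function(net, hubs, signature, alpha = 0.05) {
  nodes <- igraph::V(net)$name
  marked <- intersect(union(hubs, signature), nodes)
  n_marked <- length(marked)
  n_nodes <- length(nodes)
  if (n_marked == 0) stop("no hub or signature gene maps into the network")
  nbrs_of_marked <- unique(unlist(
    igraph::adjacent_vertices(net, marked)))
  cand <- setdiff(igraph::V(net)$name[nbrs_of_marked], marked)
  if (length(cand) == 0)
    return(data.frame(gene = character(0), degree = integer(0),
                      neighbors_in_set = integer(0), p_value = numeric(0)))
  deg <- igraph::degree(net, v = cand)
  x <- vapply(cand, function(g) {
    nb <- igraph::neighbors(net, g)$name
    sum(nb %in% marked)
  }, integer(1))
  p <- stats::phyper(x - 1, n_marked, n_nodes - n_marked, deg,
                     lower.tail = FALSE)
  out <- data.frame(gene = cand, degree = as.integer(deg),
                    neighbors_in_set = x, p_value = p,
                    stringsAsFactors = FALSE)
  out <- out[out$p_value <= alpha, , drop = FALSE]
  out[order(out$p_value, out$gene), , drop = FALSE]
}

#' Assemble the hub-anchored subnetwork
#'
#' Induced subgraph on hubs ∪ signature ∪ linking genes (those present in
#' the network), with each node annotated by role. Roles partition the node
#' set: a hub stays a hub even if also in the signature; linking genes are by
#' construction outside both.
#'
#' @param net a `GeneNetwork`.
#' @param hubs,signature,linking character vectors of symbols.
#' @return a `SubnetworkResult` list: `subnetwork` (a `GeneNetwork`),
#'   `roles` (named character: "hub", "signature", "linking").
#' @export
assemble_subnetwork <- function(net, hubs, signature, linking) {
  nodes <- igraph::V(net)$name
  members <- intersect(unique(c(hubs, signature, linking)), nodes)
  sub <- igraph::induced_subgraph(net, members)
  if (igraph::ecount(sub) == 0)
    warning("assembled subnetwork has no edges")
  roles <- stats::setNames(rep("linking", length(members)), members)
  roles[members %in% signature] <- "signature"
  roles[members %in% hubs] <- "hub"
  sub$hub_genes <- intersect(hubs, members)
  sub$citation_counts <- net$citation_counts[members]
  class(sub) <- c("GeneNetwork", class(sub))
  structure(list(subnetwork = sub, roles = roles),
            class = "SubnetworkResult")
}

#' Literature-citation enrichment of a subnetwork
#'
#' A gene is "cited" when its citation count reaches `min_citations`
#' (default 1; missing counts are 0). Reports the cited fraction in the
#' subnetwork versus the full network and the one-sided hypergeometric
#' enrichment p-value of the subnetwork's cited count.
#'
#' @param subnet a `GeneNetwork` (the subnetwork).
#' @param full_net a `GeneNetwork` containing it.
#' @param citation_counts named integer vector; defaults to the full
#'   network's stored counts.
#' @param min_citations threshold for calling a gene cited.
#' @return list: `fraction_subnet`, `fraction_full`, `p_value`,
#'   `n_cited_subnet`, `n_cited_full`.
#' @export
citation_enrichment <- function(subnet, full_net, citation_counts = NULL,
                                min_citations = 1) {
  if (is.null(citation_counts)) citation_counts <- full_net$citation_counts
  sub_nodes <- igraph::V(subnet)$name
  all_nodes <- igraph::V(full_net)$name
  if (length(sub_nodes) > length(all_nodes))
    stop("subnetwork larger than the full network")
  cc <- stats::setNames(rep(0L, length(all_nodes)), all_nodes)
  have <- intersect(names(citation_counts), all_nodes)
  cc[have] <- citation_counts[have]
  cited <- cc >= min_citations
  k_sub <- sum(cited[sub_nodes])
  k_all <- sum(cited)
  n_all <- length(all_nodes); n_sub <- length(sub_nodes)
  p <- if (k_all == 0) 1 else
    stats::phyper(k_sub - 1, k_all, n_all - k_all, n_sub,
                  lower.tail = FALSE)
  list(fraction_subnet = if (n_sub > 0) k_sub / n_sub else 0,
       fraction_full = if (n_all > 0) k_all / n_all else 0,
       p_value = p, n_cited_subnet = k_sub, n_cited_full = k_all)
}
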