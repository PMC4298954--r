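test_that("shortest-path profile matches brute-force BFS on a 5-node fixture", {
  edges <- rbind(c("A", "B"), c("B", "C"), c("C", "D"))
  net <- gene_network(edges, nodes = c("A", "B", "C", "D", "E"))
  sp <- shortest_path_profile(net, hubs = "A", targets = c("A", "C", "E", "X"))
  expect_equal(unname(sp$min_distance["A"]), 0)   # hub itself
  expect_equal(unname(sp$min_distance["C"]), 2)   # A-B-C
  expect_true(is.infinite(sp$min_distance["E"]))  # disconnected
  expect_equal(sp$unmapped, "X")
  # unreachable targets excluded from the <=2 denominator
  expect_equal(sp$fraction_within_2, 1)
  # independent frontier-expansion oracle on every node
  d_oracle <- oracle_bfs(edges, c("A", "B", "C", "D", "E"), "A")
  expect_equal(unname(sp$min_distance[c("A", "C")]),
               unname(d_oracle[c("A", "C")]))
  expect_equal(unname(d_oracle["D"]), 3)
})

test_that("unit-weight Dijkstra and BFS agree on random graphs", {
  set.seed(8)
  for (i in 1:5) {
    n <- 30
    em <- cbind(sample(paste0("n", 1:n), 45, TRUE),
                sample(paste0("n", 1:n), 45, TRUE))
    em <- em[em[, 1] != em[, 2], , drop = FALSE]
    net <- gene_network(em, nodes = paste0("n", 1:n))
    d_bfs <- igraph::distances(net, weights = NA)          # BFS
    d_dij <- igraph::distances(net,
                               weights = rep(1, igraph::ecount(net)),
                               algorithm = "dijkstra")
    expect_equal(d_bfs, d_dij)
    # spot-check one source against the naive frontier oracle
    src <- sample(paste0("n", 1:n), 1)
    expect_equal(unname(d_bfs[src, paste0("n", 1:n)]),
                 unname(oracle_bfs(em, paste0("n", 1:n), src)))
  }
})

test_that("linking-gene filter equals the hypergeometric enumeration oracle", {
  # candidate L: all 5 neighbors are signature genes; universe 20 nodes
  sig <- paste0("S", 1:8)
  bg <- paste0("B", 1:11)
  nodes <- c(sig, bg, "L")
  edges <- rbind(cbind("L", sig[1:5]),
                 cbind(bg[1:5], bg[2:6]))
  net <- gene_network(edges, nodes = nodes)
  out <- linking_gene_filter(net, hubs = character(0), signature = sig,
                             alpha = 1)
  row <- out[out$gene == "L", ]
  expect_equal(row$neighbors_in_set, 5L)
  expect_equal(row$p_value, oracle_hyper_enum_p(5, 20, 8, 5),
               tolerance = 1e-12)
  # candidate with no signature neighbors is not retained even at alpha 1?
  # it is a non-candidate: not adjacent to the marked set at all
  expect_false(any(bg[3] == out$gene))
  # alpha = 0 gives an empty linking set
  expect_equal(nrow(linking_gene_filter(net, character(0), sig, alpha = 0)), 0)
})

test_that("linking filter output is anti-monotone in alpha", {
  set.seed(19)
  em <- cbind(sample(paste0("n", 1:60), 150, TRUE),
              sample(paste0("n", 1:60), 150, TRUE))
  em <- em[em[, 1] != em[, 2], , drop = FALSE]
  net <- gene_network(em, nodes = paste0("n", 1:60))
  sig <- paste0("n", 1:12)
  alphas <- c(0.01, 0.05, 0.2, 1)
  sets <- lapply(alphas, function(a)
    linking_gene_filter(net, character(0), sig, a)$gene)
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("subnetwork assembly induces exactly the parent edges; roles partition", {
  edges <- rbind(c("H1", "S1"), c("S1", "L1"), c("L1", "B1"),
                 c("H1", "H2"), c("S2", "B1"))
  net <- gene_network(edges, nodes = c("H1", "H2", "S1", "S2", "L1", "B1"))
  res <- assemble_subnetwork(net, hubs = c("H1", "H2"),
                             signature = c("S1", "S2"), linking = "L1")
  el <- igraph::as_edgelist(res$subnetwork)
  pairs <- sort(apply(el, 1, function(r) paste(sort(r), collapse = "-")))
  expect_equal(pairs, c("H1-H2", "H1-S1", "L1-S1"))   # hand enumeration
  expect_setequal(names(res$roles), c("H1", "H2", "S1", "S2", "L1"))
  expect_equal(sum(res$roles == "hub"), 2)
  expect_equal(sum(res$roles == "signature"), 2)
  expect_equal(sum(res$roles == "linking"), 1)
  # a gene in both hub and signature lists takes the hub role (no overlap)
  res2 <- suppressWarnings(
    assemble_subnetwork(net, hubs = "S1", signature = c("S1", "S2"),
                        linking = character(0)))
  expect_equal(unname(res2$roles["S1"]), "hub")

  # union inducing no edges warns
  expect_warning(assemble_subnetwork(net, hubs = "H2", signature = "S2",
                                     linking = character(0)), "no edges")
})

test_that("citation enrichment equals the enumeration oracle and handles edge cases", {
  nodes <- paste0("n", 1:20)
  em <- cbind(nodes[1:19], nodes[2:20])
  cc <- setNames(rep(0L, 20), nodes)
  cc[1:6] <- 3L                             # cited genes
  net <- gene_network(em, nodes = nodes, citation_counts = cc)
  sub <- igraph::induced_subgraph(net, nodes[1:8])
  res <- citation_enrichment(sub, net)
  expect_equal(res$fraction_subnet, 6 / 8)
  expect_equal(res$fraction_full, 6 / 20)
  expect_equal(res$p_value, oracle_hyper_enum_p(6, 20, 6, 8),
               tolerance = 1e-12)
  # empty citation table: both fractions 0, p = 1
  net0 <- gene_network(em, nodes = nodes)
  sub0 <- igraph::induced_subgraph(net0, nodes[1:8])
  res0 <- citation_enrichment(sub0, net0)
  expect_equal(res0$fraction_subnet, 0)
  expect_equal(res0$p_value, 1)
  # identical cited fractions: no enrichment signal
  cc2 <- setNames(rep(c(1L, 0L), 10), nodes)
  net2 <- gene_network(em, nodes = nodes, citation_counts = cc2)
  sub2 <- igraph::induced_subgraph(net2, nodes[1:8])
  res2 <- citation_enrichment(sub2, net2)
  expect_gt(res2$p_value, 0.4)
})
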