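test_that("clustering recovers separable blocks and keeps duplicates together", {
  # two sample blocks with disjoint methylated probe sets
  b <- cbind(matrix(rep(c(0.9, 0.1), each = 4), 8, 4),
             matrix(rep(c(0.1, 0.9), each = 4), 8, 4))
  b <- b + matrix(runif(64, -0.02, 0.02), 8)
  dimnames(b) <- list(paste0("cg", 1:8), paste0("S", 1:8))
  cl <- cluster_samples(b, k = 2)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])
  expect_match(cl$newick, "^\\(")                 # serialized dendrogram

  # duplicated sample columns have zero distance -> same cluster
  b2 <- b; b2[, "S2"] <- b2[, "S1"]
  cl2 <- cluster_samples(b2, k = 3)
  expect_equal(cl2$labels[["S1"]], cl2$labels[["S2"]])

  expect_error(cluster_samples(b, k = 9), "k exceeds")
})

test_that("E/M labels: median split on E-cadherin, marker fallback otherwise", {
  sa <- data.frame(sample_id = paste0("S", 1:4), ecad_level = c(1, 2, 3, 4))
  out <- assign_em_labels(sa)
  expect_equal(unname(out$labels), c("M", "M", "E", "E"))
  expect_true(all(out$rule == "ecad_median"))

  # no RPPA at all -> fallback by marker z-score sign
  expr <- rbind(CDH1 = c(10, 10, 4, 4), VIM = c(4, 5, 10, 9),
                ZEB1 = c(3, 4, 9, 10))
  colnames(expr) <- paste0("S", 1:4)
  sa2 <- data.frame(sample_id = paste0("S", 1:4))
  out2 <- assign_em_labels(sa2, expr)
  expect_equal(unname(out2$labels), c("E", "E", "M", "M"))
  expect_true(all(out2$rule == "marker_sign"))
})

test_that("Wilcoxon rank-sum equals the permutation oracle on small fixtures", {
  # spec fixture: tied groups, oracle enumerates all 20 labelings
  x <- c(0.8, 0.9, 0.9); y <- c(0.1, 0.1, 0.2)
  expect_equal(wilcoxon_ranksum_p(x, y), oracle_wilcoxon_perm_p(x, y),
               tolerance = 1e-12)
  # identical distributions
  expect_equal(wilcoxon_ranksum_p(c(1, 2, 3), c(1, 2, 3)), 1)
  # constant probe
  expect_equal(wilcoxon_ranksum_p(rep(0.5, 4), rep(0.5, 5)), 1)
  # property: equals the oracle on random fixtures with <= 10 samples,
  # with and without ties
  set.seed(13)
  for (i in 1:15) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    vals <- if (i %% 2) round(runif(n1 + n2), 1) else rnorm(n1 + n2)
    xx <- vals[1:n1]; yy <- vals[(n1 + 1):(n1 + n2)]
    expect_equal(wilcoxon_ranksum_p(xx, yy), oracle_wilcoxon_perm_p(xx, yy),
                 tolerance = 1e-9)
  }
})

test_that("EMT-SRAM calls: direction from medians, invariances hold", {
  set.seed(23)
  n_e <- 6; n_m <- 6
  samples <- paste0("S", 1:12)
  labels <- setNames(rep(c("E", "M"), each = 6), samples)
  # probe 1: methylated in M; probe 2: methylated in E; probe 3: null
  b <- rbind(cg1 = c(runif(n_e, 0, 0.2), runif(n_m, 0.7, 0.95)),
             cg2 = c(runif(n_e, 0.7, 0.95), runif(n_m, 0, 0.2)),
             cg3 = runif(12, 0.4, 0.6))
  colnames(b) <- samples
  call <- call_emt_srams(b, labels, p_cutoff = 0.01)
  expect_true(call$table$is_emt_sram[1])
  expect_equal(call$table$direction[1], "M-SRAM")
  expect_equal(call$table$direction[2], "E-SRAM")
  expect_false(call$table$is_emt_sram[3])

  # invariant to sample column order
  perm <- sample(12)
  call2 <- call_emt_srams(b[, perm], labels, p_cutoff = 0.01)
  expect_equal(call2$table$wilcoxon_p, call$table$wilcoxon_p)
  expect_equal(call2$table$direction, call$table$direction)

  # swapping the label convention flips direction, keeps p
  swapped <- setNames(ifelse(labels == "E", "M", "E"), names(labels))
  call3 <- call_emt_srams(b, swapped, p_cutoff = 0.01)
  expect_equal(call3$table$wilcoxon_p, call$table$wilcoxon_p)
  expect_equal(call3$table$direction[1], "E-SRAM")

  expect_error(call_emt_srams(b[, 1:8], setNames(c(rep("E", 6), "M", "M"),
                                                 samples[1:8])),
               "3 samples per group")
})

test_that("EMT gene set membership is boundary-inclusive on log2 difference", {
  samples <- paste0("S", 1:8)
  labels <- setNames(rep(c("E", "M"), each = 4), samples)
  expr <- rbind(G1 = c(rep(10, 4), rep(8, 4)),     # exactly 2.0 -> in
                G2 = c(rep(10, 4), rep(8.1, 4)),   # 1.9 -> out
                G3 = c(rep(5, 4), rep(8, 4)))      # -3 -> in, negative sign
  colnames(expr) <- samples
  gs <- build_emt_gene_set(expr, labels)
  expect_setequal(gs$members, c("G1", "G3"))
  expect_equal(unname(gs$log2_fc["G1"]), 2)
  expect_equal(unname(gs$log2_fc["G3"]), -3)

  # noiseless planted recovery is exact
  set.seed(3)
  n_genes <- 500
  base <- matrix(8, n_genes, 8, dimnames = list(paste0("g", 1:n_genes),
                                                samples))
  planted <- sample(n_genes, 25)
  base[planted, labels == "E"] <- base[planted, labels == "E"] + 2.5
  gs2 <- build_emt_gene_set(base, labels)
  expect_setequal(gs2$members, paste0("g", planted))
})

test_that("hypergeometric overlap equals the enumeration oracle", {
  uni <- paste0("G", 1:10)
  a <- uni[1:3]; b <- uni[c(1, 2, 4, 5)]
  res <- signature_overlap(a, b, uni)
  expect_equal(res$overlap, 2)
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$p_value, oracle_hyper_enum_p(2, 10, 4, 3),
               tolerance = 1e-12)
  # identical sets: minimal p for the configuration
  res2 <- signature_overlap(a, a, uni)
  expect_equal(res2$overlap, 3)
  expect_equal(res2$p_value, oracle_hyper_enum_p(3, 10, 3, 3),
               tolerance = 1e-12)
  # disjoint sets in a large universe
  uni_big <- paste0("G", 1:1000)
  res3 <- signature_overlap(uni_big[1:5], uni_big[501:510], uni_big)
  expect_equal(res3$fraction, 0)
  expect_gt(res3$p_value, 0.9)
  expect_error(signature_overlap(character(0), b, uni), "non-empty")
})

test_that("EMT-SRAM gene summary collapses probes by most significant probe", {
  call <- structure(list(
    sample_labels = NULL,
    table = data.frame(
      probe_id = c("p1", "p2", "p3", "p4"),
      wilcoxon_p = c(1e-5, 1e-7, 1e-4, 0.5),
      is_emt_sram = c(TRUE, TRUE, TRUE, FALSE),
      direction = c("M-SRAM", "E-SRAM", "M-SRAM", NA),
      stringsAsFactors = FALSE)), class = "EmtCall")
  map <- c(p1 = "GA", p2 = "GA", p3 = "GB", p4 = "GC")
  s <- summarize_emt_call(call, map)
  expect_equal(s$n_probes, 3)
  expect_equal(s$n_genes, 2)
  # GA's direction comes from p2 (smaller p)
  expect_equal(s$n_e_genes, 1)
  expect_equal(s$n_m_genes, 1)
})
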