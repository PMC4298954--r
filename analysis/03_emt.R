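#!/usr/bin/env Rscript
# Stage 3: cluster cell lines on SRAM methylation, assign E/M labels from
# E-cadherin RPPA, call EMT-SRAMs by Wilcoxon rank-sum, and build the
# 4-fold EMT gene set from E/M differential expression.

suppressMessages(library(sramtools))
dir.create("results", showWarnings = FALSE)

g <- generate_panel(generator_config(seed = 1))
tab <- read_sram_table("results/sram_table.tsv")
sram_probes <- tab$probe_id[tab$is_sram]

cl <- cluster_samples(g$panel$beta[sram_probes, ], k = 2)
writeLines(cl$newick, "results/sram_dendrogram.nwk")
ari <- adjusted_rand_index(cl$labels, g$truth$sample_labels[names(cl$labels)])
cat(sprintf("hierarchical clustering (1-Pearson, average linkage): ARI vs planted labels %.3f\n",
            ari))

em <- assign_em_labels(g$panel$sample_annot, g$panel$expr)
cat(sprintf("E/M labels by E-cadherin median split: %d E, %d M; agreement with truth %.3f\n",
            sum(em$labels == "E", na.rm = TRUE),
            sum(em$labels == "M", na.rm = TRUE),
            mean(em$labels == g$truth$sample_labels[names(em$labels)],
                 na.rm = TRUE)))

call <- call_emt_srams(g$panel$beta[sram_probes, ], em$labels)
tr <- g$truth$probe_truth
summ <- summarize_emt_call(call, setNames(tr$gene_symbol, tr$probe_id))
write.table(merge(call$table, tr[, c("probe_id", "gene_symbol")],
                  by = "probe_id"),
            "results/emt_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("EMT-SRAMs (Wilcoxon p < 0.001): %d probes -> %d genes (%.0f%% of SRAMs), %d M-SRAM / %d E-SRAM\n",
            summ$n_probes, summ$n_genes,
            100 * summ$n_genes / length(g$truth$sram_genes),
            summ$n_m_genes, summ$n_e_genes))

gs <- build_emt_gene_set(g$panel$expr, em$labels)
write_gmt(list(emt_4fold = gs$members), "results/emt_gene_set.gmt")
cat(sprintf("EMT gene set (>= 4-fold between E and M): %d genes\n",
            length(gs$members)))

ov <- signature_overlap(summ$gene_table$gene_symbol, gs$members,
                        rownames(g$panel$expr))
cat(sprintf("EMT-SRAM overlap with the EMT gene set: %d/%d (%.0f%%), hypergeometric p = %.2e\n",
            ov$overlap, summ$n_genes, 100 * ov$fraction, ov$p_value))
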