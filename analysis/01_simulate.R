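#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic cell-line panel.
#
# The generator plants every structure the downstream stages assume: ~3% of
# probes behave as SRAMs (Spearman rho ~ -0.7 between promoter methylation
# and expression), a fifth of SRAM genes are differentially methylated
# between two latent epithelial/mesenchymal groups (80% methylated in M),
# 85% of SRAM probes sit within 500 bp of the TSS, E-cadherin RPPA tracks
# the E label and erlotinib IC50 is shifted up in the M cluster.
#
# The full matrices are large and reproducible from the seed, so they are
# written under scratch/ (regenerated on demand); the small ground-truth
# tables go to results/.

suppressMessages(library(sramtools))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/panel", recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = 1)
g <- generate_panel(cfg)

write_panel(g$panel,
            "scratch/panel/beta.tsv", "scratch/panel/expr.tsv",
            "scratch/panel/probe_annot.tsv", "scratch/panel/sample_annot.tsv")
write.table(g$truth$probe_truth, "results/ground_truth_probes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = names(g$truth$sample_labels),
                       em_label = g$truth$sample_labels),
            "results/ground_truth_samples.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("panel: %d probes x %d samples; %d planted SRAM probes (%d genes),
%d EM-differential genes (%d methylated-in-M)\n",
            nrow(g$panel$beta), ncol(g$panel$beta),
            sum(g$truth$probe_truth$is_sram), length(g$truth$sram_genes),
            length(g$truth$em_genes), length(g$truth$m_sram_genes)))
cat("matrices in scratch/panel/, ground truth in results/\n")
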