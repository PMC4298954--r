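#!/usr/bin/env Rscript
# Stage 5: shortest-path profile of EMT-SRAM genes against the EMT hub
# genes on a synthetic interaction network, linking-gene hypergeometric
# subnetwork, and literature-citation enrichment.

suppressMessages(library(sramtools))
dir.create("results", showWarnings = FALSE)

emt <- read.delim("results/emt_calls.tsv", stringsAsFactors = FALSE)
sig <- unique(emt$gene_symbol[emt$is_emt_sram])
hubs <- c("CDH1", "CDH2", "FN1", "SNAI1", "SNAI2", "GSC")

gn <- generate_network(3000, hubs, sig, frac_within_2 = 0.7, seed = 5)
sp <- shortest_path_profile(gn$network, hubs, sig)
cat(sprintf("%d/%d mapped EMT-SRAM genes within 2 hops of a hub (%.0f%%)\n",
            sum(sp$min_distance <= 2), sp$n_mapped,
            100 * sp$fraction_within_2))

lg <- linking_gene_filter(gn$network, hubs, sig)
cat(sprintf("linking genes at hypergeometric p <= 0.05: %d\n", nrow(lg)))
sub <- assemble_subnetwork(gn$network, hubs, sig, lg$gene)
write_sif(sub$subnetwork, "results/emt_subnetwork.sif")
write.table(data.frame(gene = names(sub$roles), role = sub$roles),
            "results/emt_subnetwork_roles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ce <- citation_enrichment(sub$subnetwork, gn$network)
cat(sprintf("cited genes: %.1f%% of the full network vs %.1f%% of the subnetwork (hypergeometric p = %.2e)\n",
            100 * ce$fraction_full, 100 * ce$fraction_subnet, ce$p_value))
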