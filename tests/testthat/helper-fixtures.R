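# Shared fixture builders. Everything is generated in code at test time.

make_tiny_panel <- function(n_samples = 6, n_probes = 4) {
  samples <- paste0("S", seq_len(n_samples))
  probes <- paste0("cg", seq_len(n_probes))
  genes <- paste0("G", seq_len(n_probes))
  set.seed(42)
  beta <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
                 dimnames = list(probes, samples))
  expr <- matrix(rnorm(n_probes * n_samples, 8), n_probes, n_samples,
                 dimnames = list(genes, samples))
  omics_panel(beta, expr,
              data.frame(probe_id = probes, gene_symbol = genes,
                         cpg_island = rep(c(TRUE, FALSE),
                                          length.out = n_probes),
                         tss_distance = seq(-300, 300,
                                            length.out = n_probes),
                         stringsAsFactors = FALSE),
              data.frame(sample_id = samples,
                         ecad_level = rnorm(n_samples),
                         stringsAsFactors = FALSE))
}

# small default generator config used by recovery tests (keeps runtimes low
# while preserving the planted structure of the full defaults)
small_config <- function(seed, ...) {
  generator_config(n_samples = 40, n_probes = 1200, n_genes = 1000,
                   seed = seed, ...)
}
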