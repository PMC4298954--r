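# sramtools

Integrative analysis of promoter CpG methylation and gene expression for
cancer cell-line panels. The package screens paired beta-value /
expression matrices for **SRAMs** — genes Significantly Repressed in
Association with Methylation — and follows them through the downstream
questions they raise: do they separate epithelial (E) from mesenchymal
(M) cell lines, which of them are differentially methylated between the
two states (EMT-SRAMs), how do they sit in the interaction neighborhood
of the core EMT factors, are they re-expressed by a hypomethylating
agent, and does their expression signature stratify drug response?

It is written for computational biologists working with
methylation-array + expression panels (NSCLC-style cell-line panels in
particular) who want each step of that chain as a tested, scriptable R
function.

## The statistics at the core

* **Screen** — per methylation probe, Spearman's &rho; (mid-ranks) between
  beta values and the gene's collapsed log2 expression; expression probes
  averaged when pairwise Pearson R &ge; 0.4. Candidate SRAMs satisfy
  &rho; &le; &minus;0.5 and FDR &le; 0.005.
* **FDR** — the p-values are modeled as a beta-uniform mixture
  f(p) = &lambda; + (1&minus;&lambda;)·a·p^(a&minus;1); the FDR of the
  region p &le; &tau; is &pi;&#8320;&tau;/F(&tau;) with
  &pi;&#8320; = &lambda; + (1&minus;&lambda;)a.
* **EMT-SRAMs** — two-sided Wilcoxon rank-sum (exact for small groups)
  on each SRAM probe between E and M lines at p &lt; 0.001; direction
  from group medians (M-SRAM = methylated in mesenchymal lines).
* **Enrichment** — weighted Kolmogorov-Smirnov running sum on a ranked
  gene list with gene-label permutation significance (preranked GSEA).
* **Network** — BFS/Dijkstra hub distances, hypergeometric linking-gene
  filter, and citation enrichment of the assembled subnetwork.
* **Treatment response** — per-gene 2-fold trichotomy (up/down/constant);
  P(p_up &gt; p_down | counts) in closed form from the
  Dirichlet-multinomial posterior (flat and conservative priors).
* **Signature score** — first principal component of z-scored signature
  expression, sign-anchored on CDH1.

A synthetic-data module plants every one of these structures with known
ground truth, so the whole pipeline is verified by recovery — no
external downloads.

## Worked example

The analysis scripts run the default synthetic panel end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_sram_discovery.R
Rscript analysis/03_emt.R
```

Stage 2 prints:

```
BUM fit: lambda=0.958 a=0.056 pi0<=0.960
SRAM calls: 120 probes -> 96 unique genes; sensitivity 1.000, empirical FDR 0.000
TSS proximity: 88.3% of SRAM probes within 500 bp
left-tail excess at rho <= -0.5 (CpGi): 61.1 probes, binomial p = 3.09e-50
SRAM fraction CpGi vs non-CpGi: 0.033 vs 0.027 (p = 0.37)
```

Reading: of 4000 probes, the screen calls exactly the 120 planted SRAM
probes (96 genes) and nothing else; the fitted mixture puts the null
proportion near 0.96 (3% of probes are planted signal); the &rho;
histogram of CpG-island probes shows a massive left-tail excess over its
Gaussian reference at &rho; &le; &minus;0.5, while the SRAM *fraction*
does not differ between CpG-island and non-island probes. Stage 3 then
reports:

```
hierarchical clustering (1-Pearson, average linkage): ARI vs planted labels 0.943
E/M labels by E-cadherin median split: 35 E, 35 M; agreement with truth 1.000
EMT-SRAMs (Wilcoxon p < 0.001): 26 probes -> 19 genes (20% of SRAMs), 15 M-SRAM / 4 E-SRAM
```

so about a fifth of SRAM genes are E/M-differential, ~80% of them
methylated in the mesenchymal lines — the planted structure. Stages 4-7
add the enrichment (ES &minus;0.977, p = 0.0014 for the EMT gene set on
the &rho; ranking), the network profile (68% of mapped EMT-SRAM genes
within 2 hops of an EMT hub; cited-gene fraction 2.9% network-wide vs
28.6% in the subnetwork), the treatment posteriors (&ge; 0.999 for
M-methylated genes in M cells, 0.5 where nothing was planted) and the
signature scores (PC1 separates E from M at p &asymp; 7e-13; the
methylated cluster has ~0.7 log10 higher IC50).

Equivalent calls are available directly as functions
(`spearman_screen()`, `fit_bum()`, `call_srams()`, `call_emt_srams()`,
`preranked_gsea()`, `posterior_up_exceeds_down()`, `pc1_score()`, ...);
see the vignette in `vignettes/` for the models and design decisions.

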