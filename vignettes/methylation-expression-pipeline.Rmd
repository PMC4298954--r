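---
title: "Integrative promoter methylation-expression analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative promoter methylation-expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sramtools)
```

## The problem

Promoter CpG methylation silences genes. Across a panel of cancer cell
lines, a gene whose promoter is differentially methylated *and* whose
expression falls as its methylation rises is a strong candidate for
epigenetic regulation — in this package's vocabulary, a SRAM (gene
Significantly Repressed in Association with Methylation). `sramtools`
implements the full analysis chain around that idea for non-small cell
lung cancer-style panels: SRAM discovery from paired beta-value and
expression matrices, epithelial/mesenchymal (E/M) classification of the
cell lines, EMT-SRAM calling, gene set enrichment, hub-anchored network
analysis, a Bayesian model of hypomethylating-agent (5-azacytidine-type)
re-expression, and a one-number principal-component signature score for
external samples.

Because the original cell-line matrices are not redistributable, the
package ships a synthetic-data module (`generate_panel()`,
`generate_network()`, `generate_aza()`) that plants every structure the
analysis assumes, with full ground truth. Every stage is tested by
recovering what the generator planted.

## The screening model

For each methylation probe, `spearman_screen()` computes the Spearman
correlation (mid-ranks for ties) between the probe's beta values
(methylation fraction in [0,1]) and the log2 expression of the probe's
gene, over pairwise-complete samples (at least 5 pairs). Expression is
first collapsed from probes to genes by `collapse_expression_probes()`,
averaging probes whose pairwise Pearson correlation reaches R >= 0.4.
Where several mutually-correlated subsets exist we average the largest
(ties broken by mean expression); a gene with no correlated pair keeps
its most highly expressed probe. The averaging rule itself is standard;
the subset tie-break is this package's choice and is deterministic.

Two-sided p-values use the t approximation for n >= 10 pairs and exact
permutation below that — the panel sizes this pipeline targets (~70
lines) make the approximation safe, while tiny fixtures stay exact.

### FDR by beta-uniform mixture

The p-value histogram of a genome-wide screen is modeled as
f(p) = &lambda; + (1 &minus; &lambda;)·a·p^(a&minus;1): a uniform null
component plus a Beta(a, 1) signal spike at the origin (a in (0,1]).
`fit_bum()` fits (&lambda;, a) by maximum likelihood (Nelder-Mead on a
logit-transformed parameterization, multiple starts) and reports the
standard upper bound on the null proportion,
&pi;&#8320; &le; &lambda; + (1 &minus; &lambda;)·a — the fitted density
at p = 1. The FDR of the rejection region p &le; &tau; is
&pi;&#8320;·&tau; / F(&tau;) (the Pounds-Morris construction), which is
monotone in &tau; for a < 1, so SRAM calls are monotone in the cutoff.
`call_srams()` requires both rho &le; &minus;0.5 and FDR &le; 0.005 by
default; a `fdr_only` flag drops the rho criterion, since reasonable
readings of the published selection differ on whether the two rules were
applied jointly.

`rho_distribution_report()` contrasts the observed rho histogram per
CpG-island stratum with a Gaussian reference carrying the stratum's own
mean and SD; the left-tail excess below rho = &minus;0.5 is tested
against the Gaussian tail mass with a one-sided binomial test. The
"crossing point" is the first sign change of observed-minus-expected
counts scanning upward from &minus;1 starting at the first occupied bin.

## E/M classification and EMT-SRAMs

`cluster_samples()` clusters samples on the SRAM beta submatrix with
1 &minus; Pearson correlation distance and average linkage — the usual
defaults for methylation heatmaps, chosen here because the source
analysis names neither; both are configurable and the result is
deterministic. `assign_em_labels()` labels a sample epithelial when its
E-cadherin protein level is at or above the panel median (the overlay
threshold is this package's choice), falling back to the sign of the
CDH1 z-score minus the mean mesenchymal-marker z-score (ZEB1, VIM,
TWIST1, FN1, CDH2) when RPPA coverage is below 80%.

`call_emt_srams()` runs a two-sided Wilcoxon rank-sum test per SRAM
probe between the E and M groups at unadjusted p < 0.001 (a BH column is
available via `bh = TRUE`). The exact distribution is used when both
groups have at most 12 samples — via the closed-form null when there are
no ties, and full enumeration of group assignments when there are —
otherwise the normal approximation with tie and continuity correction.
Direction uses group medians (robust on bounded beta values): higher
median beta in M means M-SRAM. Gene-level direction, where several
probes map to one gene, is taken from the most significant probe; the
published figure does not state its collapse rule, so this choice is
ours and is applied consistently.

## Enrichment

`enrichment_score()` implements the weighted Kolmogorov-Smirnov running
sum: walking a ranked gene list, hits increment by |score|^w normalized
by the set total, misses decrement by 1/(N &minus; n_set); the ES is the
signed extremum. `preranked_gsea()` assesses significance by gene-label
permutation — the input here is a ranking, not a sample-by-gene matrix,
so phenotype permutation is not applicable and the preranked convention
is used deliberately. The nominal p is the +1-corrected fraction of
same-sign permuted ES at least as extreme (never zero, approximately
uniform under the null); FDR q follows the normalized-ES procedure. Ties
in the ranking are broken by a stable sort on symbol for determinism.
Default size bounds are 15-500 and 1000 permutations, all seeded.

## Network analysis

Interaction networks are undirected with unit edge weights; interaction
direction is discarded because distances are treated symmetrically.
Shortest paths (Dijkstra, which degenerates to breadth-first search at
unit weights) give each signature gene its minimum distance to any hub;
the headline "fraction within 2 hops" uses mapped, reachable genes as
its denominator, with unreachable genes reported separately. Linking
genes are non-signature, non-hub neighbors of the signature-or-hub set
whose neighbor count inside that set is hypergeometrically surprising
given their degree (p &le; 0.05); the sampling universe is all network
nodes, the simplest defensible choice where the published universe is
unstated. Citation enrichment compares the fraction of genes with at
least one literature citation in the assembled subnetwork versus the
full network, again by hypergeometric tail. Citation counts are a
user-supplied table; live literature mining is out of scope.

## The treatment-response model

After a hypomethylating agent, each gene in each cell line is assigned
up / down / constant by `trichotomize()` at a 2-fold change (boundary
inclusive). The counts (n_up, n_down, n_const) for a gene category are
modeled as Multinomial with a Dirichlet prior; by the aggregation
property, p_up/(p_up + p_down) is Beta(a_up + n_up, a_down + n_down)
after marginalizing the constant category, so
P(p_up > p_down | counts) has a closed form — exact and fast, which is
why the closed form is the implementation and Monte Carlo and numeric
integration serve only as cross-checks in the tests. The flat prior
Dirichlet(1,1,1) is the uninformative choice; the conservative prior
defaults to Dirichlet(1,1,8), concentrating prior mass on "constant" to
encode that most genes do not respond. The original supplementary
parameterization is not public, so these hyperparameters are this
package's defaults and are always printed with the results. Posteriors
are reported per cell line and pooled within cell type — published
summaries exist at both granularities, so both modes are first-class.

## Signature scoring

`pc1_score()` z-scores each gene, then projects samples on the first
right singular vector. Standardization prevents high-variance genes from
dominating; whether the original computation standardized is unstated,
so the flag is exposed (`standardize`). The sign of a principal
component is arbitrary, so orientation is fixed by requiring a positive
loading on an anchor gene (CDH1 by default — epithelial samples then
score positive). IC50 values are log10-transformed before group
comparison because drug potencies are log-distributed.

## What the generator emulates — and what it does not

`generator_config()` defaults encode the study conditions: 70 samples,
4000 probes, 3% planted SRAM probes at target Spearman rho &minus;0.7,
20% of SRAM genes E/M-differential (beta difference ~0.4) with an 80%
M-methylated majority, and 85% of SRAM probes within 500 bp of the TSS.
Beta values are generated on the logit scale and squashed, which keeps
[0,1] bounds and gives the bimodal marginals methylation arrays show.
The expression of a SRAM gene is a baseline minus 1.5 log2 units per
latent-methylation SD plus Gaussian noise whose SD is calibrated from
the bivariate-normal identity rho_S = (6/&pi;)·asin(r/2), so the
realized rank correlation lands on the target; the 1.5 slope puts
group-differential SRAM genes past the 4-fold expression criterion, as
genes silenced by methylation are in real panels. One master seed
derives independent sub-streams per component.

The generator does *not* emulate array probe chemistry, batch effects,
normalization artifacts, probe cross-hybridization, or the correlation
structure of real co-regulated gene modules; null probes are independent
of expression by construction. Passing recovery tests therefore shows
the pipeline's statistics do what they claim under the assumed
generative structure — not that real data meet those assumptions.

Problem sizes used by the test-suite and acceptance runs (the package's
own choices): the default 70 x 4000 panel for single-run recovery;
40-sample, 1200-probe panels for the multi-seed loops (20 null-panel
seeds, 10 distribution seeds, 6 calibration seeds); a 3000-node network;
50 seeds for the power checks.

## Numerical and degenerate-input choices

* Zero-variance probes or expression rows are reported untested rather
  than producing NaN correlations; constant probes in a Wilcoxon test
  get p = 1.
* p-values of exactly 0 entering the BUM fit are clamped to the machine
  minimum with a warning; the fit requires at least 100 p-values.
* A gene set equal to the whole ranked list has no defined miss
  decrement; the uniform baseline i/N is substituted, keeping the
  profile inside a one-step envelope.
* Sample alignment is always by id intersection, never column order.
* Missing values are encoded "NA" in every TSV; correlations use
  pairwise-complete pairs.
* Matrix TSVs print doubles with 17 significant digits, so write/read
  round-trips are bit-exact.

## Known limitations

The BUM FDR is an upper-bound construction and conservative when the
signal component is far from Beta-shaped. The EMT-SRAM probe-to-gene
direction collapse (most significant probe) can mask genes whose probes
disagree. The linking-gene test treats network neighbors as a simple
random sample of nodes, ignoring degree correlation. The generator's
independence assumptions make the null panels cleaner than real arrays;
empirical FDR on real data will be higher than the recovery tests
suggest.
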