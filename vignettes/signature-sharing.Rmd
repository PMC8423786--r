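---
title: "Comparing transcriptional identities across single-cell datasets and clinical cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing transcriptional identities across single-cell datasets and clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigshare)
```

## The problem

Tumors such as childhood neuroblastoma are mixtures of cell populations, and
the clinically decisive question is often not *which genes* are expressed but
*which normal cell type* each malignant population resembles. Answering it
requires a chain of comparative operations: define what transcriptionally
characterizes each cell cluster, measure whether two clusters from different
datasets (possibly different species) share that characterization, score
individual cells against reference programs, separate malignant from stromal
populations by their copy-number clones, and ask whether a population's
program predicts survival or age at diagnosis in large bulk cohorts.
`sigshare` implements that chain as composable, tested functions. Clustering
itself, read processing, and per-cell error modeling are upstream concerns:
cluster labels, normalized matrices, and CNV state probabilities arrive as
inputs.

## Marker definitions: upregulated sets and specific signatures

Two definitions with different strictness drive everything downstream. For a
cluster $c$ with per-gene mean $\mu_{g,c}$ on the normalized matrix:

* **Upregulated set A**: genes with $\mu_{g,c} > \mu_{g,\bar c}$ (the pooled
  complement) and a Welch $t$-test BH-adjusted $p < 0.01$
  (`upregulated_genes()`).
* **Specific signature B**: genes that beat *every other cluster
  individually*: for each other cluster $k$, $\mu_{g,c} > \mu_{g,k}$ and the
  pairwise Welch test is BH-significant (`specific_signature()`).

B is the identity card of a cluster; A is its longer descriptive list. B is
not a subset of A by construction because the two test families differ.
Design choices worth stating:

* **BH family for B.** Correction is applied across all genes *within each
  pairwise comparison*, mirroring the per-comparison testing language; a
  pooled global family is available via `family = "global"`. The
  per-comparison default is the more conservative choice for membership in B
  because a gene must clear every comparison separately.
* **Zero-variance Welch inputs** take statistic 0 / $p = 1$ when the means
  are equal and $p = 0$ when two constant groups differ, a deterministic
  limit that avoids NaN propagation on sparse genes.
* **Ties in means fail.** "Higher" is a strict inequality.
* **Which matrix?** Tests run on whatever normalized matrix is supplied. The
  default analysis path is log1p-CP10K from `cp10k_normalize()`; externally
  standardized expression magnitudes (e.g. from an error-model pipeline) are
  equally valid inputs, and the Welch machinery is agnostic to the choice.

## Sharing signatures across datasets

`signature_sharing()` asks, for each pair of cluster signatures from two
datasets, whether their overlap is larger than chance within an explicit
gene universe, using a one-sided Fisher test
$P(X \ge \text{overlap})$ under the hypergeometric null. Two filters follow
the analysis conventions this pipeline encodes: pairs sharing fewer than 10
genes are reported but excluded from the BH family and from significance
calls, and significance is called at FDR 0.01 with a marginal tier up to
0.05 in `external_set_enrichment()`.

The universe is never implicit. The default recommendation — the
intersection of genes tested in both datasets, after ortholog restriction
for cross-species runs — is the only set both signatures are actually drawn
from; any other universe can be passed explicitly. Cross-species comparisons
first translate through `restrict_to_one_to_one()`: only genes with mapping
degree 1 on both sides of the ortholog table are kept, because 1:many
orthology makes "the same gene" ambiguous. Whether the ortholog table is
keyed by symbols or stable IDs is the caller's responsibility; identifiers
are opaque, case-sensitive strings throughout.

## Per-cell signature scoring

`signature_score()` measures each cell's resemblance to a reference program:

$$\text{score}(i) = \frac{1}{|R|}\sum_{g \in R}(x_{g,i}+1) -
\frac{1}{n}\sum_{g \in B}(x_{g,i}+1), \qquad n = \max(|R|, 50),$$

with $x$ in linear CP10K units and $B$ a background of $n$ genes drawn once
per call, uniformly without replacement from the non-reference genes, under
the supplied seed. The linear scale (not log) is deliberate: the score is a
difference of average expression levels, and the +1 cancels between the two
terms, so adding a constant to a cell changes nothing. An expression-binned
background (`scheme = "binned"`) is available for data with strong
mean-expression structure, but uniform is the default because nothing in the
score's definition conditions the background on expression.

## Composition and deconvolution expectations

`composition_test()` cross-tabulates each (cluster, clinical group) pair as
in/out-of-cluster by in/out-of-group and applies the two-sided Yates-corrected
chi-square, BH across all pairs at FDR 0.01. The per-pair 2x2 form
(rather than one R x C omnibus test) matches the question actually asked —
*which* cluster is over- or under-represented in *which* group — and the
R x C variant remains available behind `rxc = TRUE`.

`ls_deconvolve()` is a transparent non-negative least-squares stand-in for
reference-based bulk decomposition: adequate for synthetic validation and
for plumbing, and clearly not a published deconvolution model. Its output
(or any externally produced proportion table) feeds
`expected_cells_from_deconvolution()`, which converts group-mean cluster
proportions into expected cell counts via
$c = \text{avg nuclei per group} \times \text{bulk samples in group}$ and
tests the resulting cluster-by-group counts with the same Yates chi-square
machinery.

## CNV clone enrichment

Downstream of any six-state copy-number caller (states 1-6, 3 neutral), a
segment's *rearrangement likelihood* is the probability mass off the neutral
state; segments with neutral mass above 0.1 (likelihood below 0.9) are
discarded by `filter_cnv_calls()`. `region_state_per_cell()` averages the
most-likely state of kept segments overlapping a query region —
coordinates are 0-based half-open everywhere, so a segment ending exactly at
the region start does not overlap — and calls gain above 3, loss below.
All overlapping kept segments enter the average by default; a
direction-restricted variant is behind a flag, since restricting to
expected-direction segments is equally defensible when a region is queried
for a specific aberration. `cluster_rearrangement_enrichment()` then runs,
per sample independently, a one-sided Fisher test per cluster with BH across
cluster x region tests and an FDR 0.05 reporting threshold. Cells called
neutral and cells without regional data both count as non-rearranged (the
conservative choice); `drop_no_data = TRUE` excludes the latter.

## Survival association and the cutpoint scan

Bulk association starts from `signature_zscore_average()` (per-gene z-scores
across samples, averaged over the signature; signatures of two or fewer
usable genes are rejected for scanning). `kaplan_scan()` evaluates a
two-group log-rank test at every cutpoint between consecutive distinct
scores, subject to a minimum group fraction (default 10%, never fewer than
3 samples — the external scan tool this emulates does not document its
constraints, so ours are explicit and configurable), and returns the
cutpoint minimizing the raw p. Samples exactly at the cutpoint fall in the
low group.

A minimum over ~$0.8n$ correlated tests is anti-conservative: at these
thresholds the raw minimum-p is inflated by roughly a factor 20-30 (the
classical sup-statistic approximation over the 10-90% quantile range). A
Bonferroni family containing only the signatures tested would therefore
leave a 1.5-2.5% null rate at a nominal 0.01. For that reason the
reported family in `scan_signatures()` is **signatures x candidate
cutpoints**: `adjusted_p = raw_p * n_cutpoints * n_signatures`, capped at 1.
This absorbs the scan optimism by construction (Bonferroni is valid under
arbitrary dependence), costs little power against strong effects (the
planted hazard-ratio-3 signature is still detected in >90% of replicates at
$n = 200$), and the raw p is always reported alongside. The acceptance
suite verifies both properties.

Per-gene lists mirror the cohort-level machinery: `per_gene_group_differential()`
(one-way ANOVA on log2 expression with pseudocount 1 — unremarkable and
configurable), `per_gene_age_correlation()` (Pearson, direct/inverse split),
and `per_gene_survival_groups()` (a scan per gene, BH across genes,
worse/better-with-high split). `signature_label_enrichment()` closes the
loop by testing cluster signatures against those labeled lists with the same
Fisher/BH machinery.

## Cluster dendrograms with bootstrap support

`cluster_average_profiles()` takes per-cluster means,
`quantile_normalize()` equalizes the column distributions (limma's classic
algorithm), distances are Euclidean, and agglomeration is Ward.D2.
Cross-dataset trees require ortholog restriction *first* — only shared genes
can be compared, so restriction precedes quantile normalization — and any
cluster exclusions (e.g. dropping cortex and immune populations) are a
caller-supplied filter, not hard-coded.

`bootstrap_branch_support()` resamples genes with replacement at scales
0.5-1.4 (1000 replicates per scale by default, the conventional design for
multiscale bootstrap), counts each original branch's occurrence frequency
(BP), and fits the approximately unbiased support AU per branch by weighted
least squares of $\Phi^{-1}(1-\text{BP}_r)$ on $(\sqrt r, 1/\sqrt r)$,
evaluating $1 - \Phi(\hat d - \hat c)$ at the unit scale. Branches with
degenerate BP across scales keep AU = BP. AU > 95 is the conventional
"high support" reporting threshold. The fit is authored in-package,
following the standard multiscale-bootstrap formulation.

## The synthetic generator: what it emulates, and what it does not

`simulation_config()` fixes the study conditions all tests run under:

| parameter | default | rationale |
|---|---|---|
| clusters x cells | 4 x 100 | enough cells for stable Welch tests, small enough to run everywhere |
| genes | 2000 | keeps every planted block (<10% of genes) sparse in the universe |
| NB baseline | log-normal, meanlog 1, sdlog 1 | typical right-skewed mean distribution of read counts |
| dispersion | 0.1 | standard overdispersion for non-UMI read counts |
| unique markers | 20 per cluster, log2FC 2 | clearly separable but not trivial effects |
| shared signature | 30 genes, log2FC 2, cluster c1 of both datasets | one true positive pair among 16 |
| 1:many orthologs | 10% of genes, never planted genes | exercises the 1:1 restriction without destroying the truth |
| CNV clone | cluster c2, chr17 gain, state 5, penetrance 0.6 | sub-clonal but detectable |
| bulk cohort | n = 200, HR 3 per SD, age correlation 0.5 | effect sizes a 500-patient cohort analysis would call strong |

Survival times are exponential proportional hazards driven by the
standardized *realized* signature average (so the quantity the scan sees is
exactly the quantity that drives hazard), with uniform administrative
censoring at 1000-3000 days (roughly 60-70% events); age is generated at
the configured Pearson correlation with the same quantity; risk groups are
its tertiles, which creates the composition-versus-risk structure the
composition tests must detect. All randomness flows through the single seed
argument of each generator.

What the simulator deliberately does **not** emulate: gene-length and
GC bias, dropout curves beyond NB dispersion, batch effects, ambient RNA,
doublets, or correlated gene programs. Green tests therefore demonstrate
that the *statistical machinery* is correct and recovers planted structure
at realistic effect sizes — not that any particular biological dataset will
behave as cleanly.

## Problem sizes and numerical conventions

The test and acceptance runs use: signature recovery on the full default
configuration (two 2000 x 400 datasets); clone recovery over 50 seeds;
survival power over 30 cohorts of $n = 200$ and null calibration over
200 cohorts x 5 random signatures; dendrogram support with 1000 replicates
per scale on a 200-gene, 8-profile matrix with a planted deep split. These
sizes make every reported rate a stable Monte-Carlo estimate while keeping
a full run in tens of seconds.

Other conventions: CP10K columns must sum to 10,000 within 1e-6; CNV state
probabilities must sum to 1 within 1e-6; BH inputs must lie in [0, 1];
Fisher tables must be non-negative integers; `hclust` tie-breaking follows
the lowest-index convention of the underlying implementation.

## Limitations

* The deconvolution stand-in is ordinary NNLS; treat its proportions as
  plumbing, not estimates with the properties of published decomposition
  models.
* The scan's adjusted p is intentionally conservative; borderline
  associations (raw p within an order of magnitude of the threshold) should
  be followed up with a dedicated survival model rather than the scan.
* AU support relies on the asymptotic multiscale model; with few profiles
  or few genes, BP at the unit scale is the more trustworthy number.
* Per-sample CNV enrichment assumes the six-state probabilities are
  calibrated by the upstream caller; the likelihood filter cannot repair
  miscalibrated inputs.
```{r example, eval = FALSE}
cfg <- simulation_config()
sim <- generate_paired_datasets(cfg, seed = 1)
n1 <- cp10k_normalize(sim$expr1, log_transform = TRUE)
sets1 <- signature_sets(n1, sim$assign1)
lengths(sets1)
```
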