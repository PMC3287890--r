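---
title: "Two-step aggregation of rare-variant association signal: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step aggregation of rare-variant association signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdensea)
```

## The model

burdensea tests association between a quantitative trait and genetic
variation aggregated at two levels.

**Within genes.** Rare variants (sample MAF at or below a threshold,
default 0.01 inclusive) are individually untestable, so each gene is
summarized by a burden variable. The CMC family collapses only the rare
variants — into a carrier indicator (CMC-1) or a rare-allele count
(CMC-count) — and fits ordinary least squares of the trait on that variable
*plus each common variant of the gene*, reporting the joint F-test of all
genetic coefficients against the intercept-only model. The weighted-sum
family collapses *all* variants of the gene into one score per individual,
dividing each variant's dosage by `w_j = sqrt(n q_j (1 - q_j))` with the
pseudo-count frequency `q_j = (m_j + 1) / (2n + 2)`; the score is tested
either by a phenotype-permutation test of the centered cross product
(WeightSum1) or by the slope t-test of a simple regression (WeightSum2).
Minor-allele orientation is recomputed from the sample rather than taken
from a VCF's REF/ALT, because the collapse is defined on minor alleles; a
frequency tie at exactly 0.5 keeps the ALT coding.

**Across genes.** Gene-level results become gene scores, and a gene set is
tested by the running-sum enrichment statistic: genes ranked by decreasing
score, the running sum gaining `|score|^exponent` (normalized) at member
genes and losing `1/(G - m)` at non-members; the enrichment score ES is the
maximum-magnitude deviation. Significance is one-sided (enrichment, not
depletion) against a permutation null.

## One permutation plan, two uses

A single phenotype-permutation plan (default B = 2000) drives everything:
within one permutation, the *same* reshuffled trait is applied to every
gene. This matters because the set-level null must preserve correlation
between genes — long-distance correlation between genotypes is common, and
an enrichment null that permuted genes independently would understate the
variance of ES under the null. The plan yields, per gene and test, the
observed statistic, the B permuted statistics, and the add-one permutation
p-value `(1 + #{T_b >= T})/(B + 1)`, which can never be zero and whose
smallest attainable value is `1/(B + 1)`.

With an exhaustive plan (all `n!` permutations, `n <= 7`) the exact
enumeration p `#{T_b >= T}/n!` is reported instead, since the enumeration
already contains the identity permutation. Cross-product comparisons use a
`1e-9` relative tolerance so that permutations which merely reshuffle
individuals with equal collapsed scores — mathematical ties — count as ties
regardless of floating-point summation order.

## Why two p-value tracks, and what VSEA standardizes

Each gene score panel carries two transforms of the statistics:

- `p_permutation` — the rank-among-permutations p. This is the calibrated
  gene-level p-value: it is what the type-I-error guarantees attach to, what
  the replicate-level spurious filter consumes, and what a practitioner
  should report per gene.
- the score track — gene scores are `-log10` of the *analytic* p (the F or
  t distribution) for CMC-1, CMC-count and WeightSum2, applied identically
  to observed and permuted statistics; WeightSum1, having no analytic p,
  scores off the rank track.

The analytic p is deliberately used raw in the score track. Its per-gene
miscalibration — small-sample F behavior with few rare-allele carriers,
varying degrees of freedom with gene size, allele-frequency composition —
is precisely the heterogeneity that makes naive enrichment (GSEA) drift
toward large or common-variant-rich genes. VSEA removes it: for each gene,
the mean and SD of its B permutation scores estimate that gene's own null
location and scale, and observed score and permutation rows are
standardized by them (population-SD denominator, which makes the operation
exactly idempotent; zero-SD genes are flagged and set to 0). After
adjustment every gene's null has mean 0 and SD 1, so ranks compare like
with like. Because the running-sum test is evaluated against the same
permutation rows in either case, GSEA and VSEA are both *valid* tests; the
difference is power and where it concentrates. Had the score track used the
rank-based p instead, every gene would already be calibrated and VSEA would
collapse into GSEA — the standardization would have nothing to remove.

The per-gene null moments need a minimal permutation count; below B = 10
`vsea_adjust()` refuses rather than standardize on noise.

## Degenerate inputs and ties

Genes with no polymorphic variants, designs whose genetic columns are all
constant, and constant traits yield statistic 0 and p = 1 with a
`degenerate` flag rather than an error or a dropped row — gene-set
membership bookkeeping must survive them, and a p of 1 makes them inert in
the score track. Ranking ties in the enrichment walk break by gene-id
order, so reruns are bit-identical; if all member scores are zero under
exponent 1, member increments fall back to equal weights.

## The spurious-gene filter

Long-distance genotype correlation lets non-causal genes ride a causal
gene's signal replicate after replicate. The filter flags any non-risk gene
with p strictly below `alpha` in at least `min_hits` of R replicates. The
conventional cutoff of 16 hits in 200 replicates is not hard-coded:
`default_min_hits(R, alpha, tail)` returns the smallest k whose binomial
tail probability `P(Bin(R, alpha) >= k)` is at most `tail` (default 0.05),
which reproduces 16 at R = 200 (implied tail probability about 0.037) and
scales to any replicate count.

## The synthetic-data generator

`simulation_config()` describes the study the analysis assumes: unrelated
individuals; genes of heterogeneous size (uniform on a range, or an
explicit size vector); each variant's target MAF drawn from a rare range
within (0, 0.01] with probability `fraction_rare`, else from a common
range; dosages `Binomial(2, MAF)` under Hardy–Weinberg with no local LD;
an additive trait `y = X beta + eps` whose residual SD is scaled so the
realized genetic variance fraction equals the configured heritability; many
phenotype replicates over fixed genotypes (only `eps` is redrawn); and
optional confounder pairs, where a per-individual latent indicator copies
one gene's rare-variant genotypes into another with probability `rho`,
correlating the two genes' burdens without any shared effect — the
mechanism that manufactures spurious genes.

`gaw17_like_preset()` is a desk-scale echo of a published simulated
mini-exome design: 697 individuals, 300 genes (scaled down from 3,205), 13
causal genes, 25 phenotype replicates, a rare-dominated spectrum, five
confounded non-risk genes. Its effect sizes (0.25 to 2 per rare-allele
copy, heritability 0.4) are illustrative — chosen once to spread per-gene
power over roughly (0, 0.95) — not calibrated to the restricted original
data.

What the generator does *not* emulate: local LD within genes, population
structure, relatedness, genotyping error, non-normal residuals, non-additive
effects. Tests passing on these synthetics therefore certify the
statistical machinery — calibration under exchangeable nulls, the orderings
among methods — not robustness to those real-data complications.

## Evaluation harness and problem sizes

`run_experiment()` reproduces the replicated design end to end: simulate,
run step 1 per replicate with the shared plan, evaluate GSEA and VSEA on
the designed sets (the base risk set; noise-added and signal-removed
perturbations, re-randomized per replicate so results average over the
perturbation draw; an optional reference null set; random irrelevant sets
for the FPR), flag spurious genes from the replicate-by-gene p-values, and
re-run enrichment with them excluded. Rates are means over replicates of
the fraction of p below alpha, with Monte-Carlo SE
`sqrt(rate (1 - rate)/n)`. When exclusion is on, step 1 is recomputed for
the second pass — it is a deterministic function of the seeds — rather than
holding every B-by-genes permutation matrix of every replicate in memory.

The shipped checks run at deliberately modest sizes chosen to estimate each
quantity adequately: the global-null calibration at 500 genes x 697
individuals, B = 199, 10 replicates (5,000 null gene tests); the two-trait
reference-null and the power orderings at 60–80 genes, 300–400 individuals,
B = 199–500, 100 replicates. Power-ordering assertions allow a
pre-specified Monte-Carlo slack of 0.05 (about two binomial SEs at
mid-range power on 100 replicates).

## Open choices made here

- The joint F-test for the CMC regression (testing collapsed and common
  terms together) rather than the collapsed term conditional on common
  variants; `cmc_test()`'s design drops constant columns first.
- WeightSum1 centers both vectors before the cross product (location
  invariance).
- The weighted-sum frequency `q_j` uses the whole-sample pseudo-count form;
  with a quantitative trait there is no case/control split to define it on.
- Enrichment exponent defaults to 1 (the weighted statistic), 0 gives the
  classical Kolmogorov–Smirnov form.
- The primary enrichment null is phenotype permutation (shared plan);
  resampling random gene sets of equal size is available
  (`null = "geneset"`) as the alternative reading of "sets drawn at
  random".
- Moment (mean/SD) standardization for VSEA; an empirical-quantile variant
  would be a drop-in alternative behind the same interface but is not
  implemented.
- Missing dosages are mean-imputed per variant before regression (keeps
  design matrices full rank without dropping individuals); MAFs are
  computed over observed calls.

## Known limitations

No covariates, no binary traits (hence no Hotelling or rank-sum variants),
no FDR across sets, no leading-edge reporting, no population-structure
adjustment. The spurious filter is purely replicate-frequency based and
needs many replicates to be meaningful — with few replicates
`default_min_hits()` becomes permissive. Analytic F p-values for genes with
a handful of rare-allele carriers are approximate by nature; that is a
feature for the score track (VSEA absorbs it) but a reason to report
`p_permutation`, not `p_analytic`, per gene.
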