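---
title: "Methods: pan-tissue specificity screening and ligandome triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-tissue specificity screening and ligandome triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taascreen)
```

# The problem

Adoptive T-cell therapy against a tumor-associated antigen is only safe
if the antigen is essentially absent from healthy tissues at risk. The
computational question is therefore not "is this gene differentially
expressed on average" but "is this gene at least *k*-fold higher in the
tumor than in **every** healthy tissue" — a worst-case statistic. This
package implements that screen for pooled multi-source RNA-seq count
atlases, together with the downstream triage of eluted HLA class I
peptides and the qPCR confirmation arithmetic.

# The count model and the specificity screen

## Atlas assembly

Raw integer counts from several sources are merged on the intersection
of their gene universes (the minimum-over-tissues statistic is undefined
for a gene missing in one source). Within each (source, tissue) group,
samples beyond the source cap are dropped by seeded uniform sampling
without replacement: tumor cohorts keep at most 30 samples, bulk-healthy
(GTEx-like) tissues at most 20, protein-atlas (HPA-like) cohorts are
kept whole (typically 3–5 samples). The subsampling seed is part of the
run configuration so that an assembly is exactly reproducible; the caps
keep the tumor group from dominating the dispersion fit and bound the
compute per contrast.

## Normalization

Size factors are relative log expression (median-of-ratios): the
per-gene reference is the geometric mean of its counts across samples,
computed over the genes with nonzero counts in every sample (elsewhere
the geometric mean is zero or undefined), and a sample's factor is the
median over those genes of count/reference. Factors are deliberately
left unrescaled — counts-per-million divide by the *effective library
size* (column sum × factor), which is invariant to any global rescale
of the factors. Reported expression is `log2((y + c) / eff_lib * 1e6)`
with prior count `c = 0.5` by default, which keeps zeros finite while
perturbing counts near the expression floor by less than one part in
two hundred.

## Expression filter

Genes enter the screen only with a mean of at least 100 raw counts over
the tumor samples (boundary inclusive). The filter uses raw read counts
by default because that is what "evidence of expression" refers to in
count data; a switch (`use_normalized`) applies it to
size-factor-normalized counts instead for atlases with strong depth
imbalance.

## Testing

Counts are modelled negative-binomially with variance
$\mu + \phi\mu^2$; $\phi = 0$ is the Poisson limit. Dispersion is
estimated per gene by the method of moments on the normalized scale —
for each tissue group with $n_g \ge 2$ samples the residual sum of
squares has expectation
$(1 - 1/n_g)\,\lambda \sum_j 1/s_j + (n_g - 1)\,\phi\,\lambda^2$, and
solving across groups for $\phi$ (floored at 0) gives the per-gene
estimate. The tagwise value shrinks this toward a 25%-trimmed common
mean with weight 0.3: enough pooling to stabilise small groups without
letting a handful of genuinely noisy genes inflate everything. Both the
trim and the weight are exposed.

Each gene is then tested tumor-versus-one-tissue with a likelihood-ratio
test at the tagwise dispersion: mean parameters are fitted by Newton
iteration on the score equation
$\sum_j (y_j - s_j\lambda) / (1 + \phi s_j \lambda) = 0$ (exact at
$\phi = 0$), and twice the log-likelihood difference between free and
shared means is referred to $\chi^2_1$. A likelihood-ratio statistic at
fixed dispersion was chosen over a quasi-likelihood F-test because it is
fully specified by the model above and can be verified against an
independent brute-force likelihood maximization — which the test suite
does to $10^{-4}$ on seeded instances. The cost is that uncertainty in
$\phi$ is ignored; with 20–30 samples per group and tagwise shrinkage
this is a second-order effect, and the screen's decisions are dominated
by the fold-change threshold rather than the p-values.

## Aggregation and the pass rule

P-values are Benjamini–Hochberg adjusted within each tissue contrast
(across genes). A gene's record then takes the **minimum** fold change
and the **worst** (maximum) adjusted p over the included tissues — both
choices encode "significant and large against *every* tissue", keeping
the two halves of the rule logically parallel. Pooling all contrasts
into a single adjustment is available by applying `adjust_fdr()` to the
pooled vector, but the per-contrast default matches the worst-case
reading of the screen. Fold changes for aggregation are ratios of
normalized group means with the prior count, not GLM coefficients: the
screen statement is about mean expression, and the prior keeps the
minimum well-defined for tissues with all-zero counts. The screen is
one-sided (tumor over healthy): a healthy tissue expressing at or above
the tumor drives min FC to 1 or below and the gene simply fails; we do
not fold under-expression into an absolute value, since an
under-expressed gene is not a target.

A gene passes at `min FC >= 20` and `worst adjusted p <= 0.05`, both
boundaries inclusive, and (by default) only if protein-coding —
pseudogenes, miRNAs, antisense and lncRNA transcripts cannot be
presented as peptides and are excluded at the end rather than the start
so the report still shows them.

Reproductive tissues (and any other tumor cohorts in the atlas) are
excluded from the aggregation, not from the atlas: they still inform
normalization and dispersion, but a gynaecological tumor target may be
expressed in testis, ovary, endometrium or placenta without creating an
unacceptable risk.

# The synthetic generator

`simulate_counts()` draws what the screen assumes: NB counts with a
single dispersion, gene means constant across healthy tissues (nulls),
planted genes with an exact expected tumor/healthy ratio in every
healthy tissue, and log-normal per-sample depth factors with configured
CV (default 0.3, the multiplicative variation RLE removes; mean fixed
at 1). Group sizes follow the source caps. Defaults — 2000 background
genes with log-means uniform on [log 5, log 500], dispersion 0.1,
a panel of one tumor cohort plus 24 bulk and 6 protein-atlas tissues —
are in the range typical of bulk tissue panels.

What it deliberately does **not** emulate: batch effects between
sources (the pooled-atlas design this package serves does not correct
them either), gene–gene correlation, per-gene dispersion trends,
gene-length effects, or tissue-specific background expression. Passing
tests on this generator therefore demonstrate correctness of the
machinery and calibration under the stated model, not robustness to
confounding in real consortium data.

The proteome generator builds target isoforms as a shared core (verbatim
in every isoform) plus per-isoform unique tails, and family off-targets
by substituting a `1 - identity` fraction of the canonical target's
aligned positions — the simplest construction with a known, controllable
Hamming distance for the uniqueness filter. PSM and Ct generators invert
the downstream definitions exactly (configured strata counts are hit
exactly, zero-noise Ct tables round-trip through `relative_expression()`
to machine precision).

# Ligandome triage choices

* **Mass accuracy** |ppm| ≤ 10, boundary inclusive.
* **Score** threshold 20, *soft* by default: sub-threshold PSMs are
  retained but flagged, because a peptide's best ion score understates
  repeated low-level observations and published panels contain
  sub-threshold peptides that validated. Strict mode drops them.
* **Uniqueness**: minimum Hamming distance over all equal-length windows
  of every family off-target; default margin 2, so both exact substrings
  and single-substitution near-matches count as overlap. This
  operationalizes "no major sequence overlap" conservatively — a single
  residue difference to a ubiquitously expressed homolog has caused
  clinical cross-reactivity, so distance 1 is not unique.
* **HLA assignment** requires three gates simultaneously: predicted rank
  ≤ 2% (the conventional weak-binder cutoff; the predictor is a
  pluggable function, with a deterministic hash stub bundled for
  testing), allele present in the typing of at least one observing
  sample, and population frequency ≥ 1% (common alleles only). The
  shipped frequency table is synthetic/illustrative and labelled as
  such.
* Peptides are validated at parse to standard residues and class I
  lengths 8–15.
* Wet-lab evidence (synthetic-spectrum validation, monomer refolding)
  appears only as boolean annotation columns, defaulting to `FALSE`.

When a peptide was observed in samples with disjoint typings, the union
of the typings is used: presentation in any observing sample is
evidence the restriction is real, and the typing gate exists to exclude
alleles no observed sample could have presented.

# Numerical notes

* Newton iteration for the NB mean is damped (a negative proposal steps
  to a tenth of the current value) and starts at the exposure-weighted
  mean, the exact Poisson solution; likelihood-ratio statistics are
  floored at 0 to absorb rounding.
* Quartiles are type-7 (the R default, linear interpolation of sorted
  values); box summaries report min/Q1/median/Q3/max.
* The minimum-fold-change aggregation uses the signed minimum, ties
  broken by the first tissue attaining it.
* With an even number of all-nonzero genes the arithmetic median of
  ratios differs in the fourth decimal or beyond from the geometric
  (log-scale) median used by some implementations; this package uses
  the arithmetic median of count/reference as defined.

# Problem sizes in the test suite

The suite verifies calibration at sizes chosen to keep the full run
around half a minute: dispersion recovery on 2000 genes × 6 tissues;
LRT-versus-oracle agreement on 200 genes at 5 vs 5 samples; planted-gene
recovery on a 2010-gene atlas with one tumor cohort (30 samples) and 30
bulk-healthy tissues (20 samples each) at dispersion 0.1, with ten genes
planted at true fold change 25 and tumor mean 2000. That panel is
GTEx-like on purpose: the sampling noise of a per-tissue mean scales
like $\sqrt{\phi/n}$, so 3–5-sample protein-atlas cohorts each carry
roughly an 8% chance of dragging a true-FC-25 gene's *estimated*
minimum below 20, and a panel containing several of them cannot support
high-sensitivity recovery at that effect size — with 20 samples per
tissue the screen recovers ≥ 90% of such genes while no null gene
passes. For screens whose panels must include very small cohorts, the
practical remedies are a larger fold-change margin or treating the
small-cohort tissues as a separate, descriptive column rather than part
of the minimum.

# Known limitations

* The screen inherits the pooled-atlas design's blindness to batch:
  a source-correlated shift in one tissue moves that tissue's fold
  change directly.
* Dispersion is treated as known in the LRT; p-values are mildly
  anti-conservative for very small groups. The fold-change gate, not
  the p-value, is the binding constraint in realistic settings.
* The uniqueness scan is exact-window Hamming: it does not model
  proteasomal splicing, post-translational modification, or similarity
  under biochemical (rather than identity) distance.
* The bundled binding predictor stub carries no biology; conclusions
  about real peptides require plugging in a real predictor.
* qPCR arithmetic assumes a common amplification efficiency across
  genes (default 2.0); per-gene efficiencies, if calibrated, can be
  passed per call but not mixed within one call.
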