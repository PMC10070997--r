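# taascreen

Discovery of strictly tumor-specific target antigens for T-cell therapy,
as a reusable R pipeline. Given raw RNA-seq count tables pooled from
tumor and healthy tissue cohorts (TCGA-like, GTEx-like and HPA-like
sources), `taascreen` finds genes that are highly expressed in the tumor
and at least 20-fold lower in *every* healthy tissue of risk, then
triages HLA class I immunopeptidome identifications of those targets
into a vetted candidate peptide–HLA table, and computes the qPCR
relative expression used to confirm target expression in patient
material.

The intended users are computational immunologists and tumor-immunology
groups screening for tumor-associated antigens (TAAs) such as the
cancer-testis antigens PRAME and CTCFL, where off-tumor expression of a
candidate decides whether a TCR can be developed safely.

## The statistics at the core

**Tumor specificity by minimum fold change.** After merging sources
(tumor cohorts subsampled to 30, bulk-healthy tissues to 20, protein
atlas cohorts taken in full) the atlas is normalized with
relative-log-expression (median-of-ratios) size factors
*s<sub>j</sub>* = median<sub>i</sub> ( y<sub>ij</sub> / (∏<sub>k</sub>
y<sub>ik</sub>)<sup>1/n</sup> ), genes without evidence of tumor
expression (mean raw count < 100 in the tumor cohort) are dropped, and
each remaining gene is tested tumor-vs-tissue for every healthy tissue
with a negative-binomial likelihood-ratio test (variance μ + φμ²,
per-gene moment-based dispersion shrunk toward a trimmed common value,
statistic referred to χ²₁). P-values are Benjamini–Hochberg adjusted
within each tissue contrast. The per-gene specificity statistic is

> min FC = min over included healthy tissues of
> (normalized tumor mean + c) / (normalized tissue mean + c)

and a gene is a candidate when min FC ≥ 20 **and** the worst adjusted p
≤ 0.05 (both inclusive) **and** it is protein-coding. Reproductive
tissues are excluded from the minimum, since expression in the
reproductive compartment is tolerable for gynaecological tumor targets.

**Immunopeptidome triage.** Peptide-spectrum matches are filtered on
mass accuracy (|ppm| ≤ 10) and identification score (≥ 20, soft by
default: flagged rather than dropped), checked for uniqueness against
homologous family members by a minimum-Hamming-distance scan over every
equal-length window (default margin 2, so exact substrings and
single-substitution near-matches both fail), annotated with isoform
coverage, and assigned HLA alleles only when a binding predictor ranks
the pair ≤ 2%, the allele occurs in the typing of a sample where the
peptide was observed, and its population frequency is ≥ 1%.

**qPCR relative expression.** With reference Ct the mean of three
housekeeping genes (GUSB, VPS29, PSMB4 by convention), relative
expression = 100 × E^(Ct<sub>ref</sub> − Ct<sub>target</sub>), E = 2 for
perfect doubling; the housekeeping reference is 100% by definition.

A seeded synthetic-data generator (`sim_config()`, `simulate_counts()`,
`simulate_proteome()`, `simulate_psms()`, `simulate_qpcr()`) produces
every input with the statistical structure the analysis assumes, so the
whole pipeline is testable offline.

## Worked example

```r
library(taascreen)

cfg <- sim_config(
  seed = 1,
  panel = default_tissue_panel(n_bulk = 5, n_protein_atlas = 2),
  n_genes = 150, library_size_cv = 0.2,
  planted = planted_genes("PRAME_like", fold_change = 200, tumor_mean = 2000)
)
atlas <- simulate_counts(cfg)
atlas
#> <count_atlas> 151 genes x 137 samples across 8 tissues (30 tumor samples)

screen <- screen_specificity(atlas)
screen
#> <taa_screen> 55 genes x 5 healthy tissues; 1 candidate gene(s) at
#>   min FC >= 20, FDR <= 0.05
dplyr::filter(tidy(screen), passes)
#> # A tibble: 1 x 9
#>   gene_id    min_fold_change min_log2_fold_change limiting_tissue ...
#> 1 PRAME_like            173.                 7.44 bulk_tissue_03
```

55 of the 151 genes show tumor expression (mean count ≥ 100 over the 30
tumor samples); only the planted gene clears a 20-fold margin over all
five included healthy tissues (the two reproductive tissues of the
default panel are excluded), with min FC ≈ 173 against its most
expressed healthy tissue. `autoplot(screen)` draws the min-FC volcano;
`summarize_expression()` + `plot_expression_summary()` reproduce the
per-tissue boxes with the tumor median and 20×-lower reference lines.

The packaged panel of 17 published ovarian-cancer peptides replays
through the candidate builder:

```r
rebuilt <- replay_peptide_panel()
dplyr::count(rebuilt, gene)
#> 1 CLDN6     3
#> 2 CTCFL     5
#> 3 PRAME     9
```

and qPCR relative expression comes straight from the Ct definition:

```r
ct <- tibble::tibble(
  sample_id = "OVCA1",
  gene = c("GUSB", "VPS29", "PSMB4", "PRAME"),
  ct = c(20, 21, 22, 26.5)
)
relative_expression(ct)
#> 1 OVCA1  PRAME  2.21   # 100 * 2^(21 - 26.5) %
```

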