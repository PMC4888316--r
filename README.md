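# cnvgwas

Copy-number variation (CNV) analysis for SNP-array cohorts: from
multi-sample Log R Ratio (LRR) matrices to segmented, genotyped, filtered
common CNVs; then principal-component-corrected, permutation-based
association of those CNVs with estimated-breeding-value (EBV) traits;
then rule-based annotation against gene and QTL tracks and 2^-ΔΔCT
qPCR validation arithmetic.

The package is aimed at quantitative/livestock geneticists who want a
transparent, fully tested re-implementation of the common
"detect common CNVs → CNV GWAS → annotate → validate" chain that is
usually run through proprietary array software, plus a synthetic-data
module that generates every input with complete truth sets (marker maps,
LRR matrices with planted events and GC waviness, correlated EBV traits
with additive CNV effects and stratification, gene/QTL tracks, CT
tables) — so the whole workflow can be benchmarked end to end.

## The method

**Preprocessing.** LRR is imported per sample × marker, restricted to
autosomes, and de-waved by per-sample OLS of LRR on marker GC fraction
(mean-preserving, idempotent).

**Joint segmentation.** Greedy recursive binary splitting of each
chromosome on the pooled within-segment sum of squares around per-sample
segment means, under three constraints: ≥ 3 markers per segment, ≤ 20
segments per 10k-marker block, and a pairwise flanking-segment test at
p ≤ 0.005. The test pools the per-sample contrast — ΔSSE/σ² ~ χ²(n) under
the null for a fixed breakpoint — Bonferroni-corrected for breakpoint
selection, with σ² estimated robustly from first differences.

**Calling and events.** Per sample and segment, mean LRR ≤ −0.4 is a
loss, ≥ +0.4 a gain (inclusive), else neutral. Variant segments merge
into non-redundant events; events carried by < 10 samples (0.45% of a
2,230-animal cohort) or longer than 5 Mb are filtered; survivors are
named CNV1..CNVn by descending loss frequency and coded additively
(loss 0, neutral 1, gain 2).

**Association.** For each CNV j and trait (animals with EBV accuracy
> 0.5 only):

    y_i = α + Σ_k γ_k PC_ik + x_ij β_j + e_i

with genotype-matrix PCs as stratification covariates, Freedman–Lane
permutation p-values (p ≥ 1/(B+1), two-sided, B = 10,000 by default) and
per-trait Benjamini–Hochberg FDR at α = 0.05.

**Annotation.** ≥ 1 bp gene overlap with geometry classes
(gene-within-cnv / exon-overlap / intron-contained / partial), 2-kb
strand-aware promoter windows, and QTL confidence intervals (spans
> 30 Mb discarded; a single QTL must cover ≥ 50% of the CNV).

**Validation.** Livak 2^-ΔΔCT relative quantification from triplicate
CTs, half-up integer copy calls, concordance of qPCR calls with array
states, and one-way ANOVA of expression between copy-number groups.

## Worked example

The `analysis/` directory is a numbered, self-contained study over
simulated data (300 animals × 1,200 markers, twelve planted CNVs with
carrier fractions from 2% to 90%, nine correlated growth traits with
planted effects). Run the stages in order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_segment_call.R
Rscript analysis/04_associate.R
Rscript analysis/05_annotate.R
Rscript analysis/06_qpcr.R
```

Output of a complete run (tables land under `results/`):

```
simulated 300 samples x 1200 markers, 12 planted CNVs (carrier counts 90/30/270/15/75/150/6/120/60/45/210/36)
mean per-sample LRR~GC correlation: 0.222 before, 6.6e-18 after correction
35 segments -> 11 retained CNV events (named CNV1..CNV11)
planted events recovered with >= 80% span overlap: 11 of 12
(unrecovered events had carrier counts: 6 — below or near the 10-carrier floor)
pairwise trait correlations (selected):
  WG~CW 0.72   WG~CY 0.63   MW~MY 0.81   BW~PWG 0.15
6 significant associations (FDR < 0.05) over 2 distinct CNVs and 5 traits
  CNV9: WG (beta 0.54, q 0.011), MY (beta 0.49, q 0.0357)
  CNV3: MW (beta 0.46, q 0.011), PW (beta 0.50, q 0.0055), MY (beta 0.37, q 0.0357), PY (beta 0.47, q 0.0055)
annotated 2 significant CNVs against 60 genes and 30 QTLs (19 QTLs pass the 30 Mb CI filter)
45 qPCR reactions (5 CNVs x 9 animals): concordance with array calls 87%
expression ANOVA, 12 two-copy vs 2 three-copy animals: F = 26.57, p = 0.000239
```

Reading this: the only planted event lost to the filter chain had 6
carriers, below the 10-carrier floor — the filter working as designed.
The two CNVs flagged by the GWAS carry the planted weaning-gain and
muscling/precocity effects, and each is also flagged for correlated
traits of the same cluster, the expected behaviour when traits share
genetic structure. The qPCR stage re-derives copy numbers from simulated
triplicate CTs (noise 0.2 cycles) and agrees with the array genotypes in
87% of the 45 reactions; the 12-vs-2 expression ANOVA detects the 1.5×
dosage effect.

The same chain is available as a single call,
`run_pipeline(pipeline_config(...))`, which writes every intermediate
artifact plus a JSON manifest (input checksums, thresholds, seed, stage
counts) into a run directory and is byte-reproducible for a fixed config
and seed.

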