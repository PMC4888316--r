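---
title: "CNV calling from SNP-array intensities and CNV-trait association: methods"
author: "cnvgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV calling from SNP-array intensities and CNV-trait association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`cnvgwas` implements a complete copy-number-variation (CNV) association
workflow for SNP-array cohorts, of the kind used in livestock genomics to
relate common structural variants to estimated breeding values (EBVs) for
growth and carcass traits. The chain is:

1. **Intensity preprocessing** — import a samples × markers Log R Ratio
   (LRR) matrix, restrict to autosomes, impute missing entries, and remove
   GC-content waviness.
2. **Joint segmentation** — partition each chromosome's marker list into
   segments shared by the whole cohort, under three published constraints
   (segment budget, marker floor, pairwise significance).
3. **Three-state calling and event construction** — call loss / neutral /
   gain per sample and segment at |segment mean| ≥ 0.4, merge variant
   segments into non-redundant CNV events, filter by carrier count (≥ 10)
   and length (≤ 5 Mb), and name events CNV1..CNVn by descending loss
   frequency.
4. **Association** — per CNV and trait, additive linear regression of the
   EBV on the 0/1/2 genotype dose with genotype principal components as
   covariates; permutation p-values (Freedman–Lane) and per-trait
   Benjamini–Hochberg FDR.
5. **Annotation** — interval overlap of significant CNVs with gene,
   promoter, and QTL tracks under explicit geometric rules.
6. **qPCR validation arithmetic** — 2^-ΔΔCT relative quantification,
   integer copy calls, concordance with array states, and copy-group
   expression ANOVA.

A first-class synthetic-data module (`generate_marker_map`, `generate_lrr`,
`generate_traits`, `generate_annotations`, `generate_qpcr_fixture`)
produces all of these inputs with complete truth sets, because the
real genotype cohorts this workflow targets are typically not publicly
deposited. Every generator is a pure function of its arguments including
the seed.

# The intensity model and GC correction

The LRR at a marker is the log2 ratio of observed to expected total probe
intensity; hemizygous deletions displace it downward (≈ −0.55 at one copy,
stronger on some assays) and single-copy duplications upward (≈ +0.4).
The synthetic generator draws marker noise i.i.d. Normal(0, `noise_sd`)
(an optional AR(1) knob exists for robustness experiments), adds the
planted shift over each event's markers for its carriers, and adds a
*shared* GC wave proportional to the centred marker GC fraction —
matching the observation that GC-driven waviness is a cohort-wide artifact
correctable by a single GC covariate.

`gc_correct()` fits, per sample, an ordinary least-squares regression of
LRR on the marker GC fraction and subtracts the centred fitted component,
so each sample's mean LRR is preserved exactly and the operation is
idempotent. The vendor algorithms that inspired this step use unpublished
"GC correlation files"; a single global regression per sample is the
transparent approximation, and a rolling-window variant is deliberately
out of scope.

One desk-scale caveat is worth stating plainly: when a chromosome has only
a few hundred markers and a planted event covers several percent of them,
the per-sample GC slope is itself biased by the event, which leaks a
smooth GC-shaped residual into carriers; a pooled cross-sample test can
then detect that residual as genuine shared structure. At the realistic
scale this workflow mimics (~750k markers, events covering a vanishing
fraction) the leakage is negligible. The package's segmentation benchmarks
therefore generate GC-flat data and mark it corrected rather than passing
a tiny matrix through an in-situ correction whose bias is an artifact of
the miniature scale.

# Joint segmentation

Chromosomes are partitioned by greedy recursive binary splitting on the
pooled within-segment sum of squares (SSE) around per-sample segment
means: at each step the candidate breakpoint with the largest pooled SSE
reduction across all open segments is examined (ties broken leftmost).
A split is accepted only if

- both children hold at least `min_markers` markers (default 3),
- the pairwise comparison of the two flanking children is significant at
  `max_pairwise_p` (default 0.005), and
- the chromosome's segment count stays within
  `max_segments_per_10k_markers` (default 20) per started 10k-marker
  block.

**The pairwise test.** For a *fixed* breakpoint, the SSE reduction is a
sum over samples of independent scaled χ²(1) contrasts between the two
flanking means, so ΔSSE/σ² ~ χ²(n) under the no-change null. The
marker-level noise variance σ² is estimated robustly as the median across
samples of MAD²/2 of first differences along markers, which is immune to
the carriers' breakpoint jumps. Because the tested breakpoint is the best
of all candidate positions in its segment, the p-value is
Bonferroni-corrected by the candidate count before the 0.005 gate.

This design was chosen over the more obvious Welch t-test on the flanking
per-sample means after measuring both on the package's reference
benchmark (50 samples × 200 markers, one 10-marker loss of shift −1.0 in
30% of samples, noise sd 0.15): the uncorrected mean-based gate
over-splits badly (breakpoint precision ≈ 0.63, because max-SSE selection
over ~190 candidates inflates a nominal 0.005 test by two orders of
magnitude), while Bonferroni-correcting the mean-based test collapses
recall (≈ 0.28, because the mean contrast of a 10-marker event is diluted
across a 150-marker flank at the first split). The pooled χ² contrast has
neither defect — it accumulates carrier consistency regardless of
dilution — and measures recall 1.00 / precision 0.99 on the benchmark,
with pure-noise chromosomes left as exactly one segment. The 0.005
constraint is honoured as the (selection-corrected) significance level of
the between-segment comparison.

Two further interpretation choices: the segment budget is read as *20 per
started 10k-marker block* (a 200-marker chromosome may hold up to 20
segments), since a strictly proportional ceiling would forbid any split
below 500 markers and make small-chromosome analysis degenerate while
being materially identical at full scale (1,520 vs 1,507 segments at
753k markers); and constant (zero-noise) data yields no splits, because
σ̂² = 0 leaves the gate undefined.

**Calling.** `call_states()` thresholds each sample's mean corrected LRR
per segment at ±0.4, *inclusive* (a mean of exactly −0.4 is a loss); the
threshold is deliberately strict so that single-copy changes (≈ −0.55 /
+0.4) are called while wave residuals are not. The per-sample rule is
needed downstream: association requires a genotype per animal, not per
cohort.

# Events, filters, naming, genotypes

Segments variant in ≥ 1 sample are merged per chromosome when they
overlap or are bookended (adjacent in the marker partition); the event
spans the union. A sample carrying both loss and gain across an event's
constituent segments takes the state covering the longer basepair span,
ties resolved to loss — an explicit, logged convention for a situation
the upstream method leaves undefined. The two-step filter first removes
events with fewer than 10 carrier samples (loss and gain pooled — the
carrier floor corresponds to a 0.45% frequency in a 2,230-animal cohort),
then events longer than 5 Mb (the upper bound of the accepted CNV size
range). Events are named CNV1..CNVn by descending loss frequency, ties
broken by chromosome then start position. Genotypes are coded additively:
loss 0, neutral 1, gain 2.

# Association

For each CNV *j* and trait separately, animals pass an EBV-accuracy gate
(accuracy strictly > 0.5; accuracy is the square root of reliability and
only gates inclusion — it is simulated independently of the trait
values). The model is

$$y_i = \alpha + \sum_k \gamma_k \mathrm{PC}_{ik} + x_{ij}\,\beta_j + e_i$$

fitted per event — the standard single-marker GWAS reading of the
additive model; a joint regression on all events simultaneously is
unidentifiable when the event count approaches the sample count. The PCs
are computed from the CNV genotype matrix itself (centred, unit-scaled,
top-k left singular vectors scaled by singular values, k = 10 by
default), which keeps the workflow self-contained; with only a handful of
events the PCs become collinear with the tested genotypes, so desk-scale
analyses should use k ≪ n_events (the bundled analysis scripts use
k = 3 over 11 events).

**Permutation p-values** use the Freedman–Lane scheme: the trait is
regressed on the covariates alone, the residuals are permuted (one seeded
permutation stream shared across events, so the genome-wide null
preserves between-event correlation), re-projected, and the full model's
t-statistic recomputed; `p = (1 + #{|t*| ≥ |t|}) / (1 + B)`, two-sided,
so p can never be 0 and never undercuts 1/(B+1). Benjamini–Hochberg FDR
is applied across events within each trait (results are reported per
trait), and `significant` means q < 0.05. The asymptotic p-value is
emitted alongside as a diagnostic column.

The p-floor has a practical consequence worth knowing: with B
permutations, a *lone* true positive among m events cannot achieve
q < α unless 1/(B+1) < α/m. At B = 2,000 and m = 200 the smallest
possible q is ≈ 0.1, so effect-recovery checks run at B = 10,000 — the
workflow's standard permutation count — while null-calibration
simulations, which look at raw p, use B = 2,000.

# Annotation rules

All interval arithmetic is on 1-based inclusive coordinates
(`overlap = min(ends) − max(starts) + 1`); BED export converts to 0-based
half-open and back losslessly. Gene overlap requires ≥ 1 bp and is
classified by precedence: *gene-within-cnv* (transcript ⊆ event), else
*exon-overlap* (any exon intersects), else *intron-contained* (event
inside the gene body touching no exon), else *partial*. The precedence
matters: a gene contained in a CNV always has intersecting exons, so
testing exon overlap first would make containment unreportable.
Promoter scanning uses the 2,000 bp immediately upstream of the TSS,
strand-aware and clipped at the chromosome start; gene-body overlap alone
never yields a promoter record. QTL overlap first discards records whose
confidence-interval span exceeds 30 Mb (they carry no localisation), then
requires a *single* QTL to cover ≥ 50% of the CNV's length — coverage is
per QTL, never unioned, so each reported pair is individually defensible.
The overlap engine is IRanges/GenomicRanges; the test suite checks it
against a brute-force per-basepair membership oracle.

# qPCR arithmetic

Relative quantification follows the Livak 2^-ΔΔCT method at fixed
efficiency 2: replicate CTs are averaged first, ΔCT is target minus
control within a sample (BTF3-style DNA control or GAPDH-style RNA
control), ΔΔCT subtracts the calibrator sample's ΔCT, and RQ = 2^-ΔΔCT.
Per-sample CT offsets cancel in ΔCT by construction. Integer copy calls
are `round(RQ × 2)` with ties rounding half up — a documented convention,
since half-integer RQs sit exactly between copy classes. Concordance
between array states and qPCR calls compares loss/neutral/gain against
< 2 / = 2 / > 2 copies over identical (sample, event) keys, after
triplicate averaging. The synthetic CT generator writes
`CT = base − log2(copies/2) + sample offset + noise`, so a noiseless
3-copy sample quantifies to RQ 1.5 exactly; at a realistic well noise of
0.2 cycles, concordance of a 5-assay × 9-animal design averages ≈ 0.9.
The copy-group expression comparison is a fixed-effects one-way ANOVA; in
the archetypal 12 diploid vs 2 triploid design with a 2-sd expression
shift its exact noncentral-t power is 0.672, which the Monte-Carlo suite
reproduces.

# What the simulations do and do not show

The generators emulate: marker maps with exponential spacing and smooth
sinusoidal GC structure; planted loss/gain events from rare to nearly
fixed; shared GC waviness; correlated multi-trait EBVs (multivariate
normal with a target correlation matrix, optionally from a factor model)
with additive CNV effects and subpopulation offsets; stratified genotype
cohorts with allele-frequency drift; and triplicate CT tables under the
amplification model. They do *not* emulate B-allele frequencies, raw
probe intensities, autocorrelated wave noise beyond AR(1), genotyping
batch structure, pedigree/BLUP machinery behind the EBVs, or
linkage disequilibrium between events. Passing tests therefore show the
*method* behaves as specified under its own model assumptions at desk
scale — not that a particular biological cohort would yield any
particular discovery count.

Problem sizes were chosen so the whole suite runs comfortably on a
laptop: the segmentation benchmark is 50 × 200 × 20 seeds; oracle
equivalence uses ≤ 60-marker chromosomes where exhaustive two-breakpoint
search is feasible; association calibration uses 200 events × 500 animals
× 2,000 permutations; the end-to-end analysis in `analysis/` runs 300
animals × 1,200 markers with twelve planted events.

# Numerical and degenerate-input choices

- Marker positions are strictly increasing per chromosome; generators
  enforce a ≥ 1 bp gap.
- Missing LRR entries are masked on read and mean-imputed per marker
  (logged count) before segmentation; GC correction fits on observed
  entries only.
- Zero-variance genotype columns are dropped from PCA (warned) and
  flagged — not tested — in association; a constant GC track downgrades
  correction to a warned no-op; constant LRR yields one segment per
  chromosome.
- All tie-breaks are deterministic: leftmost breakpoint, loss over gain,
  lower start position first, largest-|loading|-positive PC signs.
- Every stochastic routine takes an explicit seed and restores the
  caller's RNG state, so library calls never perturb a user's stream.

# Known limitations

- The segmentation optimiser is greedy; it attains the exhaustive optimum
  within 1% on the benchmark scales checked, but no global-optimality
  guarantee exists.
- The pairwise-test calibration assumes approximately Gaussian marker
  noise; heavy-tailed noise would make the χ² reference anticonservative
  (the robust σ̂ mitigates but does not remove this).
- Association treats events independently; no conditional or joint
  modelling, no mixed-model relatedness correction beyond genotype PCs.
- GC correction is a single global regression per sample; local waviness
  with non-linear GC dependence is not captured.
- The qPCR model fixes amplification efficiency at 2.0; efficiency
  calibration from standard curves is out of scope.
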