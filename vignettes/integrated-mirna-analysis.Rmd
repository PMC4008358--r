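---
title: "Integrated miRNA–mRNA–copy-number analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated miRNA-mRNA-copy-number analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mirnapt` implements an integrative analysis of matched tumour profiles —
miRNA expression, gene expression and miRNA-locus DNA copy number, together
with clinical follow-up — of the kind used to characterise triple-negative
and ER-negative breast cancer cohorts. The pipeline identifies five things:

1. **Copy-number-driven miRNAs** — miRNAs whose expression tracks the DNA
   copy number of their locus.
2. **Prognostic miRNAs** — miRNAs whose expression is associated with
   distant-metastasis-free survival (DMFS) or breast-cancer-specific
   survival (BCSS) in Cox proportional-hazards screens.
3. **Subtype-specific miRNAs** — miRNAs differentially expressed across
   the five intrinsic molecular subtypes (basal-like, luminal A/B,
   HER2-enriched, normal-like) assigned by nearest-centroid
   classification.
4. **miRNAapt** ("miRNA anti-correlated to predicted targets") — miRNAs
   whose predicted-target lists are significantly enriched for genes
   negatively correlated with the miRNA, i.e. miRNAs with a detectable
   transcriptional footprint.
5. **Pathways and gene sets** correlated with, or inferred to be
   transcriptionally influenced by, those miRNAs.

The package consumes summarised matrices (log-scale expression, absolute
copy numbers); array-level preprocessing (RMA, quantile normalisation,
segmentation) is out of scope. A synthetic-cohort generator with plantable
ground truth replaces patient data for development and validation.

# Statistical model, stage by stage

## Preprocessing

Replicate samples of the same patient are averaged (arithmetic mean per
feature) before any analysis, so all statistics see one column per
patient. miRNAs flagged not-detected or saturated in **more than 10
samples** are removed — the rule is strict (`> 10`), so a feature bad in
exactly 10 samples is retained. Detection flags travel as a parallel
integer matrix (0 detected / 1 not detected / 2 saturated); how "not
detected" is defined on a given platform is left to the upstream flag
caller. When a patient's replicates disagree, the patient-level flag is
the maximum code, i.e. a feature is bad for the patient if any replicate
was bad. miRNAs co-located with transposable elements have unreliable
genomic positions and are excluded from every locus-based copy-number
analysis (they remain eligible for survival and subtype screens).

## Copy-number association

For each miRNA, samples are stratified by absolute copies: **gain**
above 2.3 copies, **loss** below 1.7, **neutral** otherwise (both
cut-offs strict). Two Wilcoxon rank-sum tests compare expression in gain
vs neutral and loss vs neutral samples; a side where either group has
fewer than 3 samples is skipped and reports q = 1 (the minimum group size
is a package choice; the stratification cut-offs are the standard ones).
Benjamini–Hochberg correction runs across miRNAs **separately within the
gain family and within the loss family** — the two tests ask different
questions and their result tables carry separate q columns; a pooled
alternative is available via `bh_family = "pooled"`. A miRNA is called
copy-number driven when the **signed** Spearman correlation between
copies and expression exceeds 0.25 (expression must track dosage — an
anti-correlated locus is not "driven" in this sense) and the smaller of
the two q-values is below 0.05.

Called miRNAs are annotated with recurrent-aberration regions overlapping
their locus by at least one base, and with oncogenes/tumour-suppressor
genes inside a **closed ±10 kb window** around the locus: a gene starting
exactly 10 000 bases past the locus end is included, one base further is
not. Coordinates are 1-based inclusive throughout (the GFF3 convention;
BED input is converted on read).

## Survival screening

Each miRNA is scaled to unit variance and fitted in a Cox
proportional-hazards model (Efron tie handling), so the hazard ratio is
**per standard deviation of expression**. The reported p-value is the
Wald test; a score-test (log-rank) switch exists because the two agree
asymptotically for a single covariate and conventions differ between
groups. BH correction runs across the testable miRNAs within one
endpoint × cohort × model combination, and a miRNA is called prognostic
at **p < 0.002 and q < 0.2** jointly. Patients who received neo-adjuvant
treatment are excluded before any fit; cohorts are `all`, `ER_neg` and
`TNBC` (ER−/PR−/HER2−). Constant miRNAs and non-converged fits are
flagged and excluded from the FDR family rather than silently dropped.

Multivariate models add histopathological covariates additively, with
fixed codings: grade low (1–2) vs high (3); nodal status as given;
lymphocytic infiltration low (< 15%) vs high (≥ 15%); tumour size in
centimetres, unscaled. The supported ladder is (i) miRNA alone, (ii)
+node +size, (iii) +node +size +lymphocytic infiltration. With an empty
covariate list the multivariate screen reproduces the univariate one
exactly (this identity is tested to 1e-10).

Kaplan–Meier curves stratify patients at the empirical 1/3 and 2/3
expression quantiles; ties are broken by stable rank order so the three
groups stay as balanced as the sample size allows, and the difference is
assessed with a three-group log-rank test. Screen-level p-value
distributions can be compared against U(0,1) by Kolmogorov–Smirnov and
against an empirical reference built by Monte-Carlo permutation of the
survival (time, event) pairs (default 10 000 permutations; tests scale
this down and check the reference against the
Dvoretzky–Kiefer–Wolfowitz envelope).

## Subtype assignment and subtype-specific miRNAs

Samples are assigned to the intrinsic subtype whose centroid profile they
correlate with best over the shared gene panel. Correlation is
**Spearman** by default (common practice for intrinsic-subtype
classifiers, and invariant to monotone per-sample transforms); Pearson is
a switch. Centroids are an input file — the synthetic generator emits
matched centroids so no proprietary centroid data are needed. The
iterative random-sampling refinement some groups apply to
basal-enriched cohorts is replaced by plain nearest-centroid plus an
optional balanced-subsample majority vote (`votes_rounds`): the exact
iterative procedure is specified elsewhere and is not reproduced here.

Subtype-specific miRNAs come from a per-miRNA one-way ANOVA across
subtype groups, BH across miRNAs, flagged at **q < 0.001**, with the peak
subtype the group with maximal mean. Pairwise histopathological
contrasts (ER− vs ER+, TNBC vs rest, grade) use pooled-variance t-tests
at **q < 0.01**.

## miRNAapt discovery

For every miRNA, Spearman correlations with **every** measured gene are
computed (chunked over genes; results are chunk-invariant because rows
are rank-transformed once). A gene is anti-correlated with a miRNA when
rho < −0.3, strictly — a pair exactly at −0.3 does not qualify. For each
prediction algorithm separately, a 2×2 table over the gene universe
(all genes in the expression matrix after filtering) crosses "predicted
target of this miRNA" with "anti-correlated with this miRNA", and the
one-sided Fisher exact test measures enrichment. The test is one-sided
because only over-representation of anti-correlated genes among targets
is evidence of repression. Computing the anti-correlation flag for
non-target genes is what completes the table margins; the margins summing
to the universe size is asserted as a conservation check.

BH correction runs across miRNAs **within each algorithm** (the
per-algorithm analyses are independent), the minimum q over algorithms is
taken **after** correction, and a miRNA is called miRNAapt at
min(q) < 0.05. miRNAs with fewer than 10 measured predicted targets in an
algorithm are excluded from that algorithm's family. A map may include a
`validated` pseudo-algorithm (e.g. curated interactions) to run the
confirmatory analysis through the same code path.

## Pathway analysis

A gene set's **signature score** in a sample is the mean expression of
its measured member genes — deliberately simple, linear (the score of a
set equals the mean of its single-gene scores) and invariant to gene
order. miRNA–pathway relationships are Spearman correlations between
miRNA expression and signature scores; a (miRNA, set) pair is selected
when |rho| > 0.5, the correlation p < 1e-6 and a one-way ANOVA of the
set's correlation values across miRNA groups (prognostic direction, or
peak subtype) has p < 1e-4. **No multiple-testing correction is applied
at this stage**: gene sets overlap heavily and are strongly dependent,
so the stage uses deliberately conservative fixed thresholds instead.

Correlation matrices are clustered two-ways (Euclidean distance; average
linkage by default — the linkage was an open choice and is configurable).
Cluster stability is the plain bootstrap proportion: features are
resampled with replacement, the tree is recomputed, and a cluster's
stability p is one minus the fraction of resamples in which exactly its
member set reappears. This is a simplification of the multiscale
(AU/pvclust-style) bootstrap — adequate for flagging well-separated
blocks, slightly conservative for small clusters.

Finally, for each called miRNAapt, gene sets smaller than 500 genes are
tested (one-sided Fisher over the same universe) for enrichment in the
miRNA's anti-correlated predicted targets; a set is assigned at
p < 0.001 with an overlap **strictly greater than 3** genes. The
`TRUE_TARGETS_<mirna>` sets that the generator injects turn this stage
into a self-validation: for a recovered miRNAapt, its exact true-target
set should be the top-ranked enrichment.

# The synthetic cohort

`simulation_config()` defaults define the reference cohort used by the
whole validation suite: 200 patients (4% profiled twice), 300 miRNAs,
5 000 genes, subtype mix basal 0.45 / lumA 0.20 / lumB 0.15 / her2 0.10 /
normal 0.10 (a basal-enriched composition, as in triple-negative-rich
series), unit residual SD on the log scale, exponential survival with
baseline hazard 0.08 and ~30% independent exponential censoring, 10% of
miRNAs TE-flagged, and 3 patients marked neo-adjuvant treated.

Planted effects:

* **10 copy-number-driven miRNAs** — one-copy gains or losses in 30% of
  samples, expression shifted by 1 noise-SD per copy; copy numbers carry
  small measurement noise so strata are realistic but unambiguous.
* **3 prognostic miRNAs** — log hazard ratio ±0.7 per SD on DMFS (two)
  and BCSS (one), entering an exponential proportional-hazards model on
  the standardized planted expression.
* **10 miRNAapt** — 30% of each miRNA's 100 predicted targets are true
  targets whose gene expression receives `repression_slope ×
  standardized miRNA expression` (slope −1); each prediction algorithm
  (6 by default) lists a true target with probability 0.8 and fills the
  rest with decoys.
* **10 subtype-specific miRNAs** — 1.5-SD mean shift in their peak
  subtype. Five of them are **also** copy-number driven; for those, the
  aberration frequency is concentrated in the peak subtype with the
  marginal frequency preserved, so the subtype shift arrives partly
  through copy number — the realistic coupling (basal-like
  copy-gain-driven miRNA clusters) and the only design under which both
  the dosage correlation and the subtype ANOVA remain detectable at the
  standard thresholds.

Two generator choices deserve explanation. First, subtype centroids are
full-panel patterns: each subtype's centroid deviates from a shared
baseline by an independent N(0, separation·SD) draw **per panel gene**
(50 genes by default), the way real intrinsic-subtype centroids differ
across their whole panel. A design where each subtype only shifts a
dedicated block of 10 genes in one direction carries too little
information for reliable nearest-centroid assignment at 1-SD separation.
Second, survival uses exponential event and censoring times — the
simplest model exactly satisfying proportional hazards, so Cox parameter
recovery is well defined; the censoring rate is matched at the baseline
hazard and is therefore approximate under planted effects.

What the generator does **not** emulate: array noise structure, batch
effects, segmentation artefacts, correlated gene–gene backbone beyond
subtype structure and planted repression, informative censoring,
competing risks, and the correlation between DMFS and BCSS within a
patient (the two endpoints are drawn independently). Passing tests
therefore demonstrate that the statistical machinery recovers planted
effects under its own model assumptions at realistic sizes — not that
the thresholds have any particular operating characteristics on real
arrays.

# Numerical conventions

* Fisher exact enrichment is the hypergeometric upper tail
  `phyper(a-1, a+b, c+d, a+c, lower.tail = FALSE)`; it is checked against
  full enumeration for every 2×2 table with total ≤ 12.
* Spearman p-values: exact permutation distribution for n ≤ 9 on
  tie-free data, the t-approximation otherwise; mid-ranks everywhere.
* Wilcoxon: exact enumeration for pooled n ≤ 12 without ties, the tie-
  and continuity-corrected normal approximation otherwise — the
  corrected form keeps the two paths within 0.02 of each other at the
  cross-over size.
* BH is `p.adjust(method = "BH")`; applying it twice is **not** the
  identity in general, so q-values are computed exactly once per family.
* Degenerate inputs (constant vectors, zero within-group variance,
  empty strata, collapsed tertiles) are flagged or raised as errors,
  never silently imputed; flagged features are excluded from their FDR
  family so they cannot dilute the correction.
* The pipeline derives per-stage child seeds from the global seed, and
  all result files are written with full numeric precision (`%.17g`), so
  re-running with the same inputs and seed is byte-identical.

# Validation problem sizes

The test suite validates kernels against brute-force oracles
(enumeration, hand step-up formula, rank formula), then checks recovery
on simulated cohorts: the reference 200 × 300 × 5 000 cohort over 10
seeds for miRNAapt, copy-number and subtype recovery and the
top-enrichment check; 50 cohorts of 300 patients for Cox log-HR
recovery; screens of 500 miRNAs on permuted outcomes for null
calibration; and two full pipeline runs for byte-level determinism.
Unit tests use smaller cohorts (40–200 miRNAs, 100–200 patients) chosen
so each property is measured where its effect size makes the check
informative.

# Known limitations

* The miRNAapt universe is "all measured genes"; with a target universe
  defined differently (e.g. union of predicted targets only), q-values
  would shift — the choice is recorded in the result object.
* Signature scores weight all member genes equally; directional
  signatures (up/down components) are not modelled.
* Bootstrap stability is a resampling proportion, not an AU p-value.
* The balanced-subsample vote for subtype assignment is a heuristic
  stand-in for iterative reclassification procedures, off by default.
* Exponential censoring is tuned to the baseline hazard, so the realised
  censoring fraction drifts slightly when planted hazards are large.
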