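---
title: "Identifying copy-number-driven genes in paired tumor/normal cohorts"
author: "scnadriver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying copy-number-driven genes in paired tumor/normal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnadriver)
```

## The analysis problem

Recurrent somatic copy number alterations (SCNAs) are a primary mechanism by
which tumors deregulate gene expression: a gene sitting inside a recurrently
deleted or amplified region tends to be expressed in proportion to its DNA
dosage. `scnadriver` implements the full integration workflow that turns a
paired tumor/normal cohort — segmented DNA copy number (DCN), FPKM-like
expression, a gene annotation and a clinical table — into a ranked list of
copy-number-driven genes, gain/loss frequency landscapes along the genome,
molecular subclass predictions, and survival stratifications. The motivating
use case is hepatocellular carcinoma, where the 13q14 region (harboring
*MRPS31* and *RB1*) is recurrently deleted and the mitoribosomal protein
(MRP) genes — the bundled 82-gene focal set, `mrp_genes()` — are screened
for dosage dependence.

## The model, stage by stage

### Gene-level copy number

Segmented DCN (linear copy ratios) is mapped onto genes with
`map_segments_to_genes()`. A gene fully inside one segment inherits its
value. For the case the segmentation leaves ambiguous — a gene spanning a
breakpoint — we take the overlap-length-weighted mean of the overlapping
segment values, which equals the per-base average over the gene body (the
test suite checks this equivalence against a literal per-base oracle at
1e-12). A gene with no overlapping segment is missing in that sample. Genes
with DCN in less than half of the tumor samples are excluded
(`filter_low_coverage_genes()`, strict `<`, so a gene covered in exactly
50% of samples survives).

### DE and SCNA matrices

Both derived matrices are log2 ratios against the mean of the non-tumor
(NT) samples:

* deregulated expression, `DE[g, s] = log2((x[g, s] + c) / (mean_NT(x[g, ]) + c))`
* copy number alteration, `SCNA[g, s] = log2(dcn[g, s] / mean_NT(dcn[g, ]))`

The pseudocount `c` (default 1, in FPKM units) keeps DE finite at zero
FPKM; how zeros are handled is otherwise unspecified in standard FPKM
pipelines, so `c` is exposed as a parameter. The SCNA denominator uses all
NT samples, not only the paired ones; tumor/normal pairing is used for
cohort validation only.

### The three-gate selection rule

`select_scna_dependent_genes()` calls a gene copy-number-driven when all of
the following hold:

1. **Differential expression**: |mean log2 DE| > 0.3 with a permutation
   t-test p < 0.005 between NT and PT. The test statistic is Welch's t —
   the unequal-variance form is the right default when the two groups are
   as unbalanced as a typical cohort (tens of NT vs hundreds of PT). The
   permutation p uses the add-one estimator `(1 + #{|t*| >= |t|}) / (B + 1)`
   so it is never zero, and switches to exhaustive enumeration when all
   label arrangements fit in `B`. Screens share one permutation plan across
   genes: the same label shuffles are applied to every gene, which makes a
   genome-wide screen reproducible from one seed and reduces it to a
   handful of matrix products. `B` defaults to 1999 in the NT-vs-PT screen
   so the 0.005 threshold is attainable with headroom.
2. **Concordance**: the mean SCNA has the same sign as the mean DE
   (copy loss with down-expression, gain with over-expression).
3. **Dosage correlation**: Pearson r > 0.5 with p < 0.005 across the tumor
   samples carrying both assays. The gate is one-sided on signed r, not
   |r|: dosage dependence is positive by construction, and a strong
   negative correlation is evidence against it.

Thresholds are applied raw — the rule is a screen, not an inference — but
BH-adjusted q-values are reported alongside for the reader.

### Frequency landscapes

Cohorts are stratified on a gene's DCN into upper/lower quartile groups of
size `k = round(N/4)` with round-half-to-even: this is the unique rounding
rule consistent with group sizes 94, 93 and 52 at cohort sizes 376, 371
and 210. Ties break by ascending sample id. The median split
(`stratify_median()`) sends exact-median samples to the low group for
determinism; an odd-sized stratum therefore splits 46/47 rather than
dropping the middle sample, and both sizes are reported.

Per gene and group, gains are calls with log2 SCNA > 0.2 and losses < −0.2
(strict inequalities; 0.2 itself is neutral), frequencies use the
informative (non-missing) denominator, and loss frequencies carry a
negative sign so they plot below zero. `differential_frequency()` flags
genes whose gain or signed-loss frequency differs by more than 0.2 between
the low and high groups.

### Nearest Template Prediction

`ntp_predict()` assigns each sample to the subclass template (a ±1
direction vector over signature genes) with minimal cosine distance on the
gene-wise z-scored matrix. Expression is log2-transformed (pseudocount 1)
before z-scoring when given on the linear scale, and z-scoring is joint
over all samples supplied. Significance is by resampling: `R` (default
1000) random gene sets of the signature's size, drawn uniformly without
replacement from all measured genes independently per sample, give a null
distance distribution and an add-one p-value. BH FDR is computed across
samples on the winning-class p-values, and a sample is `"unclassified"`
unless its FDR is below 0.05. Because the nearest of several templates is
selected before the p-value is computed, the per-sample p is mildly
anti-conservative under the null; the FDR gate absorbs this in practice
(the null call rate is checked by simulation in the test suite).

### Survival

`km_estimate()`, `logrank_test()` and `cox_univariate()` wrap the standard
product-limit estimator, the two-group Mantel–Haenszel test and the Cox
proportional-hazards model (Breslow tie handling; adequate for the
simulator's continuous times, and the convention to keep in mind on
heavily tied real data). Confidence intervals and p-values are Wald-based,
matching the forest-plot convention. Expression covariates are
standardized before fitting, so hazard ratios are per standard deviation —
the covariate scale is otherwise arbitrary for FPKM-derived values.
Monotone partial likelihood (perfect separation) is flagged and the CI
reported as unbounded. `stratified_survival()` supports conditioning on a
second gene's DCN status (e.g. restricting to copy-number wild-type
samples at log2 DCN ≥ −0.2) before stratifying.

## The synthetic cohort generator

Every stage must be testable without controlled patient data, so
`sim_config()`/`simulate_cohort()` generate cohorts with exactly the
statistical structure the analysis assumes:

* **Design**: 376 PT DCN samples with paired NT profiles, 371 PT
  expression samples of which 369 carry both assays, 50 NT expression
  samples — the assay overlap structure of a large paired liver cohort.
* **Genome**: 4 chromosomes × 500 genes (10 kb genes, 10 kb spacing).
  Chromosome labels follow the human 1–22, X, Y convention.
* **Copy number**: per sample and chromosome, the profile is cut into 5
  random segments; each segment's log2 value is Normal(0, σ_c = 0.1).
  Noise lives at *segment* level, so the segment-to-gene mapping is
  genuinely exercised rather than bypassed. Two recurrent arm events are
  planted: a "13q-like" deletion (carrier fraction π = 0.4, shift
  μ = −0.7) and a gain arm (π = 0.3, μ = +0.6).
* **Expression**: per-gene baselines are Uniform(4, 8) on the log2 FPKM
  scale — moderately expressed genes, where a pseudocount of 1 distorts
  log ratios only mildly. For the 100 dosage genes inside the deletion
  arm, log2 expression = baseline + β·c + Normal(0, σ_e) with β = 1.5 and
  σ_e = 0.55; all other genes have β = 0. These defaults put the
  theoretical dosage correlation ρ = β·sd(c) / sqrt(β²·var(c) + σ_e²)
  at 0.70 (with var(c) = μ²π(1−π) + σ_c²) and the mean DE of a dosage
  gene at β·π·μ ≈ −0.42, comfortably but not trivially beyond the 0.3
  fold-change gate — the selection rule has to work, not merely fire.
* **Survival**: event times are exponential with rate h0·exp(γ·z), z the
  driver gene's standardized log2 expression, h0 = 0.015 per month,
  γ = −0.5 (low driver expression shortens survival, the
  tumor-suppressor-like direction), uniform censoring over 120 months.
* **Subclasses**: two planted 30-gene signatures (random ±1 directions,
  shift Δ = 1.0) assigned to 25% of tumors each, on chromosomes without
  copy-number events so the two signals do not confound.

One master seed feeds four named substreams (copy number, expression,
survival, templates), so changing one component's parameters does not
perturb the draws of the others, and the whole bundle is byte-identical
under a repeated seed.

What the generator deliberately does **not** emulate: tumor purity and
subclonality, batch effects, GC/wave artifacts in DCN, allele-specific
copy number, heavy-tailed FPKM distributions, tied survival times, and
correlation between neighboring genes' expression beyond shared segments.
Passing tests therefore demonstrate that the pipeline's logic and
statistics behave as specified under clean dosage structure — not that any
particular biological conclusion transfers to real data.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at I/O boundaries (SEG input is 1-based inclusive by
  default, with a dialect flag since segment exports vary; BED annotation
  is already half-open). A 1 bp segment in 1-based inclusive input has
  internal length 1.
* Strand is ignored throughout: copy number and expression are
  strand-agnostic in this analysis.
* SEG validation is strict (overlapping segments within a sample are an
  error naming the sample); a permissive mode downgrades this to a
  warning for real-world exports. Malformed rows are rejected with line
  numbers.
* Zero-variance cases degrade explicitly: a Welch t with no variance in
  either group is 0 with p = 1; zero-variance genes are dropped before
  z-scoring with a warning; constant Cox covariates are errors.
* Permutation p-values are never 0 (add-one, or exhaustive fractions that
  include the observed arrangement); comparisons against the observed
  statistic use a 1e-12 relative tolerance so exact ties count.
* Fisher's exact test reports the sample odds ratio with Haldane's +0.5
  correction applied only when a cell is zero.

## Problem sizes used in the checks

The packaged test suite and `scripts/acceptance.R` run the full pipeline
on the default 2,000-gene, 376-sample synthetic cohort (selection-rule
recovery and landscape), a 2,000-gene 30-vs-30 global-null screen with
B = 999 (type-I calibration), an 80-sample two-class NTP cohort with
50-gene signatures at R = 1000 plus five 60-sample null cohorts, 200 Cox
replicates at n = 300 and 500 log-rank replicates at n = 200 per arm, and
exhaustive Fisher enumeration for all 2×2 tables with total at most 40.
These sizes keep every property estimate stable across seeds while the
whole suite completes in a few minutes on one core.

## Known limitations

* The permutation screen holds the permutation plan fixed across genes;
  per-gene p-values are therefore correlated across genes (exactly as
  when reusing one shuffle set genome-wide), which matters only if one
  treats the p-values as independent draws.
* NTP's per-sample p-value inherits the min-over-templates selection
  effect described above.
* No multivariate Cox, time-dependent covariates or competing risks; no
  GISTIC-style recurrence significance; no purity/ploidy correction of
  DCN. These are out of scope by design.
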