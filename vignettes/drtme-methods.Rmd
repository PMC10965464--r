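---
title: "Scoring dietary-restriction activity in tumour expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dietary-restriction activity in tumour expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drtme)
```

## The DR score

Dietary restriction (DR) — reduced nutrient intake without malnutrition —
leaves a transcriptional footprint: a set of genes whose activity rises
under DR and a set whose activity falls. `drtme` quantifies that footprint
in a single sample as the difference between two single-sample enrichment
scores:

$$\mathrm{DR} = \mathrm{NES}_{\mathrm{pos}} - \mathrm{NES}_{\mathrm{neg}},$$

where $\mathrm{NES}_{\mathrm{pos}}$ and $\mathrm{NES}_{\mathrm{neg}}$ are
the normalised ssGSEA enrichment scores of the positively and negatively
DR-related gene sets in that sample. A strongly DR-active sample enriches
the positive set and depletes the negative set, so its score is large; the
two-sided construction means shared technical effects (library size,
global shifts) cancel.

The packaged signature pairs 220 positive with 56 negative genes (276 in
total, disjoint). **The shipped gene list is a synthetic stand-in**: it
preserves the sizes, disjointness and symbol conventions of the curated
signature but not its exact membership, which is not redistributed here.
`load_dr_signature()` validates the structural invariants on every call;
any GMT with one positive and one negative set can be substituted via
`read_gmt()` + `signature_pair()`.

## The ssGSEA statistic

For one sample, genes are ranked by expression within the sample
(1 = lowest; ties get the average of the ranks they span) and walked in
decreasing rank order, ties in the ordering broken by ascending gene
identifier so results are bit-reproducible across platforms. With in-set
weights $w(g) = \mathrm{rank}(g)^\tau$, the enrichment score of a set $S$
in a sample with $N$ genes is

$$\mathrm{ES}(S) = \sum_{i=1}^{N}\left[P^{\mathrm{in}}(i) - P^{\mathrm{out}}(i)\right],$$

where $P^{\mathrm{in}}(i)$ is the cumulative in-set weight among the first
$i$ ordered genes divided by the total in-set weight and
$P^{\mathrm{out}}(i)$ is the count of out-of-set genes among the first $i$
divided by $N - |S|$. Raw scores for all sets and samples are then divided
by the global range $\max \mathrm{ES} - \min \mathrm{ES}$, so the reported
matrix has range exactly 1 whenever the raw range is nonzero (per-set
normalisation is available behind `per_set = TRUE`, off by default). A
degenerate all-equal matrix has zero raw range; raw scores are then
returned unscaled with a warning rather than dividing by zero.

Parameters, with defaults:

* `tau = 0.25` — the customary ssGSEA weighting exponent; 0 weights all
  in-set genes equally, larger values emphasise highly expressed genes.
* `min_size = 10` — sets with fewer matched genes are dropped with a
  warning; an analysis in which every set fails the filter is an error.
* `normalize = TRUE` — global range normalisation as above.
* `kcdf` — recorded for provenance only. Kernel CDFs apply to
  kernel-density enrichment variants, not to the rank-based ssGSEA
  statistic, so the setting is deliberately inert; it is kept so that
  configuration records match common usage of enrichment toolkits.

Because only within-sample ranks enter the statistic, any strictly
monotone transform of a sample — log, TPM rescaling, quantile shifts —
leaves its raw scores unchanged. Whether input expression was
log-transformed is therefore immaterial, and the engine never asks.
Single-cell and spot-level matrices go through the identical code path;
dropout zeros simply tie at the bottom ranks and no imputation is done.

## Permutation significance

The null question for one sample is: *does the curated signature separate
more than a random signature of the same size would?* For each sample,
`permutation_test()` draws `n_reps` (default 1000) random **disjoint**
pairs of gene sets, sized to the matched positive/negative sets, uniformly
without replacement from the matrix's genes, and recomputes the score
difference. Disjoint draws mirror the observed statistic's structure (the
real positive and negative sets share no genes). The p-value uses the
add-one estimator

$$p = \frac{1 + \#\{\mathrm{null} \ge \mathrm{observed}\}}{B + 1},$$

which is a valid p-value at finite $B$ and never returns 0; its smallest
attainable value is $1/(B+1)$. Sidedness defaults to `"greater"` (the
score's use is directional — DR activity present); `"two-sided"` compares
absolute values. Null statistics are computed on raw enrichment scores:
global normalisation is one shared positive rescaling, so it cancels from
the comparison and per-sample p-values stay independent of cohort
composition. One RNG stream, seeded from `permutation_config()`, is
consumed in sample order, so results are reproducible and independent of
any parallelism.

A statistical caveat that shaped the validation design: per-sample
p-values are marginally uniform under gene-label exchangeability, but
across samples of one cohort they are *correlated* whenever genes carry
shared baseline effects — the one realised assignment of baselines to
signature genes shifts every sample's observed score the same way.
Uniformity checks (Kolmogorov–Smirnov, binomial envelopes) therefore use
an iid null matrix (`baseline_sd = 0` in the generator), under which the
per-sample p-values are independent and the tests' assumptions hold.

## Stratification

* `stratify_median()`: strictly above the cohort median is `"high"`,
  everything else `"low"`. Ties at the median must break
  deterministically; they go to `"low"`, and the direction is documented
  rather than configurable.
* `stratify_quartiles()`: above Q3 is `"high"`, below Q1 `"low"`, the rest
  `"medium"` (the single-cell stratification). Quartiles use the default
  linear-interpolation sample-quantile convention (`stats::quantile`
  type 7); for scores 1..8 this puts {1, 2} low and {7, 8} high. Both
  stratifications are invariant to adding a constant or positive scaling,
  and both refuse degenerate inputs (all scores equal, or Q1 = Q3).

## Copy-number burden scores

Arm-level log2 copy-number ratios (GISTIC-style input) are binned:

| log2 ratio | score |
|---|---|
| $\ge 1$ | 2 |
| $[0.25, 1)$ | 1 |
| $[-0.25, 0.25)$ | 0 |
| $[-1, -0.25)$ | -1 |
| $< -1$ | -2 |

The **arm score** sums binned arm values; the **focal score** applies the
identical binning to focal regions ("similar procedure" resolved as
identical binning and summation); the **chromosome score** counts
whole-chromosome events — chromosomes whose two arms carry the *same*
log2 ratio — adding the shared bin once when it is non-neutral (a neutral
agreement is a non-event, not an event of size 0). The **overall score**
is the sum of the three. Two numerical choices deserve note:

* Real segmentation output never gives bit-identical arm values, so
  chromosome agreement takes a tolerance `tol` (default 0 for the literal
  same-value rule; `1e-6` recommended for real data) and a `binned = TRUE`
  variant compares binned scores instead — the looser reading, off by
  default because intent should not be guessed.
* The gain/loss **calls** (`call_arm_events()`) use strict thresholds
  (gain iff $> 0.25$, loss iff $< -0.25$), so 0.25 exactly is *neutral* as
  a call yet scores 1 in the bin table. This boundary asymmetry between
  the two definitions is preserved deliberately rather than harmonised;
  the two rules serve different outputs.

Acrocentric chromosomes may carry a single arm; they contribute to the arm
score and are skipped by chromosome-level scoring.

## Immune panel, CYT, and the LIHC-DR predictor

`immune_panel_scores()` scores 16 immune cell-type sets and 13
immunological-pathway sets per sample through the same ssGSEA engine;
rows come back cell sets first, then pathways. As with the DR signature,
the packaged panel GMT is a synthetic, marker-seeded stand-in carrying the
canonical set names — it exercises every code path and is editable, but a
curated panel should be substituted for real analyses.

The cytolytic activity score is the average of GZMA and PRF1 transcript
levels. "Average of transcripts" admits two readings, and both are
exposed: the default `"log-arithmetic"` mode averages $\log_2(TPM+1)$ of
the two genes; `"geometric"` is the classical geometric mean of
$TPM + 0.01$. The default follows the plain reading of an average of the
two transcript measurements on the log scale; the geometric variant is the
original cytolytic-activity construction.

The LIHC-DR predictor is the fixed two-gene linear risk score for
hepatocellular carcinoma:

$$\mathrm{score} = 0.001906 \times \mathrm{FZD1} + 0.000974 \times \mathrm{G6PD}.$$

The coefficients are taken as given; gene selection and refitting are out
of scope. The expression scale on which the coefficients were fitted is
not recorded with them, so the predictor evaluates the printed form on the
input matrix's values *as given* and tags the output with the matrix's
unit: raw scores are unit-dependent, while the median-split risk grouping
is scale-invariant and therefore transferable across units.

## Association and survival models

Associations of DR scores with genomic burdens adjust for age, sex and
race: ordinary least squares for continuous burdens, maximum-likelihood
logistic regression (tolerance 1e-8, at most 100 iterations, perfect
separation raised as an error) for binary gain/loss outcomes. Categorical
covariates use the alphabetically first level as reference, for
determinism. The reported p for the DR term is the single-df partial test
(t, identical to the partial F). Benjamini–Hochberg correction is applied
across strata *within one analysis family* (e.g. across cancer types for
one burden type), never across families.

Survival contrasts delegate to the survival package: Kaplan–Meier
product-limit curves, the two-group log-rank test, and Cox
proportional-hazards models with Efron tie handling and Wald 95% CIs;
non-convergence and aliased covariates are errors, not warnings.
`landmark_auc()` quantifies discrimination of a risk score for
event-by-horizon status: subjects with an event at or before the horizon
are cases, subjects followed beyond it are controls, and subjects censored
before the horizon are **excluded** — the simple landmark definition,
chosen over inverse-probability-of-censoring weighting because the
analysis it supports names no estimator; the time-dependent ROC
alternative is noted here and not implemented. The CI is a percentile
bootstrap over included subjects (default 10,000 replicates, seeded).

## What the synthetic generators emulate — and what they do not

`simulate_expression()` plants the exact structure the score is built to
detect: a random half of samples is "active", with positive-set genes
shifted up and negative-set genes down by `effect_size` log2 units
(default 1) over lognormal baselines (per-gene means N(3, `baseline_sd`),
unit noise), with an optional negative-binomial count mode (size 5) and
single-cell dropout by random zeroing. `simulate_cnv()` draws arm and
focal values strictly inside their bins (neutral |x| ≤ 0.2; events within
±[0.3, 0.95] and ±[1.05, 1.6]) and plants whole-chromosome events at rate
`0.3 × event_rate`, so its truth table is exact by construction and the
scorer must reproduce it identically. `simulate_survival()` draws
exponential event times with hazard $h_0 e^{\beta z}$ ($h_0 = 0.1$, $z$
the standardised score) and exponential censoring with rate
$h_0 c/(1-c)$ — exactly the target censoring fraction $c$ at $\beta = 0$,
approximate otherwise. All generators are pure functions of
(configuration, seed): they restore the caller's RNG state.

These generators exercise correctness, calibration and recovery; they are
*not* realistic tumour transcriptomes. They have no cell-type mixtures, no
batch effects, no gene–gene correlation beyond the planted sets, no
spatial structure, and mixture-free noise. Passing tests therefore
demonstrate that the statistics do what they claim on data satisfying
their assumptions — not that the DR score has any particular effect size
in real cohorts, which requires the original large-scale datasets.

## Validation problem sizes

The shipped checks use sizes chosen to make their statistical assertions
sharp while staying quick on a laptop: oracle agreement on 100 random
30-gene instances (tolerance 1e-10 against a brute-force double-loop CDF
evaluation); permutation calibration with 200 draws across 50 samples of
an iid null; Cox recovery of log-HR −0.69 at n = 1000 over 100 replicates
(≥ 90% within 2 SE); logistic slope recovery at n = 2000 likewise;
log-rank type-I error over 1000 null replicates against the binomial 99%
envelope; and an end-to-end run at 2000 genes × 100 samples (label
ranking AUC > 0.9 at effect size 1) with the survival direction recovered
in ≥ 95% of 60 replicates.

## Known limitations

* The packaged signature and immune panel are synthetic stand-ins (sizes
  and structure, not curated membership); results on real data require
  substituting curated GMTs.
* Permutation p-values are exchangeability-based: gene-set pairs are
  compared against size-matched random sets, not against a biological
  null that preserves gene–gene correlation.
* The landmark AUC ignores censoring within the excluded set; with heavy
  early censoring an IPCW estimator would be preferable.
* `linear_association`/`logistic_association` assume the usual model
  diagnostics have been checked upstream; they refuse rank-deficient and
  separated designs but do not test distributional assumptions.
* The predictor's raw scale is meaningful only on the expression unit the
  user supplies; only the risk grouping is unit-free.
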