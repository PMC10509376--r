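---
title: "Sparse PLS-DA for methylation classifiers: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse PLS-DA for methylation classifiers: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylpls)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the assumptions behind them, the parameters
that matter and why their defaults are what they are, what the synthetic
cohorts do and do not emulate, and the numerical choices made where the
design was genuinely open.

## The problem

DNA methylation at CpG sites, measured on Illumina arrays as beta values
(methylated fraction, β ∈ [0, 1]), carries tissue- and disease-specific
signatures. A recurring task in epigenomics is to build a classifier that
assigns a new sample to one of two clinical groups — here the motivating
case is placental tissue from early-onset preeclampsia (EOPE) versus
normotensive preterm birth (nPTB) — from a sparse panel of CpGs, with a
calibrated probability rather than a bare label. Sample sizes are small
(tens per class), dimensionality is huge (hundreds of thousands of
probes), and array data carry platform artefacts (two probe chemistries,
batch effects, failed probes and samples) that must be handled before any
modelling.

## Sparse PLS discriminant analysis

The classifier core is sparse PLS-DA. The outcome is one-hot encoded into
a dummy matrix **Y** (columns in a fixed class order; the first class is
the positive class throughout). Both **X** (samples × CpGs) and **Y** are
centred and scaled to unit variance — scaling the dummy columns follows
the convention of the standard R implementation of sPLS-DA and changes
the loadings, so it is stated explicitly. For each component the NIPALS
pair is iterated on the cross-product **M** = X′Y:

1. **v** ← first right singular vector of **M** (initialisation);
2. **u** ← S<sub>λ</sub>(**M v**), soft-thresholding at λ = the
   (keepX+1)-th largest absolute entry, rescaled to unit norm;
3. **v** ← **M′u** / ‖**M′u**‖; repeat from 2 until the change in
   **u** falls below `tol` (default 1e-6, max 100 iterations).

Scores, regression coefficients and deflation follow the usual PLS
recursion, and deflating both blocks by the score regression makes
successive score vectors orthogonal (verified numerically in the tests to
|cos| < 1e-6). One component is the natural choice for a two-class
outcome (K − 1 components for K classes); the package supports more but
the reference workflow uses one.

**Tie-breaks.** Soft-thresholding alone cannot honour the keepX budget
when several weights tie exactly at λ: with weights (1, 1, 1) and
keepX = 2 every shrunk entry would be zero. The keep-set is therefore
chosen by a stable ordering (decreasing |w|, then increasing index), λ is
the largest absolute weight outside it, and in the fully degenerate
all-tied case the kept entries retain their unshrunk values before
normalisation. Ties in the max-distance class call go to the first class
label. Both rules are deterministic and documented so that refits are
bit-reproducible.

**Sign convention.** The component-1 loading sign is fixed so the
positive class has the higher mean score. This is presentation only — the
fitted subspace and all predictions are invariant to a joint sign flip of
(u, t, c, d).

**Prediction and probabilities.** New samples are scaled with the
*training* statistics, scored component-wise with the stored loadings and
deflation coefficients, and mapped back to the dummy scale, giving one
"prediction distance" per class. The max-distance rule (largest predicted
dummy value) is used during development and cross-validation; softmax
over the distances gives two probabilities summing to 1, and a
probability threshold (default 0.55) gives the deployment call. Softmax
is applied to the distances directly, with no temperature: the absolute
probabilities therefore depend on the score scale, which is one reason
ranking metrics (AUC) are the stable comparison surface across
implementations, while Brier scores should only be compared within one
implementation and convention.

## Quality control

Samples are screened first; probes are filtered on the surviving samples,
in a fixed order (quality → blocklist → platform intersection →
non-variable). The order matters for the quality filter, whose failure
fractions depend on which samples remain, so it is fixed and documented.
Checks whose optional inputs are absent are skipped with a logged
warning, never silently passed: reproducibility of the report matters
more than completeness.

- **Inter-array correlation** (< 0.95 flags a sample): clean methylomes
  share a strongly bimodal probe-mean structure, so genuine arrays
  correlate at ~0.97 while swaps and failed hybridisations fall far
  below. On full-size arrays the metric uses a deterministic subsample of
  the 50,000 most-variable probes for speed (full-probe mode available).
- **Sex concordance**: chromosomal sex is inferred by a 2-means split of
  the per-sample chrY median log2 intensity (higher cluster → XY),
  cross-checked against chrX. A single-sex cohort makes the split
  degenerate; a fixed cutpoint (10.5, a value between typical
  female-background and male chrY summaries) is then used and announced.
- **SNP-probe contamination**: the score is the mean absolute deviation
  of a sample's SNP-probe betas from the nearest of three genotype
  centres (3-means over the pooled betas; fixed centres 0.12/0.50/0.88 if
  clustering degenerates). This nearest-centre deviation is a deliberate
  simplification of likelihood-based outlier metrics: clean three-cluster
  data score below 0.05, mixtures of two individuals score near the
  uniform-deviation level, and the 0.12 threshold sits between them.
- **Probe quality**: an observation fails at detection p > 0.01 or bead
  count < 3; a probe is dropped when *more than* 5% of samples fail —
  read as a strict inequality, so 6/100 drops and 5/100 keeps, and the
  boundary is tested.
- **Blocklist and platform filters**: union of cross-hybridising,
  polymorphic and sex-chromosome probes, then restriction to the
  HM450K ∩ EPIC intersection so a fitted model transfers across
  platforms.
- **Non-variable probes** are dropped only when flat in this dataset
  (q90 − q10 < 0.05) *and* flagged non-variable in an external reference
  list — both conditions, because a probe that is quiet in one cohort may
  still vary in the population.

## Normalization

Two methods are implemented, chosen deliberately: BMIQ, the per-sample
method used for the reference workflow, and between-sample quantile
normalization, its strongest published competitor in this setting.

**BMIQ.** Type II probes show a beta distribution compressed toward 0.5
relative to type I probes. Per sample, a 3-component beta mixture
(unmethylated U, hemimethylated H, methylated M) is fitted to each probe
type by EM: responsibilities from the current parameters, shapes updated
by method-of-moments from responsibility-weighted means and variances,
convergence on relative log-likelihood change < 1e-4. Initialisation
splits values at 0.2 and 0.75 (roughly the U/H and H/M boundaries of
typical methylomes); the choice is configurable because the original
method's initialisation is not pinned down here. Values at exactly 0 or 1
are clipped by 1e-6 since the beta density is unbounded at the boundary.
The method-of-moments update is not a true EM M-step, so monotonicity of
the log-likelihood is not guaranteed in general; on well-separated
mixtures the trace climbs with at most sliver-sized dips near
convergence, which is what the tests assert. A collapsing component
(weight < 1e-3) raises an error recommending fewer states rather than
returning a silently degenerate fit.

Each type II probe is then assigned to U/H/M by maximum posterior (ties
toward the lower-mean state), U-state probes are quantile-mapped through
the U components (p = CDF<sub>U2</sub>(β), β′ = CDF<sub>U1</sub>⁻¹(p)),
M-state probes symmetrically through the 1 − β reflection, and H-state
probes are linearly dilated into the interval between the transformed U
maximum and transformed M minimum. Empty states fall back to anchoring at
the H interval's own endpoints, with a warning. The mapping is monotone
within each state and leaves type I probes untouched.

**Quantile normalization** replaces each sample's sorted values with the
across-sample mean of order statistics; ties receive the mean of the
reference values at their would-be positions. It is idempotent and makes
every column's sorted vector identical — properties the tests assert
directly, alongside agreement with the established implementation in
limma. The interface keeps the per-sample (BMIQ) versus whole-matrix
(quantile) distinction explicit, because between-sample normalization
lets information flow across samples — a feature when it absorbs
dataset-level technical shifts, a hazard when training and deployment
cohorts are normalized together. Which method predicts better on shifted
cohorts is left as a reproducible experiment on batch-shifted synthetic
data rather than adjudicated by the package.

## Cross-validation, stability and the permutation control

Model selection uses repeated (50×) stratified 3-fold cross-validation.
Three folds keep ~27 samples per fold at the reference cohort size;
stratification by class is this package's choice (plain M-fold is
available) so that small cohorts keep both classes in every training
split. One master seed drives a deterministic per-repeat substream, so
any repeat can be reproduced in isolation.

Scaling statistics, feature selection and fitting all happen strictly
inside the training folds. The no-leakage test corrupts the held-out
labels of each fold and verifies the held-out probabilities are unchanged
to 1e-12.

Per keepX, the report aggregates OER (max-distance rule), per-class OER,
AUC and Brier. AUC is computed by pooling held-out probabilities within a
repeat and averaging over repeats (per-fold averaging is available; which
of the two a published number used is often unstated, and pooling is the
default here because 3-fold AUCs on ~14 positives are noisy). Brier uses
the binary single-class convention by default — mean((p − y)²) for the
positive class; the summed-over-classes convention is exactly twice that
for two classes and is available, with reports stating the convention.
Feature stability is the fraction of the M × repeats fits selecting a
CpG; below 0.5 is flagged low-stability. The model-size decision itself
(prefer an intermediate keepX when metrics tie) is emitted as an
annotation — the smallest keepX within one OER standard deviation of the
best — not applied automatically.

The permutation control refits the whole cross-validation on labels
shuffled uniformly at random. On a balanced cohort this sits at
chance — but a *single* permutation of ~80 labels retains a random
overlap with the truth (sd ≈ 1/(2√n)), and when the planted signal is
strong that overlap is partially learnable, so single-permutation mean
OERs scatter roughly ±0.06 around 0.5. The number of permutations is
therefore configurable; averaging a handful gives a stable chance-level
estimate, and the package's own acceptance test does exactly that.

**Threshold selection.** Youden's J = sensitivity + specificity − 1 is
swept over thresholds at midpoints of adjacent sorted unique
probabilities (calls are "probability ≥ threshold"); ties go to the
lowest threshold. The returned object carries the full ROC for plotting.

## The synthetic generator

The generator exists so that every stage is testable against known truth.
Its defaults *are* the reference study conditions: 42 + 41 samples;
5,045 probes (45 signature + 5,000 background — a desk-scale stand-in for
a ~341,000-probe array; full-scale generation is supported but not the
default); signature class means 0.47 (EOPE) and 0.61 (nPTB), i.e. a
planted Δβ of 0.14 with EOPE the lower-methylation class; beta-distributed
noise with common precision φ = 60.

Choices that merit justification:

- **Beta noise with one precision knob.** Betas stay in [0, 1] by
  construction and variance is μ(1 − μ)/(1 + φ). φ = 60 puts the
  within-class sd at ~0.064 for a mid-range CpG, making the planted 0.14
  effect ≈ 2 sd per CpG — strong enough that a 45-CpG panel reaches the
  AUC ≥ 0.95 regime at n ≈ 83, which is the regime the reference workflow
  reports. Real per-CpG dispersions are not published for this signature;
  φ is a calibration, surfaced as a tunable, not an estimate of real
  data.
- **U-shaped background means.** Background per-probe means are drawn as
  a scaled Beta(0.4, 0.4) over [0.1, 0.9], emulating the bimodal
  methylome of real tissue. This matters for QC realism: bimodal means
  give clean inter-array correlations ~0.97, comfortably above the 0.95
  screen, whereas uniformly drawn means would park clean cohorts right at
  the threshold — a property real arrays do not have.
- **Probe-type structure.** 70% of background probes are labelled type II
  and compressed toward 0.5 by a factor 0.8, giving BMIQ something real
  to undo. Signature probes are assigned type I so the planted class
  means are stated on the output scale; compressing them would silently
  shrink the planted Δβ to 0.112 and decouple the generator from its own
  calibration target.
- **Batch effects** are applied on the logit scale (no boundary
  violations), allocated round-robin across conditions so condition and
  batch are not confounded unless asked for. A validation draw can apply
  a cohort-level logit shift to emulate a dataset effect; because EOPE is
  the low-methylation class, a positive shift moves EOPE samples toward
  the nPTB profile, costing sensitivity while preserving specificity —
  the qualitative misclassification pattern expected when a deployment
  cohort is globally shifted.
- **Planted QC failures**: contaminated samples get SNP betas uniform on
  (0.2, 0.8); sex-discordant samples get the opposite sex's intensity
  summaries; bad probes fail detection p in 10% of samples (safely past
  the 5% rule). The truth record lists every planted quantity, and
  recovery tests consume only that record.

What the generator does *not* emulate: co-methylation blocks and any
genome-wide correlation structure, ancestry-linked methylation, cell
composition, probe-specific dispersion differences, and intensity-level
artefacts. Passing tests therefore demonstrate the pipeline's correctness
and its behaviour under the stated statistical structure — not
performance on real cohorts, where between-dataset heterogeneity
(diagnosis criteria, processing, ancestry composition) dominates and the
same workflow validates far below its cross-validation estimates.

## Problem sizes and determinism

The test suite runs all simulations at desk scale: unit tests use
245–1,045-probe cohorts; the acceptance checks use the full reference
specification (5,045 probes, 83 samples, 50 × 3-fold CV — about 150
model fits, a few seconds each batch). All randomness flows from
explicit seeds through derived substreams kept inside 32-bit integer
range; regenerating a cohort or a single CV repeat is exact. Model
serialization is JSON with sparse (index, value) loadings and a schema
version; numeric round-trips are exact to well below 1e-12.

## Known limitations

- Two classes only; no multiclass or multi-block variants, and no
  missing-data-tolerant NIPALS (modelling requires complete matrices;
  mean imputation is available but explicit and logged).
- Softmax probabilities are uncalibrated in the statistical sense: they
  are monotone transforms of prediction distances, not posterior
  estimates, and their scale is implementation-dependent.
- The SNP-contamination score and the sex-inference cutpoints are
  simplified stand-ins for intensity-level methods and should be
  re-tuned if applied to real intensity summaries.
- ComBat-style batch correction is out of scope by design; the pipeline
  exposes where it would slot in (between QC and model training) but does
  not reimplement it.
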