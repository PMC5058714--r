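---
title: "Discovering oncomodules behind chromatin-regulator driver mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering oncomodules behind chromatin-regulator driver mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomodules)
```

## The problem

Chromatin regulatory factors (CRFs) — the writers, erasers and remodelers of
chromatin state — are recurrently mutated cancer drivers, yet a CRF mutation
by itself says little about *which* downstream transcriptional program the
tumor has broken. This package implements a discovery pipeline that connects
driver mutations of a CRF to coherent sets of dysregulated genes
("oncomodules") in a tumor cohort with paired somatic-mutation and
expression data, and then stress-tests each candidate module against several
independent lines of evidence before anyone spends bench time on it.

The pipeline operates on four inputs: a normalized, per-gene median-centered
expression matrix (genes × samples); a somatic mutation catalog reduced to
protein-affecting mutations (PAMs: missense, nonsense, frameshift, splice);
a registry flagging which genes are drivers and which of those are CRFs; and
one or more gene-set collections (transcription-factor targets, pathways,
curated signatures) in GMT format.

## Stage 1 — differential expression under a mutation contrast

For a focal driver CRF, samples are partitioned into a **mutated** group
(≥ 1 PAM in the focal CRF; focal membership dominates any other mutation)
and a **control** group (zero PAMs in *every* driver CRF). Samples mutated
in some other driver CRF but not the focal one are excluded: they are
neither clean controls nor informative cases.

Before testing, the 30% of genes with lowest variance (population variance,
computed across all samples regardless of mutation status) are discarded —
these genes cannot carry a detectable signal and only dilute the multiple-
testing correction. Ties at the variance cut are broken toward the
lexicographically larger gene identifier so the retained set is
deterministic.

Each remaining gene is compared between the two groups with a two-sided
Wilcoxon rank-sum test. Both groups of size ≤ 10 with untied data use exact
enumeration (`pwilcox`); otherwise a tie- and continuity-corrected normal
approximation is used. We verified the approximation is within 0.01 of
exact enumeration in the decision-relevant tail (p ≤ 0.1) for group sizes
of 4 and above; at smaller sizes the exact path is always taken, because
the mid-range error of the approximation grows to ≈ 0.09 at 2 vs 2.
Benjamini–Hochberg correction is applied across all tested genes.

The DE list uses an adaptive threshold: start at adjusted p < 0.05; if
*more than* 1000 genes pass, tighten to 0.01, then 0.001 (exactly 1000 does
not advance). Direction is the sign of the median group difference, falling
back to the mean difference on a zero median gap; genes constant in both
groups get p = 1 and no direction.

## Stage 2 — enrichment and oncomodule assembly

DE genes are tested against every gene set with the upper-tail
hypergeometric probability P(X ≥ overlap). The universe is the set of
genes actually tested for DE (post-variance-filter): untested genes can
never be DE, so counting them would inflate significance. This choice is
config-overridable. BH correction runs within each collection by default —
TF targets, pathways and signatures are distinct hypothesis families — with
a pooled mode available; the scope is recorded in the output.

Each significant set becomes an oncomodule. Its members are the set's
genes with a differential-expression **raw** p below 0.05 — the "add-back"
rule, which recovers genes that were individually suggestive but fell to
the multiple-testing correction. Because a BH-adjusted p is never below its
raw p, every DE member of the set is automatically retained. Members split
into up- and down-regulated subsets; direction-less members are dropped
from both and logged. A controller gene (used by the knock-down layer) is
assigned only to sets from `tf_targets` collections, where the set is
unequivocally under one gene's control.

## Sample-level enrichment (SLEA)

Per sample, a module subset is summarized as a Z-score of its mean
expression against the null of a same-size random gene set drawn from the
same sample. The original SLEA tool estimates this null by resampling; the
default here is the exact **analytic** form, since the mean of k values
drawn without replacement from the sample's N values has expectation μ
(the sample's grand mean) and standard error

σ · sqrt((N − k)/(N − 1)) / sqrt(k),

with σ the population standard deviation — the finite-population
correction. This removes Monte-Carlo noise from the downstream rank
comparisons; the resampling mode is retained for fidelity and the two are
cross-checked in the test suite (agreement within |ΔZ| ≤ 0.1 at 10⁴
resamples in ≥ 99% of trials). The mean is the default summary; a median
summary is offered in sampling mode only, because the analytic moments
above hold for the mean. A module spanning the whole universe has Z = 0 by
construction; a zero-variance sample yields a flagged degenerate value.

The SLEA matrix has one row per module direction plus two global rows for
all up- and all down-regulated DE genes — three modules therefore give
eight rows.

## Stage 3 — evidence layers and the scorecard

Seven tri-state layers (positive / negative / NA) are assembled per module:

1. **Driver correlation** (computed): for every driver mutated in ≥ 5
   samples, module Z-scores are compared between its mutated and unmutated
   samples; the p-values are ranked. Positive only when the focal CRF ranks
   first; otherwise another driver explains the module at least as well and
   the module is *disqualified* outright (Occam's razor), voiding its
   overall score. When both module rows are usable the row where the focal
   CRF is strongest is taken.
2. **Perturbation drug list** and the three **prior-literature layers**
   (external): obtained from a drug-response database query and manual
   literature review, they enter as a per-module drug-list string and three
   booleans. The drug layer is positive exactly when the list is non-empty.
3. **Cell-line miss-regulation** (computed when a panel is given): SLEA on
   tissue-matched cell lines grouped by the CRF's mutation status, BH
   across all (module, subset) tests in the run. Positive requires
   significance *and* direction concordance with the tumor cohort — a
   significant but opposite shift scores negative. NA when the CRF's
   mutation status is not assayed in the panel or a group has < 2 lines.
4. **Knock-down overlap** (computed when a catalog is given): genes in the
   2.5% tails of a knock-down experiment's z-values are "extreme"; a gene
   must be extreme in ≥ 2 experiments of a target to enter its consensus
   signature. The focal CRF's and the controller's signatures are compared
   by a one-sided Fisher test over the assayed universe, BH across
   modules. NA for controller-less modules or missing experiments.

The aggregation rule is nowhere stated in prose in the analysis this
package reimplements; it was reverse-engineered from the published score
table and
validated by exact agreement with all of its printed rows (the fixture test
in `test-acceptance.R`): one point per favorable layer, NA layers leave
the denominator, "no better-correlating driver" and "≥ 1 drug" count as
favorable, and disqualification makes the overall score NA.

## CRF-to-driver index

The per-sample CDI quantifies how skewed a sample's driver mutations are
toward CRFs: −log₁₀ of a one-sided Fisher test on [mutated driver-CRFs,
unmutated driver-CRFs; mutated non-CRF drivers, unmutated non-CRF drivers].
The contingency universe is drivers only by default — comparing against all
genes would conflate total mutational burden with CRF involvement — with an
all-genes variant available; the log base is configurable and recorded. A
sample with no mutated drivers has CDI 0.

## Mutual exclusivity

For a chosen gene set, the test statistic is the **coverage** — the number
of samples with at least one alteration. Each permutation re-places every
gene's alterations uniformly across samples, preserving its alteration
count exactly (the stricter, variance-matching reading of "respecting the
observed probability"; a Bernoulli-resampling variant would add count
noise). The empirical p uses add-one smoothing, (1 + hits)/(1 + B), so it
is never zero and is conservatively super-uniform under the null — the
calibration test checks exactly super-uniformity, because for a discrete
statistic the p-value cannot be uniform. Per-gene burden is conditioned
on; per-sample burden is not (the algorithm behind the published layout
tool is unspecified on this point, so the simpler per-gene-only null is
implemented and documented). The staircase layout sorts genes by
descending alteration count and samples lexicographically by the
gene-ordered alteration tuple, canonically.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes: i.i.d. Gaussian background expression (downstream tests are
rank-based, so the noise family is non-critical); independent
per-(sample, gene) driver mutations at configurable frequencies; a planted
module whose up-genes shift by +δ and down-genes by −δ in focal-CRF-mutated
samples **before** per-gene median-centering, so part of the offset is
absorbed by centering as in real median-centered data; optional mutually
exclusive alteration structure drawn as one multinomial per sample; and
matched cell-line and knock-down panels under the same planted-shift
contract. One master seed fans out to per-component seeds through a
documented splitting rule (`split_seed()`), so each component is
independently reproducible.

Default study conditions — 200 samples, 2000 genes, focal CRF mutated at
frequency 0.3 among 3 CRF and 8 non-CRF drivers, δ = 2σ on 30 + 30 planted
genes, 20 decoy sets of 60 genes — were chosen once as a realistic
mid-sized tumor cohort regime: group sizes (~60 mutated vs ~100 CRF-clean)
match a typical single-cohort contrast, and δ = 2σ is a strong but not
degenerate transcriptional shift. The knock-down generator gives each
target a latent signature exactly filling its 2 × 2.5% tails (balanced
signs), sharing a fraction ρ between targets; with ρ = 0 the signatures are
independent random draws, so cross-target overlaps are hypergeometric and
the overlap p-value is (discretely) super-uniform — a literal
Kolmogorov–Smirnov uniformity check is unattainable for such a discrete
conservative p and is tested as super-uniformity instead.

What the generator does **not** emulate: copy-number and methylation
layers, realistic mutational signatures, batch effects, gene–gene
expression correlation, and cohort substructure. Passing the calibration
and recovery suites therefore demonstrates correctness of the machinery
under the stated model, not performance on real tumor data, where
correlated expression inflates module-level variance and the effective
number of independent hypotheses is smaller.

## Numerical choices and degenerate inputs

* Wilcoxon: exact path for both groups ≤ 10 without ties; tie-corrected
  normal approximation with continuity correction otherwise.
* Variance filter: population variance (divisor n); the choice only
  matters for pathological ties, and the tie rule makes those
  deterministic.
* Degenerate cases are flagged, never silently dropped: constant genes
  (p = 1, no direction), zero-variance samples (degenerate SLEA rows),
  modules with only direction-less members (empty subsets plus a warning),
  all-zero alteration matrices (coverage 0, p = 1).
* Empty mutated or control groups abort with a named error rather than
  degrade.

## Problem sizes used by the shipped studies

The calibration suite runs 200 null cohorts of 200 × 2000 and the recovery
study 100 planted cohorts of the same size; the SLEA mode cross-check uses
100 trials at 10⁴ resamples; oracle grids cover all hypergeometric tables
with margins ≤ 50 and 1000 random BH vectors. These sizes give the
binomial resolution the acceptance bounds need (e.g. ≥ 95/100 recoveries)
while keeping a full run of the suite within a few minutes on one core.

## Known limitations

* Gene identifiers are opaque case-sensitive strings; no alias resolution
  is attempted (historical symbol drift, e.g. MLL2/KMT2D, is the user's
  responsibility).
* The drug-response and literature layers are external judgements; the
  scorecard only checks non-emptiness/booleans and cannot validate them.
* BH across the single focal-CRF contrast only; no covariate adjustment or
  paired designs.
* The mutual-exclusivity test conditions on per-gene counts only, and its
  coverage statistic does not distinguish exclusivity from simple
  high-frequency alteration when one gene dominates.
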