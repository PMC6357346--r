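---
title: "Methods: integrative signature selection and fuzzy-rule classification"
author: "fuzzsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative signature selection and fuzzy-rule classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzsig)
```

# Overview

`fuzzsig` selects tumor-versus-normal gene signatures by requiring
agreement between two molecular layers (expression and promoter
methylation) and prior knowledge (literature biomarker panels), and
classifies samples with an interpretable Mamdani fuzzy-rule model. This
vignette documents the statistical model at each stage, the tunable
parameters and their defaults, what the bundled simulator does and does not
emulate, and the numerical and design decisions that were genuinely open.

# Differential calling

**Expression.** Input is a genes × samples matrix on the log2 scale
(`log2_transform()` applies `log2(x + pseudocount)`, pseudocount 1, to raw
non-negative values). Each gene is tested tumor vs. normal with a
**Welch** two-sample t-test. We use the unequal-variance form throughout —
tumor cohorts are typically larger and more heterogeneous than their
normal-tissue comparators, and Welch's test is the safe default in that
regime; genes with zero variance in both groups get p = 1 by convention
(no evidence, recorded rather than dropped). A DEG requires
|mean log2 difference| > 1 (i.e. two-fold, since the test runs on log2
data) **and** adjusted p < 0.01. Adjustment is Benjamini–Hochberg by
default; any `p.adjust` method can be substituted. Both thresholds are
arguments (`lfc_threshold`, `p_threshold`).

**Methylation.** Input is a CpG × samples matrix of beta values, validated
to lie in [0, 1] on load. A DML requires adjusted p < 0.01 and
|Δβ| > 0.1; the Δβ gate protects against statistically significant but
biologically negligible shifts at well-measured loci.

**Promoter mapping.** A gene's promoter is the closed interval from 1500 bp
upstream to 500 bp downstream of its TSS, reflected about the TSS on the
minus strand ([tss−500, tss+1500]); `strand_aware = FALSE` disables the
reflection. A locus inside several overlapping promoters contributes to
each gene independently. The interval arithmetic is delegated to
`GenomicRanges::promoters()`/`findOverlaps()`.

**Gene-level combination.** For every gene with at least one promoter
locus, Fisher's combined probability statistic
$\chi^2 = -2\sum_i \ln p_i$ over the **raw** p-values of *all* its
promoter loci is referred to $\chi^2_{2k}$. Combining all loci — not only
the significant ones — makes the gene-level call robust to error at any
single locus, which matters when the methylation matrix is an imputed
("expanded") profile with ~90% per-locus accuracy; the alternative
(`combine = "dml_only"`) is available. q-values are BH-adjusted combined
p-values across the genes carrying ≥ 1 DML, and a DMG requires ≥ 1 DML and
q < 0.01 (`q_threshold`). The q-value procedure is BH rather than a
Storey-type estimator — a deliberate, documented choice where either would
be defensible. Locus p-values are two-sided; the combination is not
directional. A p-value of exactly 0 is clamped to 1e−300 (with a warning)
so the statistic stays finite.

# Signature selection

Candidates are the genes simultaneously DEG and DMG. They are joined by
the biomarker panel and fed to a binomial elastic-net classifier
(`glmnet`), with per-feature penalty multipliers: 1 for ordinary
candidates, `biomarker_penalty` (default **0.1**) for panel genes. The
multiplier spans a continuum — 1 treats biomarkers as ordinary candidates,
0 makes them unpenalized and hence never dropped (save exact
collinearity) — so "prefer the reported biomarkers" and "force them in"
are the two ends of one knob. Mixing parameter `alpha` defaults to 0.5
(midway between ridge and lasso, a common default when no sparsity prior
is available). Features are standardized internally; coefficients are
reported on the original scale.

λ is chosen by seeded, stratified internal 10-fold cross-validation on
binomial deviance. The default rule is **one-SE** (largest λ within one
standard error of the minimum): on pure-noise inputs the literal
CV-minimum is known to be liberal, and in our null experiments it produced
spurious 10–20-gene signatures in roughly a fifth of runs, violating the
package's own no-signal sanity property, while the one-SE rule kept ≥ 95%
of null runs at ≤ 2 genes. On strongly planted signal the two rules give
identical signatures and cross-validation performance, so the conservative
rule costs nothing where it matters; `lambda_rule = "min"` restores the
liberal choice for weak-signal regimes where a larger signature is wanted.

The five model variants are pure feature-set constructors over the same
machinery: `bio` (panel only), `exp` (all DEGs), `exp_meth` (DEG ∩ DMG on
the original-array methylation), `bio_exp_meth` (the same plus panel
weighting), `bio_exp_emeth` (DEG ∩ DMG on the expanded methylation plus
panel weighting). Only expression features enter the elastic net and the
classifier; methylation acts purely as a filter — the design reading in
which the downstream model stays an expression classifier deployable on
expression-only external cohorts.

# The fuzzy-rule classifier

Each signature gene is min/max-normalized to [0, 1] with bounds fitted on
**training samples only**; test values are clamped, and a gene constant in
training maps to 0.5. Three Gaussian linguistic terms cover the range:
small, medium, large, centered at 0, 0.5, 1, common width σ = 0.175 —
with these values the curves cross near membership 0.36, giving a smooth
three-way partition of the unit interval. Centers, σ and the term count
are configurable.

**Induction (Wang–Mendel).** Every training sample yields one candidate
rule: each gene takes its maximum-membership term (ties — which occur
exactly midway between adjacent centers — go to the term with the smaller
center, deterministically), the consequent is the sample's class, and the
candidate's degree is the product of its winning memberships. Candidates
with identical antecedent patterns merge; if both classes claim a pattern,
the class with the larger summed degree wins and the kept rule's weight is
that class's share of the pattern's total degree (a confidence in (0, 1];
unconflicted patterns have weight 1). An exact tie predicts `normal` — the
conservative call for a screening context. The construction is the
classical generate-one-rule-per-example scheme with degree-based conflict
resolution; a count-based resolution would differ only on conflicted
patterns and is not currently exposed.

**Inference.** A rule fires with strength min(antecedent memberships) ×
weight; each class aggregates its rules by max; the argmax wins. Since the
output is a class label, no centroid defuzzification is needed; the
continuous score aggregate(tumor) − aggregate(normal) ∈ [−1, 1] feeds the
AUC. If no rule of either class fires above zero (impossible with Gaussian
memberships except by underflow, but reachable with zero-weight rules) the
majority training class is predicted and flagged.

# Evaluation

Cross-validation is stratified and seeded; fold ids cycle across classes so
folds stay balanced and `k = n` degenerates to leave-one-out. **All feature
selection happens inside each training fold** by default — DEG/DML/DMG
calling, candidate intersection, elastic net, and rule induction never see
the held-out fold; `selection = "global"` reproduces the optimistic
alternative (select once on everything, refit only the rulebase per fold)
for comparison, because the two designs can differ materially in reported
accuracy. Accuracy is argmax-based with no tunable cutoff; AUC is the
Mann–Whitney statistic with ties counted ½.

External cohorts are first reduced to shared genes and
quantile-normalized against the training data: each external sample's
k-th smallest value is replaced by the k-th quantile of the pooled
reference distribution (type-5 quantiles, so the transform is exactly
rank-preserving and idempotent; ties receive the mean of the quantiles
they span).

# The simulator

`simulate_dataset()` generates the paired cohort every claim is tested on:

* **Expression**: per-gene baselines Uniform(4, 10) on log2, Gaussian noise
  (SD `expr_noise_sd`, default 0.5); planted DEGs shift tumor means by
  `expr_effect` (default 3 log2 units) with random sign per gene.
* **Methylation**: per-locus Beta noise around group means with
  concentration `meth_concentration` (default 50, i.e. SD ≈ 0.07 at
  β = 0.5); planted DMGs shift a random non-empty subset (each CpG with
  probability 0.75) of their promoter CpGs by `meth_effect` (default 0.4,
  direction random per gene), with base means re-anchored so both group
  means stay inside (0.05, 0.95).
* **Structure**: `1 + Poisson(mean − 1)` promoter CpGs per gene (default
  mean 3) placed inside the strand-aware promoter window; 20% additional
  decoy loci far outside any promoter exercise the interval filter;
  biomarkers are drawn from the joint DEG ∩ DMG genes, so the panel is
  true signal by construction.
* **Reproducibility**: three RNG streams (annotation/expression/
  methylation) derive from the master seed, so identical seeds give
  bit-identical data and changing one layer's parameters leaves the other
  layers' draws untouched (this is what makes the effect-size
  monotonicity property testable).

The default study conditions — 30 + 30 samples, 300 genes, 10% DEGs, 10%
DMGs, half of each joint — describe a strongly powered design: the
standardized expression effect is d = 6, for which two-sample t-test power
is essentially 1 at n = 30 per group, and the β shift of 0.4 is four times
the call threshold. Passing tests on these conditions therefore
demonstrates that the machinery is correct and leak-free, **not** that the
method would perform comparably on real cohorts, where effects are weaker,
correlated, and confounded. Features the simulator deliberately does not
emulate: gene–gene correlation, batch structure within a cohort (only a
global location/scale shift on the external cohort), count-level
mean–variance coupling, imputation error structure beyond i.i.d. Gaussian
perturbation (`methylation_views()` models the expanded profile as
all-loci-with-noise and the original array as a clean 1/18 locus
subsample), copy-number or mutational signal, and survival outcomes.

`simulate_external()` generates the transfer scenario used for the variant
comparison: a cohort in which only the joint DEG ∩ DMG genes (including
the biomarkers) keep their differential signal while expression-only DEGs
go null — the constructed situation in which the methylation filter
provably removes the unstable expression-only features, so the
`bio_exp_emeth` variant should transfer better than `exp`. This encodes
the *mechanism* claimed for the integrative strategy; it does not test
whether real cross-cohort instability behaves this way.

# Numerical notes and test scale

* Per-row Welch statistics are computed vectorized for speed and verified
  against `stats::t.test` to 1e−12.
* The Fisher tail uses `pchisq(lower.tail = FALSE)`; tests compare it to a
  direct numeric integration of the χ² density to 1e−8.
* The penalty-multiplier semantics relied on for biomarker weighting (a
  weighted fit equals an unweighted fit on columns scaled by 1/w with
  coefficients rescaled) holds exactly for the ℓ1 term and is verified
  numerically at `alpha = 1` with penalty factors summing to the feature
  count; the ℓ2 term breaks the identity for intermediate `alpha`, which
  is why the check is pinned there.
* Test and acceptance runs use simulations between 100 and 500 genes and
  12–60 samples, 5- or 10-fold CV, 10–20 seeds per calibration claim —
  sizes at which every power calculation above saturates while the whole
  suite runs in about two minutes.

# Limitations

* Gene symbols are opaque case-sensitive strings; no alias resolution or
  genome-build handling (any user annotation is accepted as-is).
* Missing values are rejected at load; there is no imputation rule.
* Two classes only; the rule model has no pruning or membership-function
  tuning.
* The expanded-methylation pathway consumes an already-expanded beta
  matrix; producing one is out of scope.
* With many signature genes, each training sample tends to induce a unique
  rule (the antecedent space has 3^g cells), so rule weights are mostly 1
  and the model behaves like a nearest-prototype classifier under the
  min/max algebra; interpretability of individual rules remains, but rule
  *counts* grow linearly with training size.
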