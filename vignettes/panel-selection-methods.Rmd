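---
title: "Methods: dual-fraction biomarker panels, SVM-RFE and repeated cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-fraction biomarker panels, SVM-RFE and repeated cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelselect)
```

`panelselect` studies a specific failure mode of blood-based Alzheimer's
classification: measuring the same protein panel in two blood fractions
(serum and plasma) and naively pooling the columns improves *training*
performance while leaving *test* performance flat, because many same-protein
serum/plasma pairs are strongly rank-correlated and the extra columns mostly
add redundancy for a flexible classifier to memorize. The package provides
the generator, the feature-elimination procedure, the cross-validation
harness, and the statistics needed to demonstrate and quantify that effect
end to end. This vignette records the modelling choices and their
rationale.

## The synthetic cohort model

Real dual-fraction AD cohorts are access-restricted, so the package's
experiments run on synthetic cohorts whose structure mirrors the published
cohort the design is anchored on: 79 AD cases and 65 controls with both
fractions measured, 21 proteins per fraction.

**Marginals.** Protein concentrations are strictly positive and
right-skewed, and a single panel spans four orders of magnitude (serum IL-6
around 2–4 pg/mL against SAA around 8,000–10,000 ng/mL), so each marker is
log-normal. A `marker_spec()` gives the group *medians* (`nc_mean`,
`ad_mean`, assay units) and a within-group coefficient of variation
`cv_within`; the log-scale sd is `sqrt(log(1 + cv^2))`. The anchor study
prints group means without sds, so published values are interpreted as the
group medians of the marginal (for a log-normal the median equals the
geometric mean, and at moderate cv the arithmetic mean differs only by the
factor `exp(sigma^2/2)`); no within-group spread is recoverable from the
printed tables, so `cv_within` defaults to 0.5, a typical between-subject
biological variation for circulating inflammatory proteins. Nothing
downstream depends delicately on this choice: the planted-signal machinery
works in standardized (log-scale sd) units.

**Dependence.** The published analysis reports same-protein cross-fraction
Spearman correlations (five pairs at 0.90–0.93, sTNFR1 at 0.763, IL6 at
0.722) and nothing else, so by default only same-named serum/plasma pairs
are dependent and everything else is independent; arbitrary extra pairwise
targets can be supplied via `extra_rho`. Dependence is imposed by a
Gaussian copula: a latent normal vector with Pearson correlation
`rho_P = 2 sin(pi * rho_S / 6)` — the exact bivariate-normal relation —
yields, after the monotone log-normal transform, marginals whose population
Spearman correlation is exactly the target `rho_S`. For a single pair the
latent 2×2 matrix is positive definite whenever `|rho_S| <= 0.99` (the spec
bound); user-supplied `extra_rho` structures can make the assembled latent
matrix indefinite, in which case a mildly indefinite matrix (minimum
eigenvalue above −0.1) is repaired by eigenvalue clipping at 1e−8 with
rescaling to unit diagonal and a warning naming the perturbed entries,
while a grossly inconsistent one is rejected with a diagnostic naming the
offending pairs — silently "repairing" a spec that is far from feasible
would change the targets the user asked for.

**Demographics.** Ages are group-shifted normals truncated to \[40, 110\]
years (defaults AD 76.14 ± 8.79, NC 71.57 ± 8.91, the published values), so
age carries class signal, as in the real cohort. Education (pooled
15.1 ± 2.9 years, truncated \[6, 24\]) and sex (31% male in both groups)
are simulated but carry no class signal by default, matching the
non-significant published group comparisons.

**Determinism and seed-splitting.** One master seed; each connected block
of correlated columns, and each covariate, draws from its own sub-stream
seeded by a hash of the block's column names. Identical specs therefore
regenerate bitwise-identical cohorts, and adding a marker to a spec does
not perturb the columns already present. Specs round-trip through YAML/JSON
at 17 significant digits so a regenerated cohort from a re-read spec is
also bitwise identical.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: no missing values, no batch or site effects (the
source consortium pools five sites), no longitudinal structure, no
within-fraction correlation beyond what a user adds explicitly, no
covariate–marker dependence (real inflammatory markers drift with age), and
log-normality itself is an assumption, not a fact about every assay.
Recovery rates and gap reductions measured here are properties of the
pipeline under this model, not guarantees about real consortium cohorts.

## The classifier and the elimination procedure

The base model is a soft-margin SVM with linear kernel and cost `C = 1`
(`svm_model()`, fitted via e1071/libsvm). The linear kernel is not
incidental: SVM-RFE ranks features by the squared weight `w_j^2` of the
fitted decision function, which only exists per feature in the linear case.
Features are z-scored before every fit — inside `repeated_cv()` with
training-fold statistics only — so the weights are comparable across
features and `C` acts on a common scale. A constant feature standardizes to
a zero column and receives criterion 0 by construction. The alternative
`criterion = "performance"` scores a feature by the increase in
leave-one-out error when it is removed; it is selectable because weight- and
performance-based readings of an "SVM ranking criterion" are both defensible,
and it is the only criterion available for non-linear kernels.

`rfe()` removes one feature per iteration by default (safest for small
panels; `step` raises it), rescoring each reduced set by LOOCV — the fold
count equals the sample size, so the score has no split randomness, at the
price of high variance. Criterion ties are broken toward the
earlier column of the input table so runs are exactly reproducible.

**Stopping rule.** The procedure's goal is the least number of features
with the lowest error rate. Elimination continues while the LOOCV error
keeps reaching *or tying* its running minimum; only eliminations whose
error rises strictly above the minimum count against `patience` (default
1). Plateau steps must not count: the LOOCV error curve on a 20-feature
panel is noisy and flat over long stretches, and a counter that treats a
tie as a failure stops at the first plateau — in practice retaining nearly
the whole panel and defeating the procedure. The selected panel is the
smallest feature set attaining the minimum error observed anywhere along
the path (including the full initial set); `patience = Inf` eliminates down
to a single feature and then takes the argmin, and on small instances the
result provably matches an exhaustive search over the elimination-consistent
nested subsets (this is tested against an independent manual LOOCV loop).

Two baselines calibrate the selection: `pca_reduce()` (unsupervised; the
leading components maximize variance, not class separation, so signal in a
low-variance direction is lost — the package's tests construct exactly that
case) and `importance_scores()` (permutation importance: mean decrease in
accuracy over `m = 30` column permutations, clipped at zero, seeded and
deterministic).

## The evaluation harness

`cv_config()` defaults to stratified 5-fold cross-validation repeated 10
times — 50 fits — with per-repeat sub-seeds derived from one master seed.
Stratification deals each class's shuffled members round-robin over folds,
so per-fold class counts deviate from proportionality by at most one
sample; with 79/65 that gives test folds of 28–29 with 15–16 AD each.

Per split, the model is fit on the training folds (fold-internal
standardization, optional fold-internal PCA via `n_pca`, optional
fold-internal feature selection via `select_fun`) and evaluated on both
folds. Aggregation follows the published convention: confusion cells are
averaged over all 50 splits and the averages rounded half-away-from-zero
(0.5 rounds up: cell means like 14.37 → 14 and 0.63 → 1), and the six
metrics are computed from the rounded integer matrix. AUC is the
Mann–Whitney rank statistic per split (tie-robust, equivalent to
trapezoidal ROC integration), averaged over splits — averaging was chosen
over pooling scores across splits; the two differ slightly and the
published convention is not recoverable. A metric whose denominator is zero
is reported as `NA`, never 0, because fold-averaged matrices can legally
have empty cells. A test fold that ends up single-class is excluded from
AUC averaging (with a warning) but kept in confusion averaging.

**Overfitting diagnostics.** Two per configuration: the train−test accuracy
gap from the rounded matrices, and the MSE of the 0/1 test predictions —
for hard labels the pooled MSE over all test samples equals the
misclassification rate, i.e. 1 − pooled accuracy. The reported sd is the
sd of per-split MSE values and therefore lies in \[0, 1\]; published MSE
sds larger than 1 evidently follow some other convention, which is why this
package documents its own rather than matching printed sds.

`compare_outcomes()` tests two configurations with a paired two-sided
t-test across per-split test accuracies, defined only when both outcomes
share fold assignments (enforced by a split hash); all-zero differences
give p = 1 by convention. The published pairwise p-values were produced by
an unstated test, so this choice is documented rather than claimed to
reproduce them. `run_grid()` runs all requested configurations on one set
of splits; all `*_rfe` configurations on the same feature universe share a
single full-table selection, mirroring the single published panel. The age
covariate in `combined_rfe_age` is z-scored alongside the markers inside
each training fold so its scale (years) cannot dominate the margin.

**Selection bias caveat.** Full-table selection before CV leaks test
information into the panel choice; the resulting test metrics are
optimistic. This mirrors the published workflow and is the default, but
`rfe_in_folds = TRUE` reruns the elimination inside every training fold for
an unbiased estimate.

## Cohort statistics

`ttest_from_summary()` works from printed group summaries (mean, sd, n):
the pooled variant reproduces the published age comparison (p rounds to
0.002) and equals a raw-data Student t-test exactly whenever the raw data
has those summaries. The printed education p-value (0.020) is *not* exactly
recovered from the rounded printed summaries by either variant (pooled
≈ 0.023, Welch ≈ 0.021) — a rounding artefact of the source table, noted
and not targeted. The sex comparison is an uncorrected chi-square on the
2×2 table, which matches the published 0.806 to within 0.01; the original
test is unstated, so agreement closer than that is not claimed. Per-marker
group tests use Welch's t (the source's power analysis is built on
two-sample t-tests, and equal variances are not defensible across groups);
p-values are reported raw as in the source, with optional
Benjamini–Hochberg adjustment. Correlation strength uses half-open
intervals with the boundary assigned upward: `|rho| >= 0.8` strong,
`0.6 <= |rho| < 0.8` moderate, below 0.6 weak — so 0.9252 is strong and
0.763 moderate.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes,
chosen as the smallest scales at which each property is statistically
decidable: copula and marginal fidelity at n = 10,000 (Spearman tolerance
±0.02 ≈ 2 sampling sds); RFE recovery at 5 informative (1.5 sd on the log
scale) + 15 noise markers, 150 per group, 20 seeds; the overfitting-gap
comparison at 5 informative (1.0 sd) + 30 noise markers at the anchor
cohort's 79/65 with 10×5-fold CV, 20 seeds; oracle equivalence at 6
features, 10 per group. Degenerate inputs are handled explicitly rather
than by crash: constant features (criterion 0, flagged statistics),
single-class folds (AUC exclusion), zero-denominator metrics (`NA`),
zero-sd summary tests (flagged, p = 1 on equal means), zero-margin
proportion tables (flagged, p = 1), and elimination below two features or
two samples per class (errors with remediation hints).

## Known limitations

Beyond the generator's simplifications listed above: the pipeline is
strictly binary (AD/NC), hyperparameters are fixed rather than tuned (no
nested CV — the anchor workflow does none, and adding it would change what
is being replicated), no alternative selectors (LASSO, trees,
mutual information) are included, and single-split metric uncertainty is
not quantified (uncertainty lives at the CV level by design).
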