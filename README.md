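# panelselect

Blood-based biomarker panels are a practical screening route for Alzheimer's
disease (AD): serum and plasma can be drawn in primary care, and panels of
circulating proteins (IL-6, IL-7, sTNFR1, sVCAM-1, SAA, FABP3, ...) separate
AD cases from cognitively normal controls (NC) surprisingly well. Measuring
the *same* proteins in both blood fractions and pooling the columns is
tempting — but many serum/plasma pairs of the same protein are strongly
rank-correlated, so naive pooling mostly adds redundancy, inflates
training-set performance and overfits. `panelselect` implements the pipeline
for studying exactly this trade-off, for biostatisticians building
case-control classifiers on dual-fraction proteomic cohorts:

* **Synthetic dual-fraction cohorts.** A Gaussian-copula generator draws
  log-normal marker marginals with group-specific medians and imposes target
  Spearman correlations `ρ_S` between paired serum/plasma columns through
  the latent Pearson correlation `ρ_P = 2 sin(π ρ_S / 6)`. Planted-signal
  specs (`planted_signal_spec()`) put a known standardized effect into a
  known subset of markers so feature-selection recovery is measurable.
* **SVM-RFE.** Recursive feature elimination ranks standardized features by
  the squared weight `w_j²` of a linear soft-margin SVM (cost `C = 1`),
  removes the lowest-ranked feature, rescores the reduced panel by
  leave-one-out cross-validation (LOOCV), and returns the smallest panel
  attaining the minimum LOOCV error. A performance-drop criterion, a PCA
  baseline (`pca_reduce()`) and permutation importance
  (`importance_scores()`) are included.
* **Repeated stratified CV.** The evaluation harness is 10× repeated
  stratified 5-fold cross-validation; confusion matrices are averaged over
  all 50 splits, rounded half-away-from-zero, and scored with six metrics —
  Sensitivity `TP/(TP+FN)`, Specificity `TN/(TN+FP)`, Precision `TP/(TP+FP)`,
  Accuracy `(TP+TN)/N`, NPV `TN/(TN+FN)`, and the Mann–Whitney AUC. The mean
  squared error of the 0/1 test predictions (the pooled misclassification
  rate) with its across-split sd serves as the overfitting diagnostic, next
  to the train−test accuracy gap.
* **Experiment grid.** `run_grid()` compares `serum_only`, `plasma_only`,
  `combined`, `combined_rfe`, `combined_pca`, `combined_rfe_age`, ... under
  *identical* fold assignments, with paired t-tests on per-split test
  accuracies and an `overfitting_report()`.
* **Cohort statistics.** Summary-statistic t-tests (`ttest_from_summary()`),
  two-proportion tests, per-marker Welch tests with direction of change, and
  Spearman pairs with the strong (`|ρ| ≥ 0.8`) / moderate (`0.6–0.8`) /
  weak (`< 0.6`) classification.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods. A command-line wrapper
(`panel_cli()`, installed at `inst/cli/panelselect`) exposes `simulate`,
`stats`, `select`, `evaluate`, `grid` and `report` subcommands.

**Caveat baked into the design:** following the published workflow, the
default grid selects the panel once on the *full* table before
cross-validating it, which leaks test information into the selection and
biases test metrics upward. `run_grid(rfe_in_folds = TRUE)` (or
`repeated_cv(select_fun = ...)`) reruns the elimination inside every
training fold for an honest estimate.

## Worked example

```r
library(panelselect)

spec   <- demo_cohort_spec(seed = 42)   # 21 proteins x 2 fractions, 79 AD / 65 NC
cohort <- generate_cohort(spec)

demographics_table(cohort)
#>   variable  ad           nc            p_value
#> 1 N         79           65           NA
#> 2 age       76.22 (8.73) 72.13 (8.28)  0.00486
#> 3 education 15.18 (3.15) 14.69 (2.34)  0.305
#> 4 sex (% M) 38.0         27.7          0.193

spearman_pairs(cohort) |> dplyr::arrange(dplyr::desc(abs(rho))) |> head(3)
#>   feature_a   feature_b      rho strength
#> 1 Serum_FABP3 Plasma_FABP3 0.925 strong
#> 2 Serum_I309  Plasma_I309  0.904 strong
#> 3 Serum_CRP   Plasma_CRP   0.896 strong

sel <- rfe(cohort)
sel
#> <rfe_result> 42 -> 21 features; LOOCV error 0.1528 -> 0.0278

repeated_cv(cohort, features = sel$selected_features,
            config = cv_config(seed = 42))
#> <cv_outcome> 10x repeated 5-fold CV on 21 features
#>   test (rounded cells tp/fp/fn/tn = 15/1/1/12):
#>   sensitivity specificity precision accuracy npv    auc
#>   93.75%      92.31%      93.75%    93.10%   92.31% 97.88%
#>   MSE 0.0681 +/- 0.0442
```

The cohort is synthetic, so the numbers quantify the pipeline, not AD
biology: the generator reproduces the published group medians, cross-fraction
correlations and demographics it was anchored on; RFE halves the panel while
reducing the LOOCV error from 15.3% to 2.8%; and the rounded test confusion
matrix (15/1/1/12 over ~29 held-out participants) yields the six metrics in
the printed two-decimal layout.

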