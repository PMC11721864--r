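# autosegeval

Statistical evaluation of AI-based organ autosegmentation across two imaging
systems, in the multi-reader multi-case design used for CBCT-guided online
adaptive radiotherapy: several observers independently correct the AI
contours of several organs on paired scans (one per imaging system) of the
same patients, and the question is whether the higher-quality imaging system
improves autosegmentation performance, interobserver consistency, correction
time, or delineation confidence.

The package provides, as reusable pieces and as one orchestrated pipeline:

* **Contour agreement metrics** on 3D voxel masks with anisotropic spacing:
  the Dice similarity coefficient `DSC = 2|A∩B|/(|A|+|B|)` and the
  95th-percentile Hausdorff distance (pooled directed boundary-voxel
  distances, exact anisotropic Euclidean distance transform in C++),
  plus the 2 cm correction-region restriction used in the clinical workflow.
* **A crossed random-intercepts model** per organ and metric,
  `y = β0 + β1·x + u_patient + v_observer + ε`, estimated by a hand-rolled
  profiled REML (patients and observers crossed, components truncated at
  zero with refit) with Satterthwaite-adjusted inference on the
  imaging-system coefficient β1. On the balanced design this reproduces the
  exact ANOVA F test (97 denominator df at 20×3×2) and matches
  lme4/lmerTest, which serve only as cross-checks in the test suite.
* **Interobserver variability** as a variance-ratio ICC,
  `σ²_obs / (σ²_sys + σ²_pat + σ²_obs)` from the two-way crossed
  decomposition (near 0 = observers consistent), with stratified
  patient-cluster bootstrap confidence intervals (observers never resampled)
  and a Welch comparison of the two arms' replicate distributions.
* **Workflow endpoints**: paired t-test on per-patient correction-time
  totals, an exact tie-aware Wilcoxon signed-rank test on confidence scores,
  and Bonferroni control over the 26-test family (per-test α = 0.0019).
* **A synthetic cohort generator**: superellipsoid organs warped by smooth
  random displacement fields whose magnitude is calibrated to realise the
  linear model above on the Dice scale, plus correction times, confidence
  scores, a heavy-patient outlier scenario (bladder DSC < 0.2, HD95 > 60 mm
  in the conventional arm) and a field-of-view exclusion — so every stage is
  testable with no external data. Real data enter as NIfTI masks plus a CSV
  metadata table (`read_delineations()`).

## Worked example

```r
library(autosegeval)

# agreement between an AI contour and a corrected contour
v <- array(FALSE, c(8, 8, 8)); v[3:5, 3:5, 3:5] <- TRUE
w <- array(FALSE, c(8, 8, 8)); w[4:6, 3:5, 3:5] <- TRUE
ai <- binary_mask(v, spacing_mm = 2); corrected <- binary_mask(w, spacing_mm = 2)
dice(ai, corrected)   # 0.6666667  (27-voxel cubes overlapping in 18 voxels)
hd95(ai, corrected)   # 2          (one 2 mm voxel shift)

# imaging-system effect on a simulated metric table (true effect -0.03)
d <- generate_metric_table(0.86, -0.03, 3e-3, 4e-4, 2.5e-3, seed = 1)
fit <- fit_crossed_model(d, response = "value", reference = "high_performance")
fit
#> <crossed_model_fit> n = 120, converged
#>   beta1 (conventional - high_performance): -0.034941 (SE 0.00786), t = -4.447, df = 97.0, p = 2.317e-05
#>   variance components: patient 0.002595, observer 0.0003027, residual 0.001852

# interobserver ICC in one arm, with cluster-bootstrap uncertainty
arm <- d[d$imaging_system == "high_performance", ]
icc_point(arm)
#> <icc_estimate> ICC = 0.0251 (obs 0.000117 / total 0.00468), 20 patients x 3 observers
b <- stratified_bootstrap_icc(arm, B = 1000, seed = 2)
mean(b); quantile(b, c(.025, .975))
#> 0.0479;  0.0000  0.1678
```

`beta1` is reported as high-performance minus conventional, so here the
conventional arm's Dice is estimated 0.035 lower; the ICC of 0.03 says
observer variance is a negligible share of the total, i.e. the three
observers correct very consistently. The full study is one call:

```r
report <- run_pipeline(cohort_config(seed = 1), out_dir = "results/study")
report   # descriptives, model fits, ICC table, confidence and time endpoints
```

which writes `metrics.csv`, `model_fits.csv`, `icc.csv`, `confidence.csv`,
`time_comparison.csv`, `multiplicity.csv` and a human-readable `report.txt`
(identical config + seed ⇒ byte-identical outputs).

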