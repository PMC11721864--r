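Package: autosegeval
Title: Statistical Evaluation of AI Autosegmentation Across Imaging Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for multi-reader multi-case evaluation of AI-based organ
    autosegmentation across two imaging systems. Provides 3D contour agreement
    metrics (Dice similarity coefficient and 95th-percentile Hausdorff
    distance) on anisotropic voxel grids, a crossed random-intercepts model
    estimated by REML with Satterthwaite-adjusted inference on the
    imaging-system effect, a variance-ratio intraclass correlation with
    stratified patient-cluster bootstrap confidence intervals and Welch
    comparison between arms, secondary workflow endpoints (paired t-test on
    correction times, exact tie-aware Wilcoxon signed-rank test on confidence
    scores, Bonferroni multiplicity control), and a synthetic multi-observer
    contour cohort generator with controllable variance structure so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    lme4,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
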