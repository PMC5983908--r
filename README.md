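# rnflpca

Unsupervised structural-feature analysis of wide-angle retinal nerve fiber
layer (RNFL) thickness maps for glaucoma detection and progression
prediction — with a fully synthetic longitudinal cohort generator so that
every stage of the analysis is testable end to end without access to
clinical data.

## The problem

Glaucoma irreversibly thins the RNFL in characteristic spatial patterns
(arcuate bundle defects, diffuse macular loss). Clinical practice
summarizes OCT imaging into a handful of scalars — most commonly the mean
circumpapillary RNFL thickness (cpRNFLt) on a 3.45 mm circle around the
optic nerve head — discarding most of the spatial information in a
wide-angle (12.0 × 9.0 mm) thickness map that covers the optic nerve head
and macula simultaneously. This package implements an eigen-image
alternative: learn the dominant orthonormal spatial modes of thickness
variation directly from the data, and use a scan's coordinates in that
basis as its structural description.

## The method

Given a longitudinal cohort of thickness maps:

1. **Spatial normalization.** Left-eye scans are mirrored to right-eye
   orientation; each scan is mapped to a canonical frame by the exact
   two-point similarity transform aligning its marked fovea and optic
   nerve head to canonical positions; the alignment is then refined by
   maximizing the enhanced correlation coefficient (ECC) — a
   gain/offset-invariant image correlation — under a similarity motion
   model, coarse-to-fine over an image pyramid.
2. **Standardization.** Each pixel location is standardized to zero mean
   and unit variance across the registered stack.
3. **Eigen-features.** PCA (via the Gram/duality trick, since pixels
   vastly outnumber scans) yields K = 10 orthonormal component maps;
   every scan is `mean + Σ_k w_k · component_k` plus residual, and the
   weights `w_k` are its features.
4. **Association testing.** Each feature is regressed against functional
   (SAP/FDT mean deviation and pattern standard deviation) and structural
   (mean cpRNFLt) measures with age as covariate, Bonferroni-corrected;
   a 10-feature multivariate model reports the variance explained (R²)
   in each clinical measure.
5. **Detection.** A logistic model on the 10 features predicts the
   probability that a map comes from a glaucoma eye, evaluated with a
   participant-based leave-one-out protocol in which standardization,
   PCA, and the classifier are all refit with the held-out participant's
   scans removed. AUCs are estimated by a bootstrap that resamples
   participants and reweights controls to match the case age
   distribution (the groups differ in age by design), and compared
   against mean cpRNFLt, SAP MD, and FDT MD under the identical harness.
6. **Progression.** A linear mixed-effects model (random intercepts and
   slopes per participant and per eye) fit to healthy eyes' longitudinal
   measurements defines a normative rate-of-change distribution; a
   glaucoma eye whose OLS slope is worse than the healthy 95th-percentile
   rate *and* significantly nonzero (P < 0.05) is labeled progressing.
   Baseline-only features are then evaluated for predicting that label.

The synthetic cohort generator produces all inputs with known ground
truth: a healthy template (peripapillary ring, arcuate bundles, thin
fovea), per-eye damage patterns and severities, linear progression
slopes, linked visual-field scalars, anatomical between-eye variability,
and per-scan misalignment plus laterality flips.

## Worked example

```r
library(rnflpca)

config <- cohort_config(
  n_glaucoma_participants = 20, n_healthy_participants = 8,
  eye_totals = NULL, grid_h = 60, grid_w = 80, seed = 301)

report <- run_pipeline(config, K = 10, n_boot = 200)
print(report)
```

which prints (numbers from this exact configuration and seed):

```
RNFL PCA pipeline report
  cohort: 459 scans / 51 eyes / 28 participants
  variance explained by 10 features: 91.3%
  detection AUC (pca): 0.996
  detection AUC (cprnflt): 0.901
  detection AUC (sap_md): 0.856
  detection AUC (fdt_md): 0.828
  progression (mean_cprnflt): 4/37 progressing; baseline PCA AUC 0.544
  progression (sap_md): 1/37 progressing; baseline PCA AUC NA
  progression (fdt_md): 4/37 progressing; baseline PCA AUC 0.258
```

Reading this: the 10 eigen-features explain 91% of pixelwise thickness
variance in this small cohort, and the map-based features detect
glaucoma better (AUC 0.996) than mean cpRNFLt (0.901), SAP MD (0.856),
or FDT MD (0.828) — the ordering that motivates the method. Only 4 of
37 glaucoma eyes progress by the cpRNFLt mixed-model criterion in a
cohort this small, so the baseline progression-prediction AUCs are
dominated by small-sample noise (and the SAP-defined ground truth, with
a single progressing eye, is refused outright rather than scored) —
progression analyses need the larger cohorts used in
`scripts/acceptance.R` and the test suite.

`run_pipeline(..., out_dir = "out/")` additionally writes `report.json`,
CSV tables (variance explained, associations, LOO scores, ROC
coordinates, progression labels), and PNG renderings of each
eigen-feature and its change-region mask. A command-line wrapper lives
at `inst/scripts/run_pipeline.R`.

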