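---
title: "Eigen-features of RNFL thickness maps: model, design choices, and what the synthetic cohort does and does not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigen-features of RNFL thickness maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnflpca)
```

This vignette is the package's account of its science: the statistical
model behind each stage, the parameters that matter and why their
defaults are what they are, the numerical choices, and the limits of
what a passing test suite demonstrates.

## The model in one paragraph

A wide-angle OCT thickness map is treated as a vector of per-pixel RNFL
thicknesses in a canonical anatomical frame. After spatial normalization
and per-pixel standardization, the cohort's maps are assumed to live
near a low-dimensional linear subspace: `z = μ + Σ_k w_k φ_k + ε`, where
the `φ_k` are orthonormal eigen-images estimated by PCA and the weights
`w_k` are the scan's structural features. Downstream analyses are
ordinary statistics on these weights: age-adjusted linear models for
association, regularizable logistic regression for classification, and
linear mixed models for normative rates of change.

## Spatial normalization

**Laterality.** Left-eye scans are mirrored about the vertical axis so
that all maps share right-eye anatomy (optic nerve head nasal — i.e.
left — of the fovea). The mirror is an exact involution on values and
landmarks.

**Landmark alignment.** Treating 2-D points as complex numbers, the
similarity transform mapping a scan's marked fovea/ONH pair onto
canonical positions is the solution of a 2 × 2 linear system — exact, no
optimization. The canonical positions are fixed fractions of the grid
(fovea at 62% of width, ONH at 30%), which makes the reference frame
dataset-independent; aligning to one arbitrarily chosen cohort scan
would reproduce the same geometry up to a similarity transform while
making results depend on that choice.

**ECC refinement.** Manual landmark marks carry error (simulated at
1 px s.d.), and a similarity fit to two noisy points propagates that
error across the whole map. The refinement stage therefore maximizes
the enhanced correlation coefficient — correlation of zero-mean
intensity vectors, invariant to affine photometric differences between
scans — against the pixelwise mean of all landmark-aligned maps, using
closed-form Gauss–Newton updates over a 3-level image pyramid. The
motion model is full similarity, not Euclidean: the two-point landmark
fit resolves scale only up to the marking noise (≈ √2·1 px over a
~50 px fovea–ONH baseline, i.e. ~3% scale error), and restricting the
refinement to rotation + translation leaves that error in place. On a
pilot misaligned fixture, similarity refinement reduced the mean
landmark residual from 0.80 px (Euclidean) to 0.55 px. A second
refinement pass against the refined mean was tried and rejected: it
re-registers already-resampled maps and the added interpolation blur
made residuals worse. Scans whose refinement does not converge keep
their landmark-only alignment and are flagged so callers can exclude
them, mirroring reading-center quality-control exclusion of misaligned
scans.

Each scan is resampled exactly once, bilinearly, with the composed
transform. Output pixels falling outside the source grid become `NA`
sentinels that are excluded from standardization statistics — zero
filling would corrupt the per-pixel variance — and imputed with 0 (the
standardized mean) only when map vectors must be dense for PCA.

## Standardization and PCA

Per-pixel means and standard deviations are computed over the registered
stack with the s.d. floored at ε = 10⁻⁶ µm, so pixels constant across
the stack standardize to 0 rather than dividing by zero. Within any
cross-validated evaluation these statistics are refit on training scans
only: the standardization is a learned model and sharing it with test
scans would leak information.

PCA pools one vector per scan — all visits of all eyes — matching the
design in which features describe maps, not eyes; eye-level analyses
later use baseline scans' weights. With pixels ≫ scans the eigenvectors
come from the n × n Gram matrix, mapped back to pixel space and
canonicalized so each component's largest-magnitude loading is
positive; the solver is deterministic (no randomized SVD) so identical
inputs give identical models. K = 10 components are retained by
default. The threshold is dataset-dependent and exposed as a parameter;
10 is kept as the default because the downstream logistic models are
fit on cohorts of tens of participants, where a feature count an order
of magnitude below the sample size keeps them well-posed.

## Association testing

Quantitative measures: OLS of the measure on one feature weight plus
age; the feature slope's t-test is the association test. Categorical
measures: age is regressed out of the weights and a one-way ANOVA
compares residuals across categories. Age appears in every model
because the diagnostic groups differ in age by construction (healthy
~N(48, 10), glaucoma ~N(65, 10) years), and any analysis ignoring it
would partly rediscover the confound. The Bonferroni family is declared
explicitly as features × measurements — the full battery actually run —
since an undeclared family makes "corrected" significance unverifiable.
Both eyes of a participant enter these simple models as independent
rows; this mirrors common practice for baseline association scans, but
it is a known simplification and the reason the detection and
progression stages switch to participant-level resampling.

## Detection

The unit of holdout is the participant: all scans from the held-out
participant are removed, standardization + PCA + logistic model are
refit, and the held-out scans are scored. Comparator models (mean
cpRNFLt, SAP MD, FDT MD) are single-predictor logistic fits under the
identical folds — the logistic map is monotone, so their AUCs equal the
raw measurements' AUCs while sharing one harness. Logistic fits that
separate or fail to converge are refit with a lightly ridge-penalized
IRLS (λ = 10⁻³, intercept unpenalized) and flagged.

AUC is computed in Mann–Whitney rank form (ties count one half),
identical to the trapezoidal ROC area. The age-controlled bootstrap
resamples participants — not eyes or scans, respecting clustering —
drawing controls with weights equal to case/control frequency ratios in
5-year age bins (bins holding cases but no controls are merged into the
nearest occupied bin). The reported AUC is the replicate mean with a
percentile interval; paired comparisons evaluate both score vectors on
identical resamples and take the two-sided p from the distribution of
the AUC difference. The bin-reweighting scheme is this package's
explicit construction; it has the no-confound limit (identical age
distributions ⇒ weights 1 ⇒ plain bootstrap) and removes a pure
age-driven score difference by construction, both of which are asserted
in tests.

## Progression

For each measurement, a linear mixed model with fixed intercept and
time slope and random intercepts + slopes per participant and per eye
(REML, via `lme4`) is fit to healthy eyes only; each healthy eye's rate
is the fixed slope plus its participant- and eye-level random slopes,
and the normative limit is the 5th percentile of these signed rates
(worsening = more negative for thickness and MD; the direction is
declared per measurement rather than inferred). The limit is taken from
the estimated population distribution of rates — fixed slope plus the
normal quantile times the square root of the summed slope variance
components — not from an empirical quantile of the per-eye predicted
rates: BLUPs are shrunken toward the fixed slope, and a quantile of
shrunken rates is an anti-conservative normative limit (measured as a
~2-point inflation of the criterion's null false-positive rate before
this choice). A singular fit falls back to per-eye OLS slopes with an
empirical-quantile limit, flagged. A glaucoma eye is labeled
progressing when its OLS slope is below the limit *and* its slope
t-test gives p < 0.05; eyes with fewer than 3 usable visits are
unclassifiable and counted. Time is in years so slopes are per-year.

Even with the population-quantile limit, the criterion operates as
intended only when the normative between-eye rate spread dominates the
slope-estimation error of the glaucoma eyes' OLS rates (estimation
noise inflates crossings of any fixed limit); the generator's defaults
(below) are chosen in that regime, and the false-positive rate of the
criterion under a null simulation is part of the test suite.

Baseline prediction of the progression label uses the same
leave-one-participant-out structure; features are learned on all
training scans but the classifier sees baseline weights only. The
bootstrap resampling unit is the participant *within* label, since a
participant's two eyes can legitimately carry different progression
labels.

## The synthetic cohort: what it emulates, and the defaults

The generator reproduces the study design the pipeline assumes: 93
glaucoma participants / 179 eyes and 28 healthy participants / 56 eyes
by default (participants are assigned one or two eyes to force the
totals), visits every 3 months for 2 years, a 12.0 × 9.0 mm field, and
an age confound between groups.

The healthy template is built from a peripapillary ring (peak ≈ 1.6 mm
from the ONH with a superior/inferior double-hump), two arcuate bundles
following quadratic Bézier trajectories around the macula, and a foveal
depression; its overall amplitude is solved in closed form so the mean
thickness on the standard 3.45 mm circle equals the 100 µm target.
Damage masks are smooth Gaussian ridges along the bundle trajectories
(inferior/superior arcuate) or a broad macular Gaussian (diffuse), each
blended by default with 35% of a proportional thickness-weighted mask —
glaucomatous eyes typically combine focal wedge defects with
generalized loss, and a purely focal mask puts too little damage on the
measurement circle for cpRNFLt to behave like the meaningful comparator
it is clinically.

Defaults that matter, with units and rationale:

- severity ~ Gamma(2, 20) µm at the pattern peak: right-skewed with
  most mass at early damage, so detection is not trivially saturated;
- anatomical thickness offsets (participant 4, eye 3 µm s.d.): healthy
  eyes differ; without this, any classifier separates groups perfectly;
- aging slope −0.4 µm/yr with participant/eye random components
  0.5/0.35 µm/yr s.d. and 0.3 µm per-visit noise on cpRNFLt: the
  between-eye rate spread then dominates slope-estimation error
  (SE ≈ 0.2 µm/yr over 9 visits), the regime in which the normative
  95th-percentile criterion holds its design specificity;
- progression slope ~ N(−3.5, 1) µm/yr at pattern peak in a
  configurable fraction (default 20%) of glaucoma eyes, with the
  probability of progressing rising with baseline severity (log-odds
  2.5 per severity s.d.): baseline structure genuinely drives future
  change, which is the premise behind predicting progression from
  baseline data;
- visual-field links: MD = −1.0 (SAP) / −0.9 (FDT) dB per µm of
  map-mean deficit with 3 dB noise. The corresponding structure–function
  R² then lands near 0.5, the magnitude typically reported for
  OCT–perimetry relations; the true visit-level correlation is not a
  published quantity, so these coefficients are exposed in the
  configuration rather than asserted;
- cpRNFLt carries a per-eye cross-device offset (4 µm s.d.): in the
  emulated design the circle scan comes from a different instrument
  than the map, so the two agree only up to an eye-specific bias —
  without this the map features would explain cpRNFLt almost exactly;
- per-scan misalignment: translations ±5 px, rotations ±3°, scale ±3%,
  landmark marking noise 1 px, ~50% left eyes.

Noise fields are i.i.d. Gaussian per pixel, smoothed (σ = 1 px) and
renormalized to 2 µm marginal s.d., mimicking spatially correlated
segmentation error.

**What passing tests do not show.** The generator's damage is exactly
low-rank and its noise exactly Gaussian, so PCA is well-specified here
in a way it cannot be for real retinas; detection AUCs on synthetic
strong-signal cohorts (≈ 0.97–1.0) exceed what real data supports, and
only the *orderings* (map features ≥ single summaries) and the
statistical machinery (leakage guards, confound control, criterion
specificity) transfer. Real-cohort magnitudes are not reproduction
targets anywhere in the package.

## Numerical choices and degenerate inputs

- Bilinear interpolation throughout; a resampled map clips tiny
  negative interpolation overshoot at 0.
- ECC convergence is declared when the parameter update moves the image
  corner by < 10⁻⁴ px; the coarsest pyramid level keeps at least 24 px
  on its short side.
- Circle extraction uses ≥ 256 (default 512) equally spaced bilinear
  samples; an oversampled quadrature oracle agrees to < 0.1 µm.
- Flat series in rate estimation: slope 0 with p = 1 (an exact nonzero
  line gives p = 0); fewer than 3 visits yields no estimate.
- Constant feature weights or rank-deficient design matrices are
  flagged, not silently tested.
- All randomness flows from explicit seeds (`cohort_config()` requires
  one; bootstrap functions take one), and RNG state is restored after
  use.

## Problem sizes used in the test suite

Unit and property tests run on 60 × 80 px grids (0.15 mm/px, preserving
the 4:3 field) with cohorts of 4–70 participants; the end-to-end smoke
test uses 20 + 8 participants, 9 visits, and 200 bootstrap replicates;
null-specificity and coverage properties use 100 measurement-level
simulated cohorts, which are statistically identical to the generator's
cpRNFLt process without the cost of rendering maps. The acceptance
script runs the complete pipeline on 40 + 16 participants at the same
grid. These sizes are the package's chosen desk-scale study conditions;
the full 121-participant, 160 × 120 px default remains available
through `cohort_config()`.

## Known limitations

- No A-scan/B-scan physics, layer segmentation, or pointwise
  visual-field simulation (MD/PSD scalars only); device I/O for
  proprietary OCT formats is out of scope.
- The two-point landmark transform cannot represent shear or
  nonrigid deformation; real eyes differ nonrigidly.
- Associations treat two eyes of a participant as independent rows.
- The leave-one-out protocol's pooled probabilities are known to be
  slightly anti-calibrated across folds under weak signal (each held-out
  case is scored by a model trained with one fewer case); with the
  designed effect sizes this bias is negligible relative to the signal,
  but it is visible in label-permuted null runs as AUCs marginally
  below 0.5.
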