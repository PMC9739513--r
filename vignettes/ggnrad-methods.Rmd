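---
title: "Radiomic prediction of pGGN invasiveness: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic prediction of pGGN invasiveness: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggnrad)
```

## The problem

A pure ground-glass nodule (pGGN) is a lung lesion with hazy CT attenuation
and no solid component. Most resected pGGNs turn out to be adenocarcinoma in
situ (AIS) or minimally invasive adenocarcinoma (MIA) — lesions with
essentially 100% disease-free survival after a wide wedge resection — but a
substantial minority (around one in five in surgical series) are invasive
adenocarcinoma, for which segmentectomy or lobectomy is preferred. The
surgeon must commit to an operation before pathology exists, so a
preoperative, image-based prediction of invasiveness has direct clinical
value.

`ggnrad` implements the classical CT-radiomics recipe for this question:
segment the nodule in a 1 mm isotropic volume of interest, quantify its
shape, intensity distribution and gray-level texture in a fixed feature
registry, and classify invasiveness with a logistic model on a small set of
forward-selected features, evaluated by leave-one-out cross-validation
(LOOCV) with a Youden-index decision cutoff. Because no patient CT volumes
are distributed with the studies this pipeline descends from, the package
ships a synthetic-data module that generates 3D pGGN phantoms with known
ground truth, calibrated to the published cohort statistics; every stage is
exercised and tested end-to-end on those phantoms.

## The synthetic cohort: what it emulates and what it does not

`phantom_spec()` describes one nodule: an ellipsoid of geometric-mean radius
`nodule_radius_mm` (default 5.5 mm, i.e. a 1.1 cm lesion), mean attenuation
`nodule_density_hu` (default -722.7 HU, the pooled cohort mean) over a
-850 HU parenchyma, scanned at `spacing_mm = (1.0, 0.7, 0.7)` mm — a
thin-slice acquisition inside the published ranges (slice thickness
0.625–1.25 mm, pixel spacing 0.41–0.88 mm). Intensities are rounded to
integer HU, the CT convention, which also makes noiseless phantoms exactly
countable in tests.

Three mechanisms give the nodule realistic structure, all scaled by a single
`heterogeneity` knob in `[0, 1]`:

* a smooth random radial warp of the boundary (amplitude `0.2 * h`
  relative to the radius), so shape features are not trivially spherical;
* a low-pass-filtered Gaussian intensity field inside the nodule
  (amplitude `60 * h` HU, mean-centred within the mask so the calibration
  to the target mean HU is exact), which makes texture features
  class-separable through the class contrast in `h`;
* a sigmoid edge profile of relative width `0.08 * h` — the "ground-glass
  haze" — recentred so the in-mask mean still equals the target density. In
  the homogeneous limit (`h = 0`) the edge is hard.

`generate_cohort_phantoms()` draws per-patient size and density from
class-conditional normals. The non-invasive class is centred on the printed
AIS/MIA statistics (diameter 1.1 ± 0.4 cm, density -727.0 ± 46.3 HU); the
default `class_effects` shift the invasive class to the printed invasive
statistics (1.3 ± 0.6 cm, -691.0 ± 45.1 HU) and raise heterogeneity by
0.15. Setting all effects to zero makes the classes exchangeable, which the
test suite verifies with a null two-sample test over 50 replicate cohorts.
Size and density are drawn independently: the within-class correlation
between them is not published, and independence is the neutral choice.

An optional vessel is a straight cylinder (default radius 1.5 mm at
-600 HU) laid tangent to the nodule surface in a random orientation — the
simplest structure with high tubular (Frangi) response. The vessel is
excluded from the ground-truth mask, exactly as a human annotator would
exclude it.

What the phantoms do **not** emulate: scanner reconstruction kernels, beam
hardening, part-solid or solid nodules, bronchi, fissures, or the chest
wall. Passing tests on phantoms therefore demonstrate that the machinery is
correct and well-calibrated under controlled conditions, not that the
trained model transfers to clinical CT.

## Volume preparation

Internally every volume is an array indexed `(z, y, x)` with spacing in the
same order; file readers (NIfTI via RNifti, plus a minimal NRRD
reader/writer for raw and gzip encodings) convert from the on-disk
fastest-first axis order, so transposition bugs cannot arise downstream.
`resample_isotropic()` interpolates trilinearly onto a 1 mm grid anchored at
the input origin with voxel-centre alignment; this makes resampling of an
already-isotropic volume the exact identity and reproduces affine intensity
fields to machine precision, both of which are tested. Interpolation clamps
at the edges, so resampled intensities never leave the input range. The
64-cube VOI is cropped around a user-supplied seed voxel (1-based, in
resampled coordinates — seeds are defined *after* resampling); regions
outside the volume are padded with air at -1000 HU, the physically neutral
CT background.

## Segmentation

The initial segmentation is a hybrid level set: a clamped level-set function
starts as a 3 mm ball at the VOI centre and evolves under a region force
(+1 where intensity is at or above the lower lesion bound `mu_hu`, -1
below) plus `curvature_weight` times a discrete curvature proxy (3-cube box
mean minus centre). Iteration stops at `levelset_iterations` (default 60)
or when fewer than `convergence_tol` of voxels change sign in one step;
non-convergence is recorded in the result's provenance, never raised as an
error. The final mask is the component connected to the VOI centre. Two
limiting behaviours anchor the scheme: with zero curvature weight it
converges exactly to the seed-connected threshold component (tested against
an independent connected-component oracle), and on noiseless two-level
phantoms the mask is monotone non-increasing in `mu_hu`.

`mu_hu` is the one parameter a user is expected to adjust. Its default is
estimated from the VOI itself: the midpoint between the parenchyma mode
(histogram mode of the VOI outside a central ball, excluding voxels below
-950 HU so that air and VOI padding cannot masquerade as background) and
the lesion mode (median of a central 4 mm ball — the seed is the lesion
centre by construction). On two-level phantoms this lands near the
50%-contrast point, where the threshold surface tracks the true boundary.

Vessel removal combines a multiscale Frangi vesselness map (scales 0.5, 1,
1.5 and 2 mm — the calibre of vessels reaching a peripheral nodule —
`alpha = beta = 0.5`, structureness scale `c` set per filter scale to half
the maximal Hessian norm, gamma = 2 scale normalization) with hysteresis
extraction: voxels at or above `vesselness_threshold` (0.5) seed the vessel
set only if they form a connected component of at least 10 voxels (isolated
rim responses are noise, a real vessel core is a sizeable tube), and the
set grows through connected voxels above half the threshold. A deep nodule
core — more than two 6-connectivity erosions from the mask boundary — is
protected, because a tangent vessel can only overlap the peripheral shell.
Post-processing keeps the centre-connected component and fills interior
holes. On vessel phantoms this removes 80–98% of in-mask tube voxels while
retaining over 95% of true nodule voxels; on vessel-free phantoms it
changes at most 2% of the mask.

A `manual_edit` mask-delta hook stands in for the specialist adjustment
step of the clinical procedure: the supplied delta is XOR-ed onto the
automatic result, and the configuration plus per-stage statistics travel
with the mask as provenance.

## The feature registry

The characterizing step is a declared, versioned registry
(`feature_registry()`, version `"v1"`, manifest shipped as YAML) of exactly
404 features:

* 14 morphology features computed once from the mask (covariance axis
  statistics; mesh volume and surface area from a marching-tetrahedra
  surface of the lightly smoothed indicator field — meshing the raw binary
  field overestimates a ball's area by ~25%, while the smoothed mesh
  reproduces sphere area within ~1% and volume within ~2.5%);
* 20 extended percentiles (P5–P100 in 5% steps) of the in-mask HU;
* 74 intensity/texture features — 20 histogram, 24 GLCM, 16 GLRLM, 14
  GLSZM — on each of five image variants: the original VOI, three
  Laplacian-of-Gaussian scales (1, 2, 3 mm) and one Gaussian smoothing
  (1 mm). 14 + 20 + 5 × 74 = 404.

Quantization uses 32 equal-width bins over the in-mask range (lower-open
bins, top bin closed), which buys HU-shift invariance for every texture
feature and bounds all matrix sizes. GLCM counts are pooled over the 13
unique distance-1 directions and symmetrized before normalization; GLRLM
features are computed per direction and averaged; GLSZM zones are
26-connected components of constant level. These aggregation conventions
are stated exactly so that the brute-force enumeration oracles in the test
suite (exhaustive pair counts, voxel-by-voxel run walks, stack-based flood
fill) can match them to 1e-9 on a hundred random small images.

The 26 row labels of the published feature table (spelled as printed,
including "homogenity" for the inverse-difference-moment homogeneity) map
onto registry names through `table4_features()`; all 26 are present in the
default output. The full 404-entry manifest of the original work is not
published — only the family names and those 26 members are recoverable — so
the registry here is declared and auditable rather than a guess at an
unpublished list: the composition above is this package's own, fixed and
versioned.

Degenerate inputs degrade gracefully: a mask smaller than a 2-cube cannot
support shape features and a single voxel admits no co-occurrence pair;
such families are reported as `NA` with reasons attached, never silently
dropped.

## The statistical core

Features are screened univariately with pooled-variance two-tailed t-tests
(raw p-values, no multiplicity correction — the screen is descriptive and
does not gate selection by default). Normalization is z-scoring with the
sample (n-1) standard deviation; parameters are always fitted on training
rows and frozen before being applied elsewhere, and constant columns are
dropped with a warning.

Sequential forward selection adds, at each step, the feature whose
candidate model maximizes LOOCV accuracy at a 0.5 probability threshold,
stopping when no candidate improves the criterion; ties break toward the
earlier column, making selection fully deterministic. By default selection
runs once on the full cohort and LOOCV then scores the selected set — the
procedure the published work appears to use, which is optimistic for the
selection step; `nested = TRUE` in `loocv_evaluate()` wraps selection
inside every fold and is the recommended unbiased mode.

The classifier is unregularized maximum-likelihood logistic regression. On
separation or non-convergence a lightly ridge-penalized IRLS fit
(epsilon = 1e-4) is substituted and flagged — never silently. No class
reweighting is applied: prevalence is whatever the cohort provides, and
class imbalance is a known limitation of the design. LOOCV refits
normalization and the model on every fold; metrics come from the pooled
out-of-fold probabilities, making the result invariant to row order. A fold
that loses one class entirely is flagged and predicted with the training
prior. The ROC curve sweeps every observed score as a threshold; the AUC is
trapezoidal (equal to pairwise concordance with ties counted one half), and
the decision cutoff maximizes the Youden index, resolving ties to the
highest threshold. External validation applies the frozen model —
normalization parameters, coefficients and cutoff — unchanged.

Two numerical subtleties of LOOCV are worth recording, because both are
properties of the procedure rather than bugs:

* **Separable-limit boundary artifact.** On perfectly separable data with
  *uniform* spacing, the held-out boundary sample sits exactly at the
  max-margin midpoint of its training fold, so its out-of-fold probability
  is ~0.5 and LOOCV is not guaranteed a perfect AUC even though the feature
  separates the classes; with any genuine margin between the classes the
  separable limit gives AUC 1 exactly, which is what the test asserts.
* **Pessimistic null bias under imbalance.** With pooled out-of-fold
  probabilities and per-fold refits, a fold holding out a positive trains
  at lower prevalence than a fold holding out a negative, so the fold prior
  systematically anti-ranks every held-out sample. On pure-noise features
  the LOOCV AUC therefore centres well below 0.5 — around 0.42 at the
  102-patient, 12-event, 3-feature setting, a value reproduced to three
  decimals by an independent scikit-learn implementation of the identical
  protocol. This is the stratification bias documented in the
  cross-validation literature; it affects null calibration, not the ranking
  of genuinely informative models, and it is why the test suite asserts
  that the null distribution centres *below* chance rather than at it. A
  chance-level null would require either abandoning per-fold refits or
  replacing LOOCV with stratified or leave-pair-out schemes, both outside
  this pipeline's design.

## Problem sizes and simulation settings

The test suite and the acceptance script choose the following sizes as the
package's standard verification conditions: oracle equivalence on 100
random images up to 6-cube with 2–8 levels; segmentation accuracy on 20
phantoms spanning noiseless to default noise; vessel removal on 3–8 vessel
phantoms; the null simulation on 50 replicate 40-patient cohorts with
pure-noise features; and the discrimination surrogate on 20 replicate
cohorts of 102 patients (90 vs 12, the thin-slice class balance) with 50
features of which 3 carry a standardized mean difference of 1.0. Smoke
tests of the full image pipeline run at n = 5–6 phantoms on reduced grids.
Cohort-level calibration checks use 50 phantoms per class and require the
class mean of within-mask mean HU to sit inside the printed mean ± 2 SE.

## Known limitations

* The hybrid level set and the Frangi filter are faithful to the *kind* of
  algorithm named by the original pipeline, not to any specific prior
  implementation; iteration budgets, scale sets and thresholds are this
  package's defaults, documented above.
* The 404-feature manifest matches the published families and the 26
  published members, but the remaining composition is necessarily this
  package's own declaration.
* Phantom realism is deliberately minimal (see above); absolute feature
  values on phantoms — e.g. in-mask histogram entropy around 4.4–4.7 bits
  versus 5.6–5.9 on clinical nodules — sit at the hazier end of the
  published plausibility envelope because synthetic texture is
  Gaussian-dominated.
* With 12 events in 102 patients, LOOCV AUC estimates are noisy; the
  acceptance surrogate therefore reports a median over 20 replicate
  cohorts rather than any single run.

## A worked example

```{r example, eval = FALSE}
library(ggnrad)

# one phantom end-to-end
ph <- generate_phantom(phantom_spec(seed = 1))
iso <- resample_isotropic(ph$volume)
voi <- extract_voi(iso, round((dim(iso$values) + 1) / 2))
mask <- segment_nodule(voi)
features <- extract_features(voi, mask)
dim(features)                      # 1 x 404

# tabular cohort through the statistical core
cohort <- simulate_feature_cohort(n = 102, n_invasive = 12, seed = 1)
normalized <- zscore_fit_apply(cohort)
selected <- sfs_select(normalized)
ev <- loocv_evaluate(cohort, features = selected)
glance(ev)
autoplot(ev)
```
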