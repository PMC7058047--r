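---
title: "Joint space mapping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint space mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsmapr)
```

jsmapr measures three-dimensional joint space width (JSW) — the bone-to-bone
distance across a synovial joint, the CT/radiographic surrogate of cartilage
thickness — at thousands of points on the hip, and carries those maps through
a complete statistical pipeline: registration of every hip to one canonical
acetabular surface, a statistical shape model (SSM), surface statistical
parametric mapping (SPM) with random field theory (RFT), generalised
estimating equations (GEE) for the association of shape with future total hip
replacement (THR), and leave-one-out cross-validated ROC prediction. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where more than one reasonable choice existed.

## The measurement model: constrained deconvolution

The joint space is a laminar structure, often thinner than the resolution of
clinical CT. The imaging system blur (point spread function, PSF) is modelled
as an isotropic Gaussian of standard deviation $\sigma$; a naive width
measurement of a gap narrower than about $2\sigma$ is badly biased, so the
blur must be deconvolved rather than ignored.

At each vertex of the femoral joint-space patch, a 1D density profile is
sampled along the outward surface normal ([extract_profile()]) and fitted
with a four-interface Gaussian-blurred step model
([fit_profile()]):

$$y(x) = y_{bg1} + (y_c - y_{bg1})\Phi\!\left(\tfrac{x-e_1}{\sigma}\right)
 + (y_{gap} - y_c)\Phi\!\left(\tfrac{x-e_2}{\sigma}\right)
 + (y_c - y_{gap})\Phi\!\left(\tfrac{x-e_3}{\sigma}\right)
 + (y_{bg2} - y_c)\Phi\!\left(\tfrac{x-e_4}{\sigma}\right)$$

with the femoral subchondral plate on $[e_1, e_2]$, the joint gap on
$[e_2, e_3]$ and the acetabular plate on $[e_3, e_4]$. JSW is the fitted gap
$e_3 - e_2$ between the joint-facing subchondral edges — we read "the
distance between the subchondral bone layers" as the gap between their
joint-facing edges, the only reading consistent with radiographic JSW.

A blurred profile constrains little more than products of widths and density
contrasts, so the fit is *constrained*:

* **Fixed cortical plateau** $y_c$: estimated once per joint-space patch as
  the median plateau of unconstrained first-pass fits
  ([estimate_patch_density()]), then held fixed in every second-pass fit.
  Estimating it from subchondral bone local to the joint (rather than the
  whole femur) keeps the constraint representative of the bone being
  measured.
* **Fixed PSF width**: the blur belongs to the scanner, not to one sample
  line. The patch-level $\sigma$ (jointly with a refinement of the plateau)
  is chosen by profile likelihood over a shared grid, taking the median
  across a profile subsample of each candidate's best-fit residual — the
  median so that a few corrupted profiles cannot steer the patch estimates.
  Freeing $\sigma$ per profile lets sub-PSF gaps trade width against blur
  into solutions several millimetres off — we verified this from
  truth-started optimisation before fixing it.
* **Bounded joint-space density**: the gap holds cartilage and synovial
  fluid, far less dense than subchondral bone, so $y_{gap}$ is capped at
  0.4 of the plateau (`gap_density_frac`). Without the cap, a wide shallow
  gap and a narrow deep one are likelihood-equivalent under heavy blur.
* **Bounded plate widths** (0.8–8 mm): a subchondral plate cannot dissolve
  to zero thickness to re-label the far background drop as a gap edge.

The optimiser is bounded Levenberg–Marquardt least squares with interface
ordering enforced by positive-width parameterisation, multi-started from
gradient-based edge candidates plus one start seeded by a coarse exhaustive
scan of $(e_2, e_3)$ with the densities profiled out. The same scan at a
0.01 mm step ([fit_profile_grid()]) is shipped as the brute-force validation
backend. A fit is declared failed (never an exception) on optimiser failure
or when its residual exceeds five times the patch median; failed vertices are
infilled from up to three rings of valid neighbours before smoothing
([map_jsw()]).

On the default phantom sweep (gaps 1–6 mm, $\sigma$ 0.5–1.5 mm, voxels
0.977 × 0.977 × 1 mm, noise 1–2 % of the plateau) the acceptance suite
measures a cohort-level systematic bias well under 0.2 mm, and the
constrained fit beats the naive half-plateau full-width comparator
([jsw_halfwidth()]) wherever the gap is below $2\sigma$. The hardest corner
(1 mm gap under 1.5 mm blur) is close to non-identifiable at 2 % noise; its
per-profile errors are large but nearly unbiased, which is why the sweep
criterion is stated at cohort level, matching how the technique's accuracy
is quoted in practice.

## Synthetic data: what it emulates and what it does not

Clinical CT cohorts of this design are access-restricted, so the package
generates everything it needs:

* **Phantoms** ([make_phantom_volume()]): flat-slab and spherical-shell
  two-plate geometries, voxelized (anti-aliased 3×3×3 subsampling), blurred
  by a separable Gaussian and degraded with i.i.d. Gaussian noise. The blur
  is exact for the slab (closed form) and matches the exact radial
  convolution for the shell to voxel-discretization accuracy.
* **Cohorts** ([simulate_cohort()], [make_paired_hip_surfaces()]): defaults
  are the study conditions — 80 expected THR case individuals and 187
  controls; paired hips correlated at R = 0.5 through a shared
  individual-level latent field; superior narrowing in cases peaking at
  1 mm in the individual-averaged map (1.5× on the replaced hip, 0.5× on
  the contralateral case hip, so the averaged group difference and the
  replaced-minus-opposite asymmetry both peak at the stated value);
  0.75 mm posterior widening on the replaced side only; 16 supra-noise
  shape modes whose first 7 hold 90 % of the signal variance (geometric
  head, flat tail — the flat tail keeps all 16 separable from the noise
  floor by parallel analysis); per-adjusted-SD odds ratios 1.43, 1.75,
  1.37, 1.02, 0.88, 1.39, 1.18 for the first seven modes; age 74.3 ± 4.9,
  BMI 27.6 ± 4.2, sex correlated with the scale mode at r² = 0.7; ordinal
  KL grade (0–4) and a noisy minimum-2D-JSW surrogate driven by the
  planted superior state. The hip-level THR outcome is Bernoulli from the
  logistic model with the intercept solved so the expected case fraction
  is 80/267.

The generator emulates regional effects, pairing, and measurement noise; it
does **not** emulate realistic femoral anatomy, osteophytes, correlated CT
noise, scanner drift, or positioning variation. Passing tests therefore show
that the algorithms recover what was planted under idealised geometry — not
that the pipeline's clinical numbers would reproduce on real data. In
particular the cross-validated AUC ladder on synthetic cohorts depends
entirely on the planted signal-to-noise and is not calibrated to match any
published cohort's values.

Regional windows are raised-cosine in the cup's spherical coordinates
(superior: polar cone of 40°; posterior: azimuth band of ±50° about the
posterior direction at mid-polar angles) — regions are described
anatomically in the literature, not in coordinates, so the windows are this
package's parameterisation.

## Registration and the canonical surface

All hips (left hips first mirrored through the sagittal plane with winding
flipped, [mirror_hip()]) are registered canonical-to-subject: similarity ICP
with closed-form Procrustes updates, then an interpolating 3D thin plate
spline (kernel $|r|$) whose control points are rim correspondences plus a
farthest-point subsample of 200 interior vertices ([register_hip()]). The
rim is the boundary loop of the open mesh; source rim points are sampled at
equal arc length and paired with their closest points on the target rim
polyline. Three warp passes re-derive correspondences from the warped
positions, and a final tangent-plane projection settles the vertices onto
the subject surface. Displacement vectors from canonical vertices to their
final positions are the SSM input.

ICP begins with centroid/spread alignment and a dense azimuth scan about the
cup axis: a cup is nearly a surface of revolution, so azimuthal local minima
are the dominant failure mode and are worth paying for up front. The
canonical template ([canonical_surface()], ~2,300 vertices) carries a fixed
low-order radial asymmetry for exactly this reason — a perfect surface of
revolution would make rotation recovery ill-posed.

Correspondence under closest-point matching is inherently ill-posed against
tangential sliding (a known limitation of this family of registrations), so
registration accuracy is quantified as point-to-plane distance from the
warped canonical vertices to the target surface; known similarity and
thin-plate-spline warps of the template are recovered to well below 0.1 mm
RMS by this measure, and similarity parameters themselves to ~1e-3 relative.

## Shape model and mode retention

The SSM is a PCA (thin SVD) of the mean-centred per-hip displacement fields
([build_shape_model()]): orthonormal modes, descending variances, per-hip
coefficients SM1…SMK, with signs fixed by making each mode's
largest-magnitude loading positive so that coefficient directions are
reproducible. PCA is on raw per-hip displacements (no vertex-area
weighting, no individual averaging) — averaging the two hips happens at the
analysis stage, where clustering matters.

Retention uses Horn's parallel analysis ([horns_parallel_analysis()]):
eigenvalues are compared with the 95th percentile of eigenvalues of
column-wise independently permuted data; modes are retained from the first
until one falls below its threshold. Under the generator defaults the
planted rank of 16 is retained in well over 90 % of replicates at the
validation mesh (~170 vertices, 530 hips, 100 permutations).

Visualisation helpers give the ±3 SD mode point clouds ([mode_point_cloud()])
and group mean shapes with displacement vectors exaggerated ×3
([group_mean_shape()]).

## Association: GEE with the 1/(1+R) pairing adjustment

Two hips from one individual are not independent. The association stage
([gee_odds_ratios()]) fits a logit-link GEE with exchangeable working
correlation, clusters = individuals, robust sandwich standard errors with
the small-sample factor $m/(m-p)$, and covariates age and BMI (sex excluded
by default because it is collinear with the scale mode; `include_sex`
re-adds it). Odds ratios are reported per *adjusted* SD of each mode
coefficient: each hip is weighted $1/(1+R)$, where $R$ is the left–right
correlation of that coefficient within individuals, giving the effective
sample size $n_{eff} = n/(1+R)$ and

$$\mathrm{adjusted\ SD} = \sqrt{\frac{\sum_i (x_i - \bar x)^2}{n_{eff} - 1}}.$$

This is the package's explicit reading of the pairing adjustment: duplicated
hips ($R = 1$) count once, independent hips ($R = 0$) count fully.
Significance uses a Bonferroni factor of 18 (16 modes plus age and BMI), so
the threshold is 0.05/18 < 0.003. Because the adjusted SD is a data-estimated
scale, confidence intervals on that scale absorb a small extra variance; the
coverage validation therefore plants its effect at R = 0, where the adjusted
and raw SDs coincide and the planted odds ratio is exactly the estimand.

## Surface SPM with random field theory

The SPM stage ([spm_jsw()]) averages paired maps and coefficients per
individual, smooths the maps (default FWHM 5 mm), and fits at every vertex
the linear model `JSW ~ 1 + THR + SM1 + … + SM7`, confounding on the leading
shape modes to absorb systematic registration bias; age and BMI are excluded
by default (they do not alter results; a flag re-adds them). The THR term is
tested with a partial F test; familywise correction is peak-level RFT: the
corrected p-value is the expected Euler characteristic of the F excursion,
$\sum_d R_d \rho_d(F)$, with resel counts $R_0 = \chi$ (Euler characteristic
of the mesh) and $R_1, R_2$ accumulated *locally*: residual roughness
$\lambda$ is estimated per edge from normalised-residual differences, each
face contributes $\mathrm{area}_f \bar\lambda_f / (4\log 2)$ to $R_2$ and each
boundary edge the analogous length term to $R_1$. Local accumulation matters
because smoothness on a real mesh is not stationary (vertex density and
smoothing reach vary over the cap); a single global FWHM overstated the
resel count by ~70 % in our null calibrations and made the correction
needlessly conservative. The global summary
$\mathrm{FWHM} = \sqrt{4\log 2/\bar\lambda}$ is still reported. Corrected p is clamped
to at least the uncorrected p, so a single-vertex mesh degenerates to the
ordinary F test. Cluster-extent inference is not provided; peak-level
inference is the criterion throughout, and a Freedman–Lane-style
permutation max-F backend ([permutation_max_f()]) ships as the nonparametric
reference.

Numerical notes: RFT peak inference on a discretely sampled surface is
mildly conservative (measured null FWER ≈ 0.02–0.03 at nominal 0.05); the
null calibration smooths to ~3× the mesh edge length, the regime the
continuous-field theory assumes. Side-difference maps (replaced hip minus
opposite; seeded-random side for bilateral cases and controls,
[side_difference_map()]) run through the same machinery
([side_difference_spm()]).

## Prediction

[min3d_feature()] is the single 3D severity parameter: minimum JSW within
the SPM-significant ROI divided by the global mean JSW. The ROI is frozen
from the full-sample SPM — as the source analyses do — which is an optimism
source worth remembering; [loo_cv_scores()] with a nested ROI would be the
honest alternative when that matters. The classifier is plain logistic
regression (KL entered as a single ordinal numeric); leave-one-out scores
omit the fold intercept, which under LOO carries a pure class-imbalance
artifact that drags pooled null AUC below 0.5. Even so, pooled LOO AUC
retains a small pessimistic bias at modest n; at n = 1000 it matches the
closed-form binormal value $\Phi(d/\sqrt2)$ to better than 0.01, which is
where the calibration checks run. AUC is the midrank Mann–Whitney statistic
([roc_auc()]); [model_comparison_report()] evaluates the standard feature
ladder (HP, KL, min2D, SM, min3D, 3D combined, 3D + KL) and reports each
model's percent improvement over the min2D baseline,
`round(100 * (auc - auc_base) / auc_base)`.

## Validation problem sizes

The test-suite and acceptance-script problem sizes are the package's
standard validation settings: phantom sweep of 36 conditions × 3 profiles;
50 profiles against the 0.01 mm grid oracle; full-resolution (~2,300-vertex)
canonical template for registration; ~170-vertex mesh, 530 hips and 100
permutations × 100 replicates for parallel-analysis retention; 500
replicates for GEE coverage; ~500-vertex surface and 500 null replicates
(200 with a 99-permutation max-F reference) for SPM error control; n = 1000
for ROC calibration. Larger sizes change none of the conclusions; these are
the smallest at which the Monte-Carlo bands in the tests are meaningful.

## Known limitations

* Hemispherical synthetic geometry: no aspherical deformity, no osteophytes,
  no segmentation error; patch extraction and registration are exercised on
  idealised cups.
* The measurement model assumes a locally constant cortical density and a
  Gaussian, spatially invariant PSF; real scanners violate both mildly.
* Identifiability of sub-PSF gaps leans on the physical priors described
  above; profiles violating them (e.g. dense loose bodies in the joint
  space) would bias the fit.
* Correspondence across subjects is defined by the registration, which is
  ill-posed; different registration choices could shift mode definitions
  and, with them, shape-mode associations.
* The GEE working correlation is exchangeable; misspecification costs
  efficiency, not validity (robust errors are used throughout).
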