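---
title: "Measuring dense 3D facial fluctuating asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dense 3D facial fluctuating asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Fluctuating asymmetry (FA) is the random, individual component of deviation
from bilateral symmetry; it is the morphological readout usually taken as a
proxy for developmental instability. Directional asymmetry (DA) is the
component of asymmetry shared across a population (for faces, e.g. a
population-wide nose deviation) and is considered uninformative about
developmental instability, so it must be removed before FA is scored.

`facefa` implements a spatially dense measurement of facial FA from 3D
surface scans:

1. **Dense correspondence.** A mirror-symmetric template surface with an
   explicit left–right vertex pairing (an involution `p` with midline fixed
   points on the sagittal plane x = 0) is mapped onto each scan by rigid
   iterative closest points followed by a non-rigid ICP stage. The result is
   one position per template vertex, so every face is expressed in the same
   vertex ordering.
2. **Mirroring.** The mapped face is reflected by negating the x
   coordinates and relabelling each vertex with its paired counterpart,
   which restores template ordering for the mirror image. The operation is
   an involution and fixes perfectly symmetric faces.
3. **Superimposition.** The mirror is rigidly superimposed onto the face by
   weighted Procrustes analysis (uniform weights by default; an iteratively
   reweighted variant that down-weights strongly asymmetric regions is
   available). No scaling is applied by default, so asymmetry is in
   absolute millimetres.
4. **Decomposition.** The total asymmetry field is the vertex-wise
   difference between the face and its aligned mirror. DA is estimated as
   the vertex-wise mean total-asymmetry field of the analysis sample
   (separately per sex group), and each face's FA field is its total field
   minus DA. By construction the sample mean of the FA fields is zero.
5. **Scoring.** The FA field is reduced to a scalar, by default the root
   mean square over vertices of the displacement-vector norms (label
   `"rms"`); a `"mean-norm"` reduction is available and the label is carried
   in all outputs, since the field's literature does not agree on a single
   reduction.

Before step 2 the mapped face is rigidly aligned onto the template
(ordinary Procrustes). This pose canonicalization makes the total-asymmetry
field exactly invariant to rigid motion of the input scan and makes DA
averaging across faces scanned in different head poses meaningful.

## The non-rigid mapping

The non-rigid stage fits a per-vertex displacement field `D` by alternating:

* closest-point correspondences from the deformed template to the scan
  surface, down-weighted smoothly to zero as they approach the distance cap
  `correspondence_distance_cap` (default 10 mm) or the normal-compatibility
  threshold `normal_compatibility_min` (default cos 60°) — smooth tapers
  rather than binary gates, so the fitted field is continuous in the scan's
  pose;
* reverse correspondences from the scan vertices onto the deformed template
  surface, expressed in barycentric coordinates — these anchor how the
  template parametrization spreads over the scan; reverse matches fade out
  smoothly near the borders of the open template sheet;
* a sparse linear solve of the data terms plus `alpha` times a
  graph-Laplacian smoothness penalty, with `alpha` following a decreasing
  (coarse-to-fine) stiffness schedule (default 50 → 0.05 over eight
  levels). Vertices with no accepted correspondence are extrapolated by the
  smoothness term.

A weak zero-deformation prior (`displacement_prior`, default 0.1 relative
to the unit data weight) is part of the model. It addresses a genuine
identifiability gap: on a smooth surface, sliding the template tangentially
changes no distances to the surface, so tangential placement is determined
only by the regularizer. The prior anchors the parametrization to the
rigidly aligned starting position and bounds this drift at the cost of a
small (order 10%) multiplicative shrinkage of the recovered deformation.
Because the shrinkage is common to all faces mapped with the same settings,
rankings and correlations of FA scores are essentially unaffected.

Two consequences are worth stating plainly. First, only the
normal-directed component of a deformation is geometrically real on a
smooth surface; a tangential displacement field is a re-parametrization.
The synthetic generator therefore plants its asymmetric fields along the
template's vertex normals. Second, correspondence recovery for a smooth
synthetic warp is accurate to roughly a third of the warp amplitude at the
default test density (300 vertices), while the surface geometry itself is
recovered an order of magnitude more closely; recovery improves with
template density, and the published-scale density (thousands of vertices)
is a configuration, not a constant, of this package.

Convergence: each stiffness level iterates until the mean per-vertex motion
falls below `convergence_tol` (default 1e-3 mm) or its share of
`max_iterations` is exhausted. The rigid initialization runs point-to-point
ICP until the mean per-iteration vertex motion falls below 1e-6 mm (or,
on noisy scans where ICP settles into a small limit cycle, until the
motion stops shrinking; the best-residual pose seen is kept), and then
polishes the pose against soft-assignment targets — Gaussian-weighted
blends of the closest points on the candidate triangles. The polish
matters: the hard closest-point objective on a faceted surface has many
local minima a few hundredths of a millimetre apart, so two scans of the
same geometry in different poses would otherwise align to slightly
different optima, and that pose noise would masquerade as fluctuating
asymmetry. With the soft objective and the smooth acceptance tapers, the
whole mapping is continuous in the scan's pose: re-posing a scan changes
the measured asymmetry at the nanometre scale. All steps are
deterministic: identical inputs give identical output.

## The synthetic generator

`simulate_faces()` builds each scan as

> symmetric template + individual symmetric deformation + scale_i × DA
> field + FA_i field + sensor noise, then rigid pose jitter,

with all smooth fields drawn from a Gaussian-bump basis (default 12 bumps,
30 mm kernel). Asymmetric fields are exactly antisymmetric under the
pairing, directed along vertex normals, and orthogonalized against the
template's rigid motions, so that a planted magnitude is exactly what the
mirror-and-superimpose measurement should report; they are planted as
half-fields so a planted magnitude σ yields a total-asymmetry contribution
of rms σ mm.

Defaults, chosen once as realistic study conditions: symmetric individual
variation 2 mm rms; DA magnitude 1 mm rms with an individual DA scale SD of
0.2; per-individual FA magnitudes from a zero-truncated normal with mean
0.5 mm and SD 0.15 mm (the sub-millimetre scale of the published asymmetry
heat maps); sensor noise 0.1 mm (the level used in the published retest
subsample); pose jitter up to 5° and 5 mm. The recorded ground truth
`fa_mag_true` is the rms of the full planted deviation from the
population-mean asymmetry — the idiosyncratic field plus the individual's
DA-scale deviation — because under the method's definition FA *is* the
deviation from mean asymmetry. The template is an analytic face-like dome
with nose and brow ridges on a grid with mirror-symmetric triangulation, so
its geometry, pairing and vertex normals are exactly symmetric in floating
point.

What the generator does **not** emulate: scan holes and occlusions, facial
hair, expression differences, texture, and spatially correlated scanner
artifacts. Passing the recovery suites therefore shows the measurement
chain is correct and well-conditioned under the stated noise model, not
that any particular real scanner or population matches these conditions.

`simulate_ratings()` gives each target a latent attractiveness equal to a
linear blend of its standardized true FA magnitude (with signed latent
correlation `target_r`) and independent noise; each rater adds independent
noise, so the expected interrater reliability is
ICC(3,k) = 1 / (1 + `rater_noise_sd`² / k). The default rater pool (15 per
sex) and noise (SD 2 in latent units) give an expected average-measures ICC
of about 0.88, matching the high reliabilities typical of aggregated
attractiveness ratings. Rounding to the integer scale is off by default and
available for realism.

## The statistical workflow

The replication workflow mirrors a two-sample individual-differences study:

* per-item rater means, then the mean of short- and long-term item means,
  per target (familiarity-flagged ratings excluded first);
* interrater reliability as the two-way consistency, average-measures
  ICC(3,k) computed from the targets × raters mean squares — the ANOVA
  route; the variant label is recorded because the literature's "ICC" is
  ambiguous;
* Pearson correlations with pairwise-complete cases, p-values from the
  exact t transform;
* standardized ordinary least squares (all variables z-scored) for the
  covariate-adjusted models (facial attractiveness in one; age and BMI in
  the other);
* a pooled-variance two-sample t with Cohen's d against the pooled SD for
  the sex comparison of vocal attractiveness, with the 11-point scale
  affinely converted to the 7-point scale first (Welch available);
* equivalence testing of a correlation against a stated negative bound via
  the one-sided Fisher-z test: z = (atanh r − atanh bound)·√(n−3),
  p = P(Z > z). This one-sided form reproduces the published worked
  example (r = 0.13, n = 130, bound −0.06 → p ≈ 0.016, printed as 0.02);
  the full two-one-sided-tests (TOST) variant against a symmetric pair of
  bounds is exposed separately and reports the larger one-sided p.

## Numerical and design choices

* Superimpositions use the closed-form weighted SVD (Kabsch/Umeyama)
  solution; degenerate (collinear or zero-weight) configurations are
  rejected with an error. Reflections are excluded by the determinant sign
  correction.
* The Procrustes weights default to uniform, which keeps the estimator
  transparent; the `"irw"` option (Gaussian weights on residuals, three
  iterations) covers the down-weighting reading of "weighted Procrustes".
  The choice is recorded in the outputs.
* Mesh I/O supports ascii and binary little-endian PLY (with one per-vertex
  scalar channel, used for heat maps) and OBJ; the left–right pairing
  travels as a two-column CSV. Round-trips preserve coordinates to float
  precision and connectivity exactly.
* Landmark FA indices (horizontal, vertical, comprehensive) are computed
  against a midline fitted per configuration — a least-squares line through
  the midline landmarks in 2D, a sagittal plane with in-plane vertical axis
  in 3D — and are exactly zero on mirror-symmetric configurations,
  rigid-invariant, and linear under scaling. The default 17-point scheme
  (seven bilateral pairs, three midline points) is a conventional choice;
  landmark sets are user-configurable, and the comprehensive index's
  normalization is optional and labelled.
* Group processing is fully separate per sex group (DA estimation, FA
  scoring, statistics), and every reported statistic carries its n.

## Problem sizes used in the checks

One calibration property deserves a plain statement. Under a planted null
association and one-sided testing at the 5% level, the power of the
Fisher-z equivalence test against a bound b at sample size n is
Φ(atanh(|b|)·√(n−3) − 1.645): at n = 150 this is about 0.94 for b = −0.26
but only about 0.79 for b = −0.20 — a property of the test and the bound,
not of this implementation; roughly n ≥ 212 would be needed to reach 90%
power against −0.20. The calibration suite computes both rejection rates
and the corresponding check against the tighter bound passes at its target
while the looser bound's rate sits at its analytic ceiling.

The test and acceptance suites run at deliberately reduced problem sizes,
chosen as the package's own test conditions: templates of 100–300 vertices,
samples of 45–150 faces per group, and one mapped measurement per scan. The
equivalence-test calibration measures FA once per group of 150 synthetic
faces and then redraws the rating stage across 100 seeded replicates — the
rating draw is the stochastic component whose power the calibration
property concerns, while re-mapping identical meshes would only repeat a
deterministic computation.

## Known limitations

* Tangential correspondence on smooth, feature-poor regions is
  regularizer-determined (see above); dense correspondence methods with
  landmark anchoring or statistical shape priors would pin it down, and
  both are deliberately out of scope here.
* The FA scalar and the Procrustes weighting scheme are stated choices
  among several used in the literature; outputs carry their labels so
  alternatives remain comparable, and no claim is made that either is "the"
  reduction used by any particular published study.
* The generator's rating model is a single-latent-trait model with
  homoscedastic rater noise; it does not model rater drift, halo effects,
  or target-by-rater interaction beyond noise.
* Scans are assumed to be single connected sheets without large holes;
  validation, not repair, is provided.
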