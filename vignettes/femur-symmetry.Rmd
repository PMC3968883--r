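---
title: "Methods: shape-model based left-right symmetry analysis of the proximal femur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape-model based left-right symmetry analysis of the proximal femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femsym)
```

## The problem

On an AP pelvic radiograph the two proximal femurs are 2D projections of
3D anatomy, and the projection depends on how the subject was positioned:
pelvic rotation and internal/external leg rotation change the apparent
shape of the left and right femurs *in opposite directions*. Any
landmark-based comparison of the two sides therefore mixes true
anatomical asymmetry with positioning artefact. `femsym` quantifies
left-right proximal femur symmetry while explicitly identifying and
removing the oppositional part.

The package works on ordered 2D landmark contours: 65 points per femur
with fixed anatomical meaning per index (correspondence), combined into a
130-point configuration per subject in which row `i` and row `i + 65`
are the same anatomical location on the two sides. Coordinates are
assumed calibrated to millimetres, y-up (a `--y-down` import flag
converts image-convention files).

## The shape model

Each configuration is modelled as

$$x = T_\theta(\bar{x} + P b + r)$$

with $\bar{x}$ the mean in a common reference frame, $P$ orthonormal
modes from PCA of the Procrustes-aligned training shapes, $b$ the mode
coefficients, $r$ a residual, and $T_\theta$ a similarity transform.

**Alignment.** Generalized Procrustes analysis iterates full-similarity
alignment of every shape to the evolving mean. The common frame keeps
millimetre scale: the mean is re-normalised each iteration to centroid
zero and centroid size equal to the *mean centroid size of the inputs*,
because all downstream quantities (point-to-curve distances, adjustment
effects) are reported in mm. A consequence worth stating: the frame is a
function of the input sizes, so GPA output is invariant to per-shape
rotations and translations unconditionally, and to per-shape rescaling
only up to the change it induces in the mean centroid size. The frame
orientation is canonicalised intrinsically (major axis of the mean
vertical, positive y-skewness), so results do not depend on which input
happened to seed the iteration. Convergence tolerance is an RMS mean
change below 1e-10 mm with a 200-iteration cap (non-convergence warns,
never errors).

**PCA.** The decomposition uses the point-space covariance or its
shape-by-shape dual, whichever is smaller, with divisor $n-1$; retained
mode count $k$ is the smallest number whose cumulative variance reaches
the threshold (default 0.95, the conventional cut-off for separating
structured variation from landmarking noise). Eigenvalue ties are broken
by a stable descending sort, and each mode's sign is fixed so its
largest-magnitude loading is positive, making stored models reproducible
bit-for-bit. A zero-variance training set yields $k = 0$ rather than an
error.

**Fitting.** Fitting a new shape minimises
$\lVert T^{-1}(x) - (\bar{x} + P b)\rVert^2$ jointly over the similarity
and the coefficients. Because a 2D similarity is linear in
$(s\cos\theta, s\sin\theta, t_x, t_y)$, this is solved as one linear
least-squares problem. We initially used the classical alternation
(pose step, projection step, fixed iteration cap) and abandoned it: in a
millimetre-preserving frame, size variation is genuine shape variation,
so the scaling direction lies largely inside the retained mode span and
the alternation's two blocks become nearly collinear — coordinate descent
then stalls short of the optimum at any fixed cap. The closed form is
exact, and makes the residual orthogonal to the modes by construction.
Degenerate inputs (coincident points, rank-deficient design) raise
errors. Note the $(pose, b)$ split is only identifiable when the modes do
not span similarity directions, i.e. for models built on aligned shapes —
which is how the package builds them.

## Oppositional modes and the positioning adjustment

For a combined-model mode, split its displacement field into left and
right halves, mirror the right half into the left anatomical frame
(negate x; indices already correspond), and take the cosine similarity
of the two 130-dimensional vectors. Shared-anatomy variation scores near
+1; positioning artefacts, which move the sides in opposite directions,
score near −1. Classification uses symmetric/oppositional thresholds of
+0.7/−0.7: scale-free, sign-stable (the score is invariant to the
arbitrary sign of a mode), and a reasonable quantitative reading of
"clearly attributable" — the identification is usually done visually, and
the cosine rule is this package's formalisation of it, not a published
criterion.

The mirroring convention requires the model frame's mirror axis to be
vertical, so `build_combined_model()` aligns the side-swapped reflection
of the mean onto the mean and splits the rotation difference.

**Symmetry-adapted refinement.** PCA eigenvectors are arbitrary within
(near-)degenerate eigenspaces, and sample eigenvalue repulsion hides the
degeneracy: when an artefact mode and an anatomy mode have similar
population variances, their sample modes are an arbitrary rotation of the
pair, and the cosine score of both is smeared towards 0. Under the
bilateral model the population covariance commutes with the mirror-swap
operator $M$, so population eigenvectors can be chosen as eigenvectors of
$M$ (scores exactly ±1). `symmetry_refine_modes()` therefore examines
each adjacent retained pair, diagonalises the restriction of $M$ to its
2D subspace, and rotates the pair **only** when that restriction has
eigenvalues within 0.2 of +1 and −1 — the certificate that the subspace
genuinely contains one mirror-symmetric and one oppositional direction.
Pure pairs pass through unchanged (the rotation is the identity) and
noise subspaces fail the certificate, so the refinement cannot invent
oppositional structure; this is verified by property tests on
artefact-free data. The refinement assumes anatomy varies symmetrically;
a true *directional* asymmetry of anatomy sharing a subspace with an
artefact mode would be attributed to the artefact. That is the same
assumption the visual identification makes, and it is the reason the
classification should be reviewed (`classify_modes()` output is written
to every run directory) rather than trusted blindly.

**Adjustment.** Excluding a mode zeroes its entry in each subject's $b$
and re-evaluates all 130 points with the original pose and residual
retained, so exactly the targeted mode's contribution is removed and
nothing else. The adjustment effect is the mean point-to-curve distance
between original and re-evaluated points after similarity alignment,
evaluated per femur segment (never across the gap between femurs), and
one-directional by default (adjusted points against the original curve).

## Symmetry statistics

The single 65-point model pools the left femur and the mirrored right
femur of every subject (any vertical mirror axis is equivalent up to the
subsequent alignment; the implementation uses each femur's centroid).
GPA is re-run independently for the before- and after-adjustment models,
so the two reports differ only through the excluded modes. Per-subject
left-right difference is the mean point-to-curve distance of the 65 left
landmarks against the aligned mirrored-right polyline — in the left
femur's mm scale. Per-mode statistics are two-sided Welch t-tests
(unequal variances, Welch–Satterthwaite df) of left vs right
coefficients, with per-group Kolmogorov–Smirnov normality checks
(estimated parameters, so the Lilliefors caveat applies: the reported KS
p-values are conservative) and Bonferroni control at
`family_alpha / k` — for 12 retained modes at family $\alpha = 0.05$ the
per-mode threshold rounds to 0.004. Subjects missing a side are excluded
from paired statistics and counted in the report.

A caution that shaped the test design: a two-sample Welch test on paired
data with *shared* anatomy is conservative, not calibrated, because the
sides are positively correlated. The calibration property test therefore
uses a null configuration whose sides are genuinely independent (all
anatomy and positioning SDs zero, per-point noise only); exchangeability
alone would not be enough.

## Hip geometry

The four conventional measurements are concrete constructions configured
by an `index_map` (the 65-point scheme's anatomical semantics are not
standardised, so the region indices are data, not code):

* **head diameter** — algebraic least-squares (Kasa) circle through the
  head landmarks; exact on exact circles, collinear input errors.
* **neck width** — minimum distance between the superior and inferior
  neck border polylines measured perpendicular to the neck axis; the
  axis runs from the fitted head centre through the midpoint of the
  narrowest crossing and is found by fixed-point iteration (seeded from
  the `neck_axis_anchor` landmarks, 12 iterations, 400-sample width
  grid).
* **shaft width** — mean perpendicular distance between the paired
  medial/lateral border points relative to the total-least-squares shaft
  axis through the border midpoints.
* **neck-shaft angle** — angle between the neck axis (towards the head)
  and the distally directed shaft axis, reported in the anatomical
  obtuse convention.

All four are rigid-invariant; lengths are scale-covariant and the angle
scale-invariant (property-tested). Paired asymmetry uses
$AD = |m_l - m_r|$ and $AA\% = |m_l - m_r|/\mu \times 100$ with
$\mu$ the pairwise mean; cohort summaries report mean ± SD with
normal-approximation 95% CIs ($\pm 1.96\,SD/\sqrt{n}$, adequate at
cohort sizes in the hundreds and stated as such for small demos).

## The synthetic generator

`generate_dataset()` emulates exactly the structure the analysis
assumes; it is the package's study population, and its defaults are the
declared study conditions:

* **Template.** A deterministic 65-point left femur built from a
  circular head arc, concave (parabolic) neck borders and parallel shaft
  borders — no trochanters. Default dimensions are adult-female cohort
  means: head diameter 51.6 mm, neck width 35.3 mm, shaft width 37.0 mm,
  neck-shaft angle 126.7°. Secondary proportions (neck length 1.15 × head
  radius, neck-shaft offset `1.4 × shaft_width / (2 cos(angle − 90°))`,
  flare `0.2 (r − w/2)/L²`) scale with the primary dimensions so the
  construction stays valid across the sampled anatomy range; the
  construction guarantees the head landmarks lie exactly on the circle
  and the isthmus is sampled exactly, so `measure_hip()` recovers the
  parameters.
* **Anatomy.** Per subject one shared draw: head radius SD 1.7 mm, neck
  width SD 2.9 mm, shaft width SD 3.2 mm, neck-shaft angle SD 5.8°
  (cohort-scale SDs), log-normal global size SD 0.03. The right femur is
  the exact mirror before noise.
* **Left-right noise.** Independent N(0, 0.3 mm) per point and
  coordinate on each side — the anatomical noise floor.
* **Pelvic rotation.** One angle ρ ~ N(0, 3°) rotates *both* femurs by
  the same image-frame angle about their own centroids. Relative to the
  mirror relation this is oppositional (the mirrored right field is the
  negated left field), which is what the combined model detects. A pure
  in-plane rotation, however, is invisible to any per-femur
  similarity-aligned metric, so the generator also applies the
  first-order projective consequence of the 3D rotation: an apparent
  neck-shaft-angle change of `projection_coupling` (default 1°/°) with
  opposite signs on the two sides, implemented as a smooth bend of the
  head/neck block about the isthmus, tapered to zero at the shaft
  junction. Without this coupling the rotation artefact would be pose,
  not shape, and adjusting for it could not reduce the left-right
  distance — the projective component is precisely why positioning
  matters in practice.
* **Shaft sliding.** With prevalence 0.2 (and probability 0.3 of being
  bilateral, with independent offsets), shaft landmarks are
  re-parameterised along their border by a N(0, 2 mm) arc-length offset,
  clamped to the border extent: the silhouette is exactly unchanged,
  only the correspondence moves — the landmarking failure mode seen when
  the lesser trochanter is obscured.
* **Pose.** Per image: rotation N(0, 2°), translation N(0, 5 mm),
  log-normal scale SD 0.02, anchored at the fixed midline so the pose is
  an imaging transform independent of the artefacts.

Randomness comes from one stream per subject derived from
`(seed, subject index)` — datasets are byte-stable under changes of
`n_subjects`, and all draws are standard normals scaled afterwards so
zero-SD configurations consume the stream identically (needed for
matched with/without-artefact comparisons).

**What the generator does not emulate:** real silhouettes (the template
is piecewise-analytic and has no trochanters), correlated anatomy (the
four dimensions are drawn independently; real cohorts have strong
covariance structure), genuine directional asymmetry, segmentation
failures, and any true 3D projection physics beyond the first-order
angle coupling. Passing recovery tests on this generator shows the
*pipeline* is correct and calibrated under its stated assumptions — it
does not show that real radiographic asymmetry decomposes this cleanly.

## Numerical and design choices

* Point-to-curve distance is the exact point-to-segment minimum over the
  open polyline (no closing segment, clamped feet at the open ends),
  validated against a dense-sampling oracle to 1e-3 mm. It can only be
  ≤ the corresponding-landmark distance.
* The `.pts` format prints 6 decimal places; read/write round-trips are
  lossless at that precision. Model files (`ssm-v1`) store 17 significant
  digits and round-trip exactly.
* Mode exclusion is available both manually (`exclude = c(3, 6)` style)
  and automatically via the cosine classification; the pipeline default
  is automatic, and every run writes the score table for review.
* Test and demonstration problem sizes (tens to 200 subjects, 500
  calibration replicates at 30 subjects) were chosen as the smallest
  sizes at which the recovery and calibration properties are
  statistically meaningful.
* The paired geometric comparison after adjustment shows the
  neck-shaft-angle AD collapsing toward the noise level while shaft
  width is untouched — consistent with the generator: the angle artefact
  is projective (shape), the slide artefact is correspondence-only
  (silhouette-invariant). Head diameter AD can *increase* slightly after
  adjustment: exclusion removes each subject's noise projection on the
  excluded mode too, perturbing the head region by a fraction of a
  millimetre.

## Limitations

2D only — no 3D reconstruction, no estimation of actual rotation angles
from projections, and the sagittal plane is not corrected. The
measurement constructions (minimum neck width, fixed-level shaft width)
are declared substitutes for unpublished operational definitions and are
configurable through `index_map`. The oppositional threshold −0.7 is a
design constant, not an estimated quantity; borderline modes land in an
explicit `indeterminate` class rather than being silently excluded.

```{r example, eval = FALSE}
cfg <- synthetic_config(n_subjects = 100, seed = 1)
res <- run_full_analysis("run1", synthetic = cfg)
res$adjustment$mode_scores
res$report_before$mean_lr_distance
res$report_after$mean_lr_distance
```
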