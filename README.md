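# femsym

Bilateral symmetry analysis of proximal femur shape from calibrated 2D
landmark contours.

In total hip arthroplasty and related planning tasks, the contralateral
femur is often used as a template for the diseased side — which is only
justified if left and right proximal femurs are in fact symmetric. Testing
that on AP pelvic radiographs is confounded by *subject positioning*:
pelvic and leg rotation change the projected 2D shape of the two femurs in
opposite directions, so apparent asymmetry can be an acquisition artefact
rather than anatomy. `femsym` implements a statistical-shape-model
workflow that separates the two:

1. **Combined model.** Each subject contributes a 130-point configuration
   (65 ordered landmarks per femur, indices in anatomical
   correspondence). After generalized Procrustes alignment, a point
   distribution model is built:

   `x = T_theta( x_bar + P b + r )`

   where `x_bar` is the mean configuration, `P` the orthonormal PCA modes
   retaining 95% of the variance, `b` the per-subject mode coefficients,
   `r` a small residual and `T_theta` a similarity transform.

2. **Oppositional-mode detection.** For each retained mode the left and
   right halves of its displacement field are compared after mirroring
   the right half into the left anatomical frame; the cosine similarity
   scores +1 for mirror-symmetric variation (shared anatomy) and −1 for
   *oppositional* variation — the signature of positioning artefacts.
   Modes scoring ≤ −0.7 are classified oppositional. Because PCA is
   unidentifiable inside near-degenerate eigenvalue pairs, a
   symmetry-adapted refinement first rotates any mixed pair whose
   subspace genuinely contains one mirror-symmetric and one oppositional
   direction.

3. **Adjustment.** Oppositional modes are zeroed in every subject's `b`
   (pose and residual kept) and all 130 points are re-evaluated.

4. **Symmetry quantification.** Single 65-point models (all femurs
   mirrored to left) are built before and after adjustment; left–right
   shape difference is the mean point-to-curve distance between a
   subject's left landmarks and the aligned mirrored-right contour
   polyline, and per-mode Welch t-tests (with Bonferroni correction and
   KS normality checks) compare left vs right coefficients.

5. **Hip geometry.** Head diameter (least-squares circle), minimal neck
   width, shaft width, and the anatomical neck-shaft angle are computed
   per femur, with the paired statistics `AD = |m_l − m_r|` and the
   absolute percent asymmetry `AA% = |m_l − m_r| / mu × 100`,
   `mu = (m_l + m_r)/2`.

Because the radiograph cohorts behind this kind of analysis are not
redistributable, the package ships a first-class synthetic generator
(`synthetic_config()` / `generate_dataset()`) that emulates shared
bilateral anatomy, mirror correspondence, independent per-point noise,
oppositional pelvic rotation with its projective neck-shaft-angle
consequence, and shaft-sliding correspondence error — with a per-subject
ground-truth log for recovery experiments.

## Worked example

```r
library(femsym)
cfg <- synthetic_config(n_subjects = 50, seed = 42)
res <- run_full_analysis("demo_run", synthetic = cfg)
#> [input] 50 subjects
#> [combined_model] 4 modes reach 95% of variance
#> [adjust] excluded mode(s): 2; mean effect 1.32 mm
#> [symmetry] mean left-right distance 0.73 mm before, 0.38 mm after

res$adjustment$mode_scores
#>   mode_index score classification variance variance_fraction
#> 1          1     1      symmetric     1837             0.468
#> 2          2    -1   oppositional     1266             0.323
#> 3          3     1      symmetric      339             0.086
#> 4          4     1      symmetric      289             0.074
```

Mode 2 is flagged oppositional (score −1): it carries the injected
positioning artefact. Re-evaluating all points without it moves landmarks
by 1.32 mm on average (the adjustment effect), and the mean left–right
point-to-curve distance drops from 0.73 mm to 0.38 mm — the residual is
the independent per-point noise floor plus small artefact leakage, i.e.
the apparent asymmetry was largely positioning, not anatomy.

The geometric measurements tell the same story:

```r
res$geometry$comparison
#>        measurement ad_mean_before ad_mean_after paired_t  p_value
#> 1    head_diameter          0.168         0.599   -4.396 5.92e-05
#> 2       neck_width          0.365         0.420   -1.209 2.33e-01
#> 3      shaft_width          0.140         0.139    0.693 4.92e-01
#> 4 neck_shaft_angle          4.885         0.812    7.120 4.33e-09
```

The mean absolute left–right difference in neck-shaft angle falls from
4.9° to 0.8° after adjustment (the artefact acts on the projected angle),
while shaft width — silhouette-invariant under the injected artefacts —
is unchanged.

A thin command-line front end with verbs `simulate`, `build-model`,
`adjust`, `symmetry`, `geometry` and `run-all` is installed at
`inst/cli/femsym.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/femsym.R", package="femsym"))')" \
  run-all --simulate-n 100 --seed 1 --out run1
```

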