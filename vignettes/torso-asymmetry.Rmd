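---
title: "Quantifying torso cross-section asymmetry from 3D surface scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying torso cross-section asymmetry from 3D surface scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsometry)
```

## The problem

Scoliosis — a three-dimensional spinal deformity with at least 10° of
lateral curvature plus axial vertebral rotation — is monitored through
repeated X-rays, which accumulate ionizing dose in growing patients. The
deformity, however, leaves visible signatures on the torso *surface*: a rib
hump on the convex side of a thoracic curve, waist asymmetry for lumbar
curves. `torsometry` quantifies those surface signatures from a radiation-free
3D body scan, so that follow-up examinations can track deformity progression
between X-rays.

The method analyzes transverse (horizontal) cross-sections of a closed torso
surface mesh, one per vertebral level from C7 down to L5, each slice
independently of all others. Because every level is scored on its own,
results are insensitive to the patient's longitudinal growth between scans.

## The per-slice procedure

Each slice is an ordered closed contour in the transverse plane. The chain
of operations is:

1. **Centroid** — the arithmetic mean of the contour points (the contour is
   what the scanner measures, so its point density is the natural
   weighting). The contour is translated so the centroid is the origin.
2. **Polar conversion** — points become $(r_i, \theta_i)$ pairs sorted by
   polar angle, turning shape analysis into the analysis of a radius
   function $r(\theta)$. This requires the contour to be star-shaped about
   the centroid; where it is not, the outer silhouette (largest radius per
   1° bin) is kept and a warning recorded.
3. **Spinous-process (SP) detection** — the skin landmark over the spinous
   processes is a characteristic dip in the posterior contour, found as the
   radius minimum within the posterior 120° sector.
4. **Two-step alignment** — first the maximal diameter through the centroid
   (the angle maximizing $r(\theta) + r(\theta + 180°)$ on a 1° grid) is
   made horizontal; then a fine-tuning rotation places the SP directly
   below the centroid. A fine-tune beyond 45° flags a disagreement between
   the SP and the principal direction.
5. **Angular resampling** — radii are linearly interpolated onto the exact
   grid $\theta = 0°, \pm1°, \dots, \pm180°$ of signed offsets from the SP
   (positive offsets sweep the right body side, negative the left).

On the aligned grid, three kinds of parameters are computed.

**Relative radius and the left–right fit.** Radii are normalized by the
mean contour radius $r_m$ and scaled to percent, $RR(\theta) = 100\,
r(\theta)/r_m$, making all parameters scale-free. The right branch
$RR^{right}_i$ ($\theta = 0..180°$) and left branch $RR^{left}_i$
($\theta = 0..-180°$) are paired by equal absolute offset; for a perfectly
symmetric slice every pair satisfies $RR^{right}_i = RR^{left}_i$, i.e. the
points lie on the line $y = x$. An ordinary least-squares line is fitted to
the pairs and its coefficient of determination

$$R^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2}$$

quantifies how tightly the slice respects bilateral symmetry (1 = perfect).
$R^2$ is computed about the *fitted* line: the fitted slopes away from 1 are
themselves reported as deformity indicators, which is only meaningful if
the fit is free to find them. The residual measure about the identity line
$y = x$ is additionally exposed as `r_squared_identity` for diagnostics;
unlike the OLS $R^2$ it is not bounded below by 0.

**Fan areas and area asymmetries.** The area enclosed between the contour
and the centroid over any angular sector is a sum of triangles — the
centroid plus two consecutive grid points — each contributing
$\tfrac12 r_i r_{i+1} \sin 1°$. The left and right half areas $LA$ and $RA$
give the left–right area asymmetry $|LA - RA|/(LA + RA) \in [0, 1]$, zero
iff the halves balance. The same construction restricted to the backside
segments between the SP and two anchors at $\pm 70°$ (BLSP/BRSP, the
separation is configurable) gives the backside area asymmetry, which is
more specific to rib-hump prominence.

**Vertebral-body line and Dist_VB.** A proxy for the vertebral-body center
is placed on the SP–centroid axis, a configurable spinous-process length
(default 40 mm) anterior of the SP surface point. The vertical distances
from the horizontal line through that point down to the backside contour
points, indexed by offset from the SP, profile the prominence of each back
side; a rib hump shows as one side's profile riding above the other.

Per-torso summaries are arithmetic means of the three parameters over all
processed levels and over a configured apex region. The apex region is an
operator input: clinically it is chosen from the extent of the lateral
curvature, which surface data alone does not determine.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `separation` | 70 | deg | backside anchor offset from the SP |
| `sp_offset` | 40 | mm | assumed spinous-process length for the VB line |
| `sp_search` | (-150, -30) | deg | posterior sector searched for the SP dip |
| `sp_smooth` | 0 (off) | deg | moving-average pre-filter before SP detection |
| `apex_range` | empty | levels | apex region for the apex summary |
| `masks` | none | deg | per-level angular sectors removed (arm fragments) |

The 70° separation is the standard backside extent; the spinous-process
length is not measurable from the surface, so it is an explicit assumption —
40 mm is a plausible adult mid-thoracic value, and all Dist_VB profiles
shift rigidly with it, so comparisons between scans are unaffected by its
exact value. The SP search is restricted to the posterior 120° because a
global radius minimum could hit waist concavities at lumbar levels. For
noisy scans, setting `sp_smooth` to roughly twice the expected dip width
acts as a matched filter; in simulation at radial noise of 1% of the torso
radius it kept the detected SP within 1.5° of truth, versus up to 7.5°
unfiltered.

## Numerical choices

- **The 1° grid and the mean radius.** The angular grid runs
  $0°, \pm1°, \dots, \pm180°$ — 361 values of which the anterior point
  appears twice ($\pm180°$ is one physical direction). The mean radius is
  the arithmetic mean over all 361 grid values, which makes the
  normalization identity (mean $RR$ = 100) and the wraparound constraint
  $r(-180°) = r(+180°)$ hold exactly.
- **Sub-sample SP refinement.** The minimum-radius sample is refined by the
  vertex of the parabola through it and its two angular neighbours. Without
  it the detected angle hops in sampling quanta as the shape deforms
  continuously, which injects spurious steps into the severity response of
  downstream parameters; with it the full pipeline responds strictly
  monotonically to a growing rib hump.
- **Ties and degenerate cases.** Exact ties in the minimum search are broken
  toward the posterior midline; a flat minimum spanning more than 30° (a
  dipless, near-circular back) is flagged low-confidence and the posterior
  midline is used. A constant contour gives a zero-variance fit, returned
  as the perfect-symmetry convention (slope 1, $R^2 = 1$) with a warning.
  In the two-step alignment, tied maximal diameters (a circle) resolve to
  the diameter closest to horizontal, and the final orientation is fixed by
  the SP in any case.
- **Maximal diameter, not principal axis.** Step 1 of the alignment uses
  the maximal centroid-through diameter on the 1° grid, taken literally,
  rather than a principal-axis (inertia) fit. The two differ on strongly
  asymmetric slices; the diameter rule is discrete, deterministic, and
  cheap, and step 2 overrides the residual ambiguity.
- **Non-star contours** keep the largest radius per 1° bin — the outer
  silhouette is what a surface scanner sees; inward folds are scanner
  artifacts at this resolution.
- **Area triangles are unsigned**; star-shapedness about the centroid is
  enforced upstream, so unsigned and signed sums agree.
- **Level spacing.** Only C7, T8 and L5 are marked on a scan by the
  examiner. Intermediate levels are placed by equal spacing within each
  span (8 intervals C7–T8, 9 intervals T8–L5) — the simplest reproducible
  rule that honours all three landmarks exactly; true inter-vertebral
  spacing varies by a few percent, which displaces slices slightly along
  the axis but does not bias any per-slice parameter.
- **Arm removal** at lower thoracic levels is automated as configured
  angular masks about the centroid (replacing manual editing); masked gaps
  are bridged by linear chords and flagged, and masks covering 180° or more
  are rejected as unanalyzable.

## The synthetic torso generator

Patient scans are not distributable, so the generator is the package's
primary test instrument, not a fixture. A cross-section at level $l$ is

$$r(\theta) = \mathrm{se}(\theta; a, b, p) - d\, g(\theta - \theta_d; w_d)
 + h(l)\, g(\theta - \theta_h; w_h) + \varepsilon,$$

a superellipse base (defaults $a = 170$, $b = 120$ mm, exponent 2.5 — a
torso-like rounded box), a Gaussian posterior dip of depth $d$ emulating
the SP landmark, and one or more Gaussian rib-hump bumps whose amplitude
follows a Gaussian profile along the vertical axis peaking at a chosen apex
level ($h(l) = A\exp(-(l - l_{apex})^2 / 2\sigma^2)$, levels counted as
indices). Optional radial Gaussian noise is seeded and bit-reproducible.
Three presets ship: `healthy` (dip only), `thoracic_t8` (right hump, apex
T8, 18 mm ≈ 12% of the torso radius — a clearly visible single curve), and
`double_curve` (right T9 + left L2, the classic combined pattern). Preset
amplitudes are scenario choices, not fits to any patient.

Each generated contour carries ground truth: the true dip angle, hump side,
and left/right fan areas computed by quadrature at 0.01° resolution using
the same centroid-plus-dip-axis split as the pipeline. `generate_torso`
can also loft a watertight triangulated mesh through the continuous radius
model (rings every 5 mm, capped), so the mesh-slicing stage is exercised
end to end; slicing it back reproduces the generator contours to well
under 1% of the torso radius.

What the generator does *not* emulate: postural sway, breathing artifacts,
scanner holes and seams, skin-fold occlusions, and any quantitative link
between hump amplitude and the Cobb angle. Passing the synthetic suite
therefore demonstrates the correctness of the geometry and statistics, and
the qualitative behaviour (asymmetry parameters grow with severity, peak at
the apex, and $R^2$ falls) — not clinical accuracy on real scans.

One geometric caveat the tests respect: the SP is *defined* as the radius
minimum, so dip-center recovery is only well-posed where the two coincide.
On the superellipse base a shallow dip 20° off the midline does not move
the global minimum to itself (the base's own posterior minimum dominates —
errors up to ~20° are geometric fact, not detector failure). Recovery is
therefore verified for midline dips on the superellipse and for arbitrary
dips on a circular base, where the equivalence is exact.

## A worked run

```{r example}
tor <- generate_torso(preset_spec("thoracic_t8"))
rep <- run_assessment(tor, default_config(apex_range = c("T7", "T8", "T9")))
rep
head(rep$per_level[, c("level", "r_squared_full", "lr_area_asym",
                       "backside_area_asym")], 3)
rep$per_level$level[which.max(rep$per_level$lr_area_asym)]
```

The apex summaries exceed the whole-torso means and the most asymmetric
level is the generated apex, T8. Problem sizes throughout the package's own
test runs are 360 points per contour (720 where sub-degree detection
accuracy is probed), 18 levels per torso, and meshes of roughly 27k
vertices — a full 18-level run, including mesh slicing, completes in about
a second.

## Limitations

- Landmark heights (C7, T8, L5) are expert inputs; the package does not
  detect them on the mesh.
- The VB point is a fixed-offset proxy; actual vertebral-body position and
  rotation are not estimated.
- No mapping from surface asymmetry to the Cobb angle is attempted, and no
  cross-patient statistics are provided: the parameters are longitudinal,
  within-patient comparators.
- Slices that are not star-shaped about their centroid are silhouetted,
  which flattens deep folds; severely non-convex anatomies (e.g. extreme
  lordosis with skin folds) would need a different contour representation.
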