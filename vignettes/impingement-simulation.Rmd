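---
title: "Simulating ACL graft impingement: model, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ACL graft impingement: model, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aclimpinge)
```

## The model

The package treats graft impingement as a purely geometric quantity: the
Boolean overlap volume between the femoral bone solid and a virtual graft.
Three simplifications define the model, and all three are deliberate:

1. **The graft is a rigid straight cylinder** spanning the femoral and
   tibial footprint centres. Real grafts deform, bend over the notch
   margin, and are pretensioned; none of that is modelled. The overlap
   volume of the *rigid* cylinder is an upper-bound-style severity score,
   not a contact mechanics prediction.
2. **Bones are rigid watertight surfaces**; the knee pose is a rigid
   placement of the tibia relative to the femur at a prescribed flexion
   angle.
3. **Impingement is measured against the whole femoral solid**, not a
   pre-segmented "notch region". Overlap can only physically occur where
   the graft runs, i.e. inside the intercondylar notch and beneath its
   roof, so no region-of-interest definition is needed — and any such
   definition would be an extra arbitrary input.

Footprint positions are percentage coordinates in two reference frames:
the quadrant grid on the medial wall of the lateral femoral condyle (its
superior border runs through the highest point of the notch along the
notch-roof direction) and the bounding rectangle of the tibial plateau
outline in top view. Frames are fitted from named landmarks; for real
meshes these come from a JSON sidecar (manual annotation, as in clinical
planning software), for synthetic knees the generator emits them.

Two conventions deserve explicit mention because the field's prose is
ambiguous about both:

* **Femoral depth fractions are measured from the posterior border.**
  The operational definition of the quadrant grid measures the footprint
  depth from the posterior edge of the frame; some textual descriptions
  say "from anterior to posterior". The posterior convention is the
  default; `depth_from = "anterior"` mirrors the fraction for users whose
  coordinates follow the other reading.
* **The frame's depth axis is the primary orthonormalization axis**,
  taken along the notch-roof (Blumensaat) direction through the notch
  apex; the height axis is the in-plane perpendicular pointing
  inferiorly. This matches the quadrant-grid construction, in which the
  superior border *is* the roof line.

## The volume kernel

Exact mesh–mesh Booleans are fragile and unnecessary here: only the
intersection **volume** is needed. The kernel rasterizes both solids on a
common voxel lattice and counts centres inside both:

* **Common grid.** The lattice is anchored at the combined bounding-box
  minimum of the two solids, rounded down to a multiple of the spacing,
  and only the overlap region of the two boxes is evaluated. Anchoring
  makes `intersection_volume(a, b)` exactly symmetric; disjoint bounding
  boxes short-circuit to zero.
* **Inside test.** One ray per voxel column, crossing parity per column
  (a column-sweep over triangles, so cost scales with triangle count
  times covered columns, not with voxel count times triangles). A
  generalized winding-number test is also implemented; it is the slower,
  more robust formulation and serves as the independent cross-check — the
  test suite asserts voxel-for-voxel agreement of the two inside tests.
* **Tie-breaking.** All query points carry fixed, documented sub-voxel
  offsets (about `1e-4` of the spacing, different in x, y and z) so that
  centres never lie exactly on facet planes, edges or vertices of the
  axis-aligned synthetic geometry. This makes results deterministic and
  watertight-parity-safe at a volume perturbation far below the
  discretization error.
* **Spacing.** Default 0.5 mm. The measurement chain it feeds was
  validated to about 1 mm in the original planning software, and 0.5 mm
  keeps a full 9-knee × 72-cell battery in the tens of seconds. The
  closed-form oracles (cube/cube, cylinder/slab, sphere/cube) agree to
  better than 1 % at 0.25 mm, with monotone error reduction over
  spacings 1.0 → 0.5 → 0.25 mm; pass `spacing` explicitly for a
  convergence report on your own geometry.
* **STL input** merges duplicated facet vertices at 1e-6 mm (STL stores
  every facet's corners independently) and rejects non-watertight
  surfaces, naming the open-edge count.

## The attachment ambiguity

A straight cylinder that reaches its own femoral footprint necessarily
buries part of itself in the condyle wall around the insertion — for
typical geometry a sliver of tens to hundreds of mm³ that is *invariant
under flexion*. Published impingement volumes behave differently:
posterolateral cells are near zero and deep-flexion volumes are
negligible, which is only possible if insertion-site overlap is not
counted. How the original Boolean measurements excluded it is not
documented; this is the main reconstruction ambiguity of the method.

The package therefore exposes the exclusion policy explicitly
(`factorial_design(attachment_exclusion = ...)`):

* `"wall_plane"` (default): overlap is counted only on the notch side of
  the femoral-wall tangent plane through the footprint centre. This
  removes exactly the insertion sliver, leaves roof overlap untouched,
  and reproduces the expected zero at deep flexion by construction.
* `"cap"`: the probe is the graft truncated by `cap_depth` mm at each end
  (`attachment_exclusion_mask()`), for sensitivity analyses. With
  `cap_depth = 0` this is the full graft.
* `"none"`: count everything, insertion sliver included.

## The synthetic knee generator

The generator stands in for CT-reconstructed subjects. It is a stylized,
analytic geometry — controllability and closed-form ground truth are the
point, not anatomical fidelity:

* **Femur**: a block of two 24 mm-wide condylar slabs flanking a notch
  (default width 19 mm, height 25 mm) whose planar roof slopes
  anteriorly–inferiorly at `roof_angle` (default 40°), the synthetic
  Blumensaat surface. 24 vertices, 44 triangles, watertight by
  construction.
* **Tibia**: an elliptic plateau slab (default semi-axes 25 × 25 mm)
  whose centre sits `tibia_offset` = 14 mm anterior to the femoral
  centre. Together with the roof angle this encodes the full-extension
  pose in which the graft runs nearly parallel to the roof and slides
  under its anterior margin — the classical roof-impingement mechanism.
  These two defaults were tuned once so that the extension AM–AM
  configuration impinges strongly while PL–PL barely does; they are a
  calibration of the synthetic study conditions, not an anatomical claim.
* **Kinematics**: a fixed hinge about the transepicondylar axis. No
  femoral rollback, sliding or axial rotation.
* **Population sampling**: independent truncated Gaussians over the
  continuous parameters (notch width 19.0 ± 3.4 mm; smaller SDs for the
  other dimensions), rejection-resampled to feasibility, fully
  reproducible per seed.

Every emitted ground-truth quantity (frames, six footprint centres,
notch width, flexion axis) is recovered independently by the measurement
pipeline, and the tests enforce recovery to 1 mm (footprints) and 0.5 mm
(notch width) across seeded populations.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show about clinical data: curved condylar walls and a
rounded notch arch, cartilage, per-subject footprint variability
independent of bone size, and physiologic multi-degree-of-freedom
kinematics. Two visible consequences, both accepted:

* At 45° of flexion the hinge swings the tibial insertion posteriorly
  fast enough that impingement typically drops to zero, whereas in vivo
  poses retain reduced but nonzero overlap at 45°. The orderings
  (0° ≥ 45° ≥ 90° ≈ 120° ≈ 0) are preserved.
* The femoral-position effect is comparatively stronger on the synthetic
  block wall than in vivo, where it is typically not significant. The
  tibial ordering (AM > central > PL in every femoral row) and the
  diameter effect match the expected pattern cell for cell.

## Statistics

The battery mirrors standard practice for this design: independent
pooled-variance *t*-test by graft diameter (Welch optional), paired
*t*-tests between flexion angles matched on (knee, femoral position,
tibial position, diameter) — all pairs are computed since the choice of
pairs is conventionally left open —, one-way ANOVA per footprint factor
and two-way ANOVA with interaction; partial eta squared
(SS_effect / (SS_effect + SS_error)) accompanies every F statistic.
Tests are two-sided at α = 0.05 with no multiplicity correction, matching
the apparent practice of the studies this design follows; all of these
are flags. The unit of analysis is the record within a caller-selected
stratum (typically one angle × one diameter, knee as replicate);
degenerate inputs (zero variance of differences) return p = 0 or p = 1
with an explicit note rather than erroring mid-batch. Type-I error of
every test is verified by 1000-replicate null simulation in the test
suite, together with the exact F = t² identity and a hand-computed ANOVA
oracle.

## Problem sizes and runtime

The shipped tests and the acceptance script use a 9-knee population ×
72 cells at 0.5 mm spacing (about ten seconds), 20-knee recovery checks,
and 1000-replicate null simulations — sizes chosen so the whole battery
runs comfortably on a laptop while leaving the statistical checks
well-powered. All sizes scale through ordinary function arguments.

```{r example, eval = FALSE}
knees <- generate_population(9, seed = 1)
records <- run_population(knees, factorial_design())
aggregate_impingement(records[records$flexion_angle == 0 &
                              records$diameter == 9, ])
stats_report(records)
```

## Known limitations

* Rigid cylinder, rigid bones: no deformation, wrapping, pretension or
  contact force estimation.
* Hinge kinematics without rollback (see above).
* No automatic landmarking or segmentation: real meshes need a landmark
  sidecar.
* The voxel kernel measures volume only; it does not construct the
  intersection solid.
* Bone tunnels are not drilled; the graft attaches at surface footprint
  centres.
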