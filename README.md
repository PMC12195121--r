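# aclimpinge

Virtual 3D simulation of graft impingement in anatomical single-bundle
ACL (anterior cruciate ligament) reconstruction.

After an ACL tear the ligament is replaced by a tendon graft strung
between tunnels drilled at the femoral and tibial footprints. If the
tunnels sit too far anteriorly, the graft collides with the femoral
intercondylar notch — mostly its roof — near full knee extension, which
abrades and ultimately fails the graft. `aclimpinge` quantifies that
conflict *in silico* for surgeons and biomechanics researchers planning
tunnel placement: it models the graft as a rigid cylinder between
footprint centres, poses the knee at four flexion angles, and measures
the graft–femur Boolean overlap volume for every combination of tunnel
positions and graft diameters.

## What it computes

* **Footprint placement.** Tunnel positions are specified on the
  classical quadrant grid of the medial wall of the lateral femoral
  condyle (superior border through the highest point of the notch, along
  the notch-roof/Blumensaat direction) and on the bounding rectangle of
  the tibial plateau outline. The bundle centres use the standard
  percentage coordinates — femoral AM at 25 % of total height / 33 % of
  total depth (from the posterior border), femoral PL at 45.1 % / 50 %,
  tibial AM at 35 % of depth / 50.5 % of width, tibial PL at
  46.4 % / 52.4 % — with the central point defined as the re-projected
  midpoint of AM and PL.
* **Impingement volume.** The graft is a capped cylinder of diameter 7 or
  9 mm between the two footprint centres. Overlap with the femoral solid
  is measured by a voxel Boolean kernel: both watertight surfaces are
  rasterized on one common lattice (default spacing *h* = 0.5 mm) and

  ```
  V = h^3 · #{ voxel centres inside femur ∩ graft }
  ```

  which converges to the exact Boolean intersection volume as *h* → 0.
  The count is clipped at the femoral-wall tangent plane through the
  footprint so that the geometrically unavoidable overlap of a straight
  cylinder with its own insertion site is not scored as impingement.
* **The factorial study.** 3 femoral × 3 tibial positions × 2 diameters
  × 4 flexion angles (0°, 45°, 90°, 120°) = 72 cells per knee, with
  mean ± SD tables and the statistical battery: independent *t*-test by
  diameter, paired *t*-tests across flexion angles, one-way ANOVA per
  footprint factor and two-way ANOVA with interaction, each with partial
  eta squared (SS_effect / (SS_effect + SS_error)).
* **Synthetic knees.** Clinical CT reconstructions are not distributed,
  so the package ships a parametric watertight knee generator (condylar
  blocks flanking a sloped-roof notch, elliptic plateau) with analytic
  ground truth for every quantity the pipeline measures — frames,
  footprints, notch width, flexion axis — and Gaussian population
  sampling (notch width 19.0 ± 3.4 mm by default).

## Worked example

```r
library(aclimpinge)

knee <- generate_knee()                 # default synthetic knee
notch_width(knee$femur)
#> [1] 19

frame <- fit_femoral_frame(knee$femur, knee$landmarks$femur)
fp <- footprint_center("femur", "AM", frame, knee$femur)
tfr <- fit_tibial_frame(knee$tibia, knee$landmarks$tibia)
tp <- footprint_center("tibia", "AM", tfr, knee$tibia)

graft <- build_graft(fp, tp, diameter = 9)
impingement_volume(knee$femur, graft, spacing = 0.5,
                   clip_planes = list(list(point = as.numeric(fp),
                                           normal = attr(fp, "face_normal"))))
#> [1] 317.5
```

317.5 mm³ is the notch-roof overlap of a 9 mm graft in the AM–AM
configuration at full extension — the worst-case cell. The full study
over a nine-knee population:

```r
knees <- generate_population(9, seed = 1)
records <- run_population(knees, factorial_design())
aggregate_impingement(records[records$flexion_angle == 0 &
                              records$diameter == 9, ])
#>   femoral_position tibial_position n  mean   sd
#> 1               AM              AM 9 272.5 50.2
#> 4               AM         central 9 189.3 47.0
#> 7               AM              PL 9  99.8 39.8
#> 2          central              AM 9 125.9 36.1
#> 5          central         central 9  80.2 31.0
#> 8          central              PL 9  35.8 21.9
#> 3               PL              AM 9  51.1 22.3
#> 6               PL         central 9  31.8 17.8
#> 9               PL              PL 9  13.7 11.7

ttest_diameter(records[records$flexion_angle == 0, ])
#> independent t-test (diameter): t = -5.832, df = 160, p = 2.94e-08
anova_oneway(records[records$flexion_angle == 0 &
                     records$diameter == 9, ], "tibial")
#> one-way ANOVA (tibial position): F = 11.41, df = 2, 78, p = 4.496e-05, partial eta^2 = 0.2264
```

Impingement falls monotonically from anteromedial toward posterolateral
tunnels on both bones, 9 mm grafts always impinge at least as much as
7 mm grafts, and every cell is exactly zero at 90° and 120° of flexion.

A command-line front end is installed at
`system.file("scripts", "acl-impinge.R", package = "aclimpinge")` with
`synth`, `run` and `stats` subcommands over STL + JSON knee fixtures and
CSV record files.

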