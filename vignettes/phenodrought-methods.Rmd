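---
title: "Methods: image-based drought phenotyping with phenodrought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based drought phenotyping with phenodrought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodrought)
```

## The problem

Controlled-environment phenomics platforms move potted plants on conveyors
through imaging cabinets, photographing each plant from three side angles
(0°, 120°, 240°) and from above at regular intervals, while automated
weighing-and-watering stations hold each pot at a target weight expressed as
a fraction of the growth medium's field capacity. From these images one can
derive non-destructive "digital traits" — above all the estimated shoot
biomass (ESB), the total plant pixel count over the four views — and use
them together with harvest traits (dry biomass, seed yield) to score
genotypes for drought tolerance and group them into breeding-relevant
clusters.

`phenodrought` implements that analysis end to end for a safflower-style
drought trial: image segmentation and tissue classification, 2-D shape
descriptors, the watering-schedule model, drought tolerance indices,
BLUE-adjusted growth curves, and k-means classification of genotypes.
Because the original glasshouse images and trait tables are not publicly
available, the package ships a synthetic-data module that generates all of
these inputs with known ground truth, so every downstream stage is testable
without any download.

## Segmentation model

A raw view is segmented by the following fixed stage order, all tunables
living in `seg_config()`:

1. **ROI crop** (`crop_roi`): removes imaging-unit pixels (cabinet frame,
   conveyor). Half-open rectangle, 0-based pixel coordinates; defaults to
   the full frame minus a configurable margin since cabinet geometry varies
   by installation.
2. **Colour candidates** (`color_candidate_masks`): per-channel interval
   rules in two colour spaces. HSI uses the classical decomposition
   (intensity `(R+G+B)/3` on 0–255; saturation `1 − min/I`; angular hue in
   degrees, set to 0 with `S = 0` for achromatic pixels, so grey never
   passes a saturated-hue rule). Lab is CIE L\*a\*b\* under D65 via
   `grDevices::convertColor`. Default rules keep hue 15–180° (yellow-brown
   through green), `S ≥ 0.2`, `I ≥ 40`, and `b* ≥ 15` with `L* ≥ 20`:
   both healthy green and senescent yellow/brown tissue pass, the dark
   cabinet background fails.
3. **Logical combination** (`combine_logical`): default `or` — the union
   favours recall, and later stages remove what slips through. Whether the
   two colour spaces should be intersected or united is genuinely open;
   both are supported.
4. **Adaptive threshold** (`adaptive_threshold`): keep a candidate pixel
   only if its intensity exceeds the local mean plus an offset (default
   −5). The default window is 101 px — deliberately wide relative to the
   canopy, so the local mean stays anchored to the dark background even
   inside dense plant regions; with a window comparable to organ spacing
   the local mean approaches plant intensity and darker tissue drops out.
5. **Median filter** (`median_filter`): binary majority vote in a 3×3
   neighbourhood (odd kernels only), smoothing edges and deleting isolated
   speckle.
6. **Morphological cleanup** (`morphological_clean`): optional binary
   erosion (3×3 cross element), hole filling, then removal of 8-connected
   components below `min_component_area` (default 50 px). Two defaults
   deserve comment:
   * `erosion_iters = 0`. Un-recovered erosion removes a one-pixel ring
     around every organ; on desk-scale rasters where organs are 3–6 px
     wide that costs 10–30 % of the plant. The operator is implemented and
     exposed for high-resolution use, but the default pipeline does not
     erode.
   * `max_hole_area = 5` in the pipeline default. A branched silhouette
     legitimately encloses background pockets between branches; filling
     every enclosed hole would paint these over. The cap repairs pinholes
     left by sensor speckle while preserving genuine pockets. The operator
     itself defaults to `Inf` (fill everything), matching the classical
     fill-areas semantics.
7. **Object composition** (`compose_objects`): the facility images one
   plant per frame, so all surviving components are treated as a single
   plant object (their union). An empty mask is flagged
   (`no_plant = TRUE`), not an error.
8. **Tissue classification** (`classify_color_nn`): every plant pixel gets
   the class of its nearest reference colour (Euclidean distance, default
   in Lab where distances are more perceptually uniform). Ties break
   toward green, for determinism.

All windowed operators use mirrored (symmetric, edge-repeated) borders, and
connectivity is 8-connected for plant components (thin diagonal stems) and
4-connected for background when finding enclosed holes.

## Shape traits

Descriptors are computed on true-pixel *centres*: the convex hull area of
a single pixel is 0, while pixel-count quantities (ESB, green/non-green
counts) count pixels. This keeps the geometry exact and testable against
brute-force oracles:

* `estimated_shoot_biomass`: plant pixels summed over the four views,
  ÷ 1000 (kilopixels). Both green and senescent tissue count; a green-only
  ESB is emitted alongside.
* `convex_hull_area`: shoelace area of the hull of pixel centres.
* `caliper_length`: default is the maximum Feret diameter (largest
  pairwise distance, attained at hull vertices) — the standard phenotyping
  reading of "plant extent"; the literal vertical extent (max row − min
  row) is available as `mode = "vertical"`. Which of the two a given
  commercial pipeline used is generally not documented, so both are
  provided and neither is claimed canonical.
* `min_area_rectangle`: exact rotating-calipers minimum — the optimum
  rectangle has a side collinear with a hull edge, so the minimum over all
  hull-edge directions is exact (verified against a dense 0.1° angle
  sweep in the tests).
* `bounding_box`: axis-aligned, half-open. For non-degenerate masks the
  containment chain CHA ≤ MAR ≤ BB holds on the pixel-centre convention.

Per-view traits default to the `side_0` view (with all views emitted in the
long output), since aggregating CHA/CL/MAR across views has no standard
definition.

## Irrigation model

Field capacity is calibrated gravimetrically
(`field_capacity_weight`): pots are saturated, drained, weighed, oven-dried
and weighed again; the pot weight at a fraction *f* of field capacity is
`mean(dry) + f·(mean(wet) − mean(dry))`. The watering protocol itself uses
the printed pot-weight anchors as configuration: 5200 g early growth,
5300 g control (90 % FC) from the initial-branching day, 4400 g for the
40 %-FC treatments, 4600 g for the 50 %-FC treatment, two-week holds, and
recovery ramps of exactly 150 ml/day back to 5300 g with the final step
clamped. The anchors are configuration rather than derived values because
they are not exactly collinear in the FC fraction; we reproduce the
protocol as printed. Schedules are fixed calendars, so the start of each
14-day hold is placed using an expected drawdown duration computed from
`expected_daily_loss` (default 180 g/day, a typical pot
evapotranspiration). The control ramp 5200→5300 g is placed on the
initial-branching day, a documented assumption. Throughout, 1 g of water
is 1 ml dispensed.

`generate_pot_weight_series` simulates the daily weigh–water–weigh loop:
watering tops a pot up to the day's target and never beyond it, and during
withholding no water is added, so the after-watering weight equals the
before-watering weight until the pot dries down to the stress target. The
water budget `Σ added = Σ loss + Δweight` holds exactly by construction
and is asserted in the tests.

## Drought indices

For a genotype with yield `Yp` under control and `Ys` under stress, and
`Ȳp` the control population mean:

* yield index `YI = Ys/Yp` (the variant `Ys/Ȳs`, relative to the stress
  population mean, is available via `yi_mode`);
* geometric mean productivity `GMP = √(Yp·Ys)`;
* mean productivity `MP = (Yp+Ys)/2`;
* tolerance `TOL = Yp − Ys`;
* stress tolerance index `STI = Yp·Ys/Ȳp²`.

Secondary (trait-ratio) indices for branch number, bud number, plant
height, dry biomass, seed number and ESB are the stress-treatment trait
mean over the all-genotype control mean, `Xt/Xc_mean`: below 1 means the
trait was depressed by stress, at/above 1 unaffected or improved. A
`1 − Xt/Xc_mean` rendering circulates in some write-ups, but only the plain
ratio is consistent with that reading, so the ratio is the default and the
other form sits behind `form = "one_minus_ratio"`. Zero denominators flag
the affected index rather than poisoning the rest. Correlation p-values in
`pearson_matrix` are reported raw (no multiplicity correction), as is
conventional for these trait-correlation panels.

## BLUE growth curves

`blue_adjusted_means` fits the additive fixed-effects model
`value = genotype + block + error` per timepoint and reports each
genotype's least-squares adjusted mean (equal-weight average over blocks,
via `emmeans`). In a balanced complete design this is exactly the raw
genotype mean; with missing cells it is the normal-equations solution,
verified in the tests against an independent dense least-squares solve. We
use fixed effects rather than a REML mixed model deliberately: the two
coincide in balanced designs, the fixed-effects solution is fully
specified with no iterative fitting, and the package does not claim to
reproduce any particular mixed-model software's shrinkage in unbalanced
cases. Disconnected genotype/block designs are refused with the
disconnected groups named.

## Clustering

`kmeans_cluster` standardizes ESB (kilopixels) and seed yield (g) to zero
mean and unit variance — they are incommensurate scales — then runs
Lloyd's algorithm from k-means++ starts, keeping the best of 25 restarts
by total within-cluster sum of squares. `k = 4` by default. Cluster labels
are then renamed by descending centroid performance (standardized ESB +
SY, ties broken by SY), so cluster 1 is always the high-biomass/high-yield
(drought-tolerant) group and cluster 4 the lowest; `tolerance_report`
flags cluster-1 genotypes as breeding candidates. Clustering operates on
per-genotype means under stress — whether one should instead cluster
per-plant observations is open; means are the documented default.

## The synthetic-data module

The generators emulate, with pixel- or row-level ground truth:

* **Genotypes** (`generate_genotypes`): growth rate (log-normal, median 1),
  drought sensitivity and senescence propensity (uniform), branch factor
  (3 + Poisson(4)), yield per biomass (log-normal, median 0.30 g/g). An
  optional tier structure plants a known tolerance grouping.
* **Growth** (`grow_plant`): a seeded organ template (branch azimuths,
  attachment heights, leaf sizes) expressed progressively with a
  development fraction `day³/(day³ + 95³)`, cubic so that most shoot
  biomass accumulates after the initial-branching stage (~day 66), as
  platform growth curves show. Under stress, post-onset increments are
  scaled by `1 − sensitivity × severity` with severities 0.90 (40 % FC at
  initial branching), 0.75 (50 % FC at both stages) and 0.50 (40 % FC at
  flowering) — chosen so harvest biomass reductions have the relative
  magnitudes reported for such trials (earliest and driest stress
  harshest, late stress mildest). Branches form a nested fan (lower
  branches spread wider, upper steeper), which is both safflower-like and
  keeps projected silhouettes from crossing themselves. Senescent organ
  fraction grows with accumulated stress exposure, leaves first.
* **Rendering** (`render_views`): independent 2-D silhouette projections —
  three side views and a top view — painted with per-organ palette
  colours over a dark cabinet background, with additive Gaussian noise
  (default sd 8 of 255) and salt-and-pepper speckle (rate 0.001) to
  exercise the median filter; an optional frame band exercises the ROI
  crop. Default scale is 144×144 px at 0.6 px/mm with organ widths
  7.5–10 mm, so the thinnest organ spans ≥ 3 px: a 3×3 majority median
  destroys 1–2 px structures, and real platform cameras give stems tens
  of pixels of width, so adequate sampling is part of what the fixture
  emulates. Rendered silhouette area is conserved against a supersampled
  analytic projection to within 5 %.
* **Experiments** (`generate_experiment`): the two study designs — a
  randomized complete block design with six replications over four
  treatments, and a split-plot design (control vs combined-stage stress)
  for large panels. Observations are deterministic genotype × treatment
  expectations times multiplicative log-normal noise (continuous traits;
  positivity), Poisson draws (counts), and a multiplicative block effect.
  `noise_scale = 0` gives exact expectations for oracle tests. The
  generated ESB is proportional to dry biomass with log-normal scatter
  `esb_sdlog = 0.10`, calibrated once so the ESB–DB Pearson correlation is
  ≈ 0.9 at the first experiment's n = 96.
* **Pot weights** (`generate_pot_weight_series`): daily truncated-normal
  losses against any treatment schedule.

What the fixtures do **not** emulate: occlusion and perspective (each view
is an independent projection), leaf shape (discs), illumination gradients,
soil/pot pixels inside the ROI, imaging-arm reflections, or any
correlation between image noise and plant size. Passing segmentation tests
therefore demonstrate correctness of the pipeline's logic and its
behaviour under the stated noise model — not performance on real glasshouse
imagery, which would need its own validation.

## Numerical conventions and degenerate inputs

* All RNG flows through per-call integer seeds (`withr::with_seed`); the
  pipeline derives stage seeds from one master seed, and a fixed master
  seed reproduces byte-identical CSV artifacts.
* Windowed operators: mirrored borders; odd windows only.
* Nearest-neighbour ties → green; hue at achromatic pixels → 0 with
  saturation 0; k-means label ties → higher SY centroid.
* Empty masks: shape traits return 0 with an `empty` flag; segmentation
  of a background-only frame returns an empty mask plus `no_plant`, not an
  error. Collinear pixel sets have zero hull and rectangle area by
  convention.
* Yield pairs with `Yp = 0` flag YI (and STI when the population mean is
  0) as undefined without dropping the remaining indices.

## Problem sizes in the shipped tests

The test-suite and the acceptance script use desk-scale versions of the
study conditions: 144×144 px views (50 image sets for fidelity checks),
200 random ≤ 100-pixel masks for the geometry oracles, 100+ random
≤ 32×32 inputs per per-pixel operator oracle, 1 000 random yield pairs,
20 simulated block experiments for BLUE coverage, 200-genotype tiered
populations for cluster recovery, and a demo pipeline of 8 genotypes × 2
treatments × 3 blocks × 3 imaging days at 64×64 px. These sizes were
chosen as the smallest that still exercise every code path and give stable
statistical checks.

## Known limitations

* The fixed-effects BLUE diverges from mixed-model shrinkage in strongly
  unbalanced designs.
* Segmentation defaults are tuned for dark-background cabinets; bright or
  textured backgrounds need different colour rules.
* The caliper length's two readings (Feret vs vertical) can differ
  materially for sprawling plants; outputs label which was used.
* Correlations between digital and destructive traits computed on
  synthetic data reflect the generator's planted association strength,
  not any real experiment's value.
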