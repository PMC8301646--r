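# phenodrought

Image-based drought phenotyping for controlled-environment plant trials.

Conveyor phenomics platforms photograph each potted plant from three side
angles (0°, 120°, 240°) and from above at regular intervals while automated
stations weigh and water every pot to a target expressed as a fraction of
the growth medium's field capacity. `phenodrought` turns those images and
pot-weight logs into drought-tolerance calls for a genotype panel:

* **Segmentation** — ROI crop, HSI + CIE L\*a\*b\* colour-interval candidate
  masks, logical combination, adaptive intensity thresholding, binary
  median filtering, morphological cleanup, object composition, and
  nearest-neighbour classification of plant pixels into green and
  senescent (non-green) tissue.
* **Digital shape traits** — estimated shoot biomass (ESB: plant pixels
  over all four views, in kilopixels), convex hull area (CHA), caliper
  length (CL, maximum Feret diameter), minimum-area enclosing rectangle
  (MAR) and bounding box (BB), computed exactly on pixel centres.
* **Irrigation** — gravimetric field-capacity calibration, the four
  watering regimes (control at 90% FC; 40% FC at initial branching; 40% FC
  at flowering; 50% FC at both stages, with two-week holds and 150 ml/day
  recovery ramps), and the daily water-loss trait.
* **Statistics** — drought tolerance indices per genotype

  YI = Ys/Yp, GMP = √(Yp·Ys), MP = (Yp+Ys)/2, TOL = Yp−Ys,
  STI = Yp·Ys/Ȳp²

  plus trait-ratio indices (BrNI, BdNI, PHI, DBI, SNI, ESBI = stress
  trait mean over control population mean), Pearson correlation matrices
  with significance stars, and BLUE-adjusted genotype means
  (`value = genotype + block + error`) for dynamic growth curves.
* **Clustering** — k-means (k = 4, standardized features, k-means++ starts,
  best of 25 restarts) of genotypes on (ESB, SY) under stress, labels
  ordered so cluster 1 is always the high-biomass/high-yield
  drought-tolerant group; `tolerance_report()` flags those genotypes as
  breeding candidates.
* **Synthetic data** — because the original glasshouse imagery is not
  public, the package generates all of its own inputs with ground truth:
  procedurally grown safflower-like plants rendered into the four views
  with per-pixel truth masks and class maps, replicated trait tables for
  the two study designs (RCBD with six blocks over four treatments;
  split-plot control vs combined-stage stress), and daily pot-weight logs.

Everything is tidyverse-native: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and each result
type has an `autoplot()`.

## Worked example

Grow one synthetic plant under the combined-stage stress, image it,
segment the side view, and compile its digital traits:

```r
library(phenodrought)

g    <- generate_genotypes(4, seed = 3)
p    <- grow_plant(g[1, ], "IB50FL50", day = 90, seed = 11)
p
#> <plant_geometry> day 90 IB50FL50 - 18 organs, height 142 mm, 14 % senescent

iset <- render_views(p, render_config(), seed = 5)
seg  <- segment_plant(iset$views$side_0)
seg
#> <segmentation> 144 x 144 px; 1322 plant px ( 1116 green / 206 non-green )
```

The plant lost ~14% of its organs to senescence and the classifier finds
206 of 1322 plant pixels (~16%) non-green — the pixel-level view of the
same stress response. Compiling all four views into one trait row:

```r
x <- purrr::imap(iset$views, function(img, v) tibble::tibble(
  plant_id = "G001", day = 90, view = v,
  class_map = list(segment_plant(img)$class_map))) |> purrr::list_rbind()
compile_digital_traits(x)
#>   plant_id   day   esb esb_green   cha    cl mar_area bb_area
#> 1 G001        90  4.79      3.96  3120  113.    5024.    5311
```

ESB is 4.79 kilopixels (3.96 green-only); the side-view hull covers
3120 px², the plant's largest extent is 113 px, and the minimum-area
rectangle (5024 px²) is tighter than the axis-aligned box (5311 px²), as
it must be. The drought indices evaluate their closed forms:

```r
primary_indices(tibble::tibble(yp = 4, ys = 1), yp_bar = 2)
#>      yi   gmp    mp   tol   sti
#> 1  0.25     2   2.5     3     1
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all of the above
for a demo panel (8 genotypes × 2 treatments × 3 blocks × 3 imaging days)
and writes every intermediate table as CSV plus a run log; a fixed master
seed reproduces the CSVs byte for byte. A thin command-line wrapper lives
at `inst/scripts/phenodrought.R` (`run-all`, `simulate`, `irrigate`,
`cluster`).

## Layout

```
R/                      implementation (one file per stage)
tests/testthat/         unit, property and acceptance tests with
                        independent brute-force oracles
scripts/acceptance.R    end-to-end quantitative report (JSON)
inst/scripts/           command-line wrapper
vignettes/              methods vignette: models, conventions, defaults,
                        design decisions and limitations
```
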