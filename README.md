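# perioStage

Measures percentage radiographic bone loss (RBL) and assigns
periodontitis stages from segmentation masks of two-jaw dental
radiographs.

## What problem it solves, and for whom

Under the 2017 World Workshop classification, periodontitis stages 1–3
can be determined radiographically from how far the alveolar bone crest
has receded from the cementoenamel junction (CEJ) toward the root apex,
as a fraction of root length. Panoramic radiographs magnify
non-uniformly, so absolute lengths are unreliable — but this ratio is
magnification-invariant. perioStage is for researchers building or
evaluating automated periodontal staging pipelines: it implements the
geometric measurement half of a hybrid design, where any detector (a
Mask-R-CNN-style network, an atlas method, or the shipped synthetic
oracle) supplies masks and this package turns them into per-tooth
measurements, stages and evaluation statistics.

## The method

Given masks of (a) the oral-cavity region enclosed by the maxillary and
mandibular periodontal bone levels, (b) one crown band per jaw, and (c)
tooth/implant instances:

1. per-column extremal rows of the enclosed region give the two bone
   level curves; the apical edge of each crown band gives the CEJ level
   (lateral ends trimmed, default 5%);
2. each instance's long axis is the minimum-inertia principal axis of
   its boundary pixels — the eigendirection of
   `[[μ20, μ11], [μ11, μ02]]` with the larger eigenvalue — oriented
   apically by jaw;
3. the axis is intersected with both level curves, and with the root
   apex `a`, CEJ intersection `c` and bone-level intersection `b`:

   `RBL% = 100 · (‖a − c‖ − ‖a − b‖) / ‖a − c‖`

4. stage 1 if RBL < 15%, stage 2 if 15–33%, stage 3 if > 33%.

The package also ships the matching evaluation suite (pixel accuracy as
printed in the source protocol, i.e. TP/(TP+FN); Dice; Jaccard; mean
absolute stage difference; Pearson; ICC(2,1) from two-way ANOVA mean
squares) and a synthetic two-jaw phantom generator with exact per-tooth
ground truth, so the full pipeline is testable with no clinical data.

## Worked example

```r
library(perioStage)

spec <- phantomSpec(lossFractions = c(0.05, 0.20, 0.40, 0.60),
                    tiltDegrees = c(-5, 0, 3, 8), teethPerJaw = 4L, seed = 7L)
scene <- generatePhantom(spec)
report <- stageAll(sceneMasks(scene))
report[report$jaw == "maxilla",
       c("id", "jaw", "d_cej_px", "d_pbl_px", "rbl_percent", "stage")]
#>   id     jaw d_cej_px d_pbl_px rbl_percent stage
#> 1  1 maxilla    72.19    68.17       5.561     1
#> 2  2 maxilla    72.00    58.00      19.445     2
#> 3  3 maxilla    72.10    43.06      40.278     3
#> 4  4 maxilla    71.69    29.26      59.189     3
```

The four maxillary teeth were generated with true bone-loss fractions
0.05, 0.20, 0.40 and 0.60 (true RBL 5/20/40/60%). `d_cej_px` is the
apex-to-CEJ intersection length (the ~72 px phantom root), `d_pbl_px`
the apex-to-bone-level length; the recovered RBL percentages are within
~0.6 points of truth — residual error is pixel rasterization — and the
stages are exact.

Degrade the masks like an imperfect detector and score them:

```r
noisy <- perturbMasks(scene, boundaryNoisePx = 2, seed = 1L)
tr <- sceneTruth(scene)
ev <- evaluateRun(scene, sceneMasks(noisy),
                  data.frame(id = tr$id, stage = tr$stage),
                  data.frame(id = report$id, stage = report$stage))
subset(ev, metric %in% c("dice", "mad", "icc") &
           structure %in% c("oral_cavity", "stages"))
#>    metric   structure value      n
#> 2    dice oral_cavity 0.998 141687
#> 13    mad      stages 0.000      8
#> 15    icc      stages 1.000      8
```

A command-line interface wraps the same functions
(`inst/scripts/periostage simulate|stage|evaluate`); see
`?periostageMain`.

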