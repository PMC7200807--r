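---
title: "Measuring radiographic bone loss and staging periodontitis from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring radiographic bone loss and staging periodontitis from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perioStage)
```

## The measurement problem

Periodontitis destroys the alveolar bone that supports the teeth. Under the
2017 World Workshop classification, stages 1–3 can be assigned from
radiographs alone through the *percentage radiographic bone loss* (RBL): how
far the bone crest has receded from the cementoenamel junction (CEJ) toward
the root apex, expressed as a fraction of root length. Panoramic radiographs
carry position-dependent magnification, so absolute millimetre lengths are
unreliable — but a ratio of two lengths measured along the same tooth axis
is magnification-invariant, which is why RBL is defined as a percentage.

perioStage implements the geometric half of a hybrid design: some upstream
detector (in practice a CNN; here a pluggable segmenter) supplies
segmentation masks of three deliberately simple structures per image —

* the region of the partial oral cavity **enclosed by the two periodontal
  bone levels** (one structure for the whole jaw pair),
* one **crown band** per jaw whose apical edge is the CEJ level (the
  fixture top for implants), and
* per-tooth / per-implant **instance masks** —

and this package turns those masks into per-tooth RBL percentages and
stages. Annotating the bone level as the boundary of one enclosed region,
rather than tracing every defect, sidesteps the variety of destruction
patterns (horizontal loss, angular defects, craters) that make direct
bone-loss segmentation hard.

## The procedure

For one instance the pipeline is:

1. **Binarize** each probability raster at a threshold (default 0.5, ties
   to foreground).
2. **Level curves.** For each retained image column, the topmost pixel of
   the oral-cavity mask is the maxillary bone level and the bottommost the
   mandibular one; the apical edge of each crown band (topmost row for the
   maxilla, bottommost for the mandible) is the CEJ level. A fraction of
   columns (default 5%) at each lateral end is dropped: detection errors
   concentrate at the lateral walls of the enclosed region, which carry no
   bone-level information. We use per-column extremal rows rather than a
   generic contour trace because the intersection step needs exactly one
   y per column and no lateral-wall points.
3. **Long axis.** The instance's boundary pixels (4-neighbor rim) feed the
   central second-moment matrix [[mu20, mu11], [mu11, mu02]]. Its
   eigendirection with the larger eigenvalue — the axis of *minimum* moment
   of inertia — is the tooth's long axis. The sign is resolved apically:
   upward (decreasing y) for maxillary, downward for mandibular teeth,
   with the jaw decided by the centroid's position relative to the mean of
   the two bone curves.
4. **Apex.** The mask pixel with maximal projection onto the apical
   direction; ties break toward the axis line, then toward smaller x.
   Constraining the apex to mask pixels keeps it inside the instance even
   when the continuous axis extremum lies outside a tilted crown outline.
5. **Intersections and RBL.** The infinite axis line through the centroid
   is intersected with each piecewise-linear level curve. With
   `d_cej = ‖apex − CEJ point‖` and `d_pbl = ‖apex − bone point‖`,

   `RBL% = 100 · (d_cej − d_pbl) / d_cej`

   clamped to [0, 100] with flags. The ratio `d_pbl / d_cej` itself equals
   1 for a healthy tooth, so reporting the *loss* complement is what makes
   "RBL < 15%" describe near-health; the literal remaining-ratio reading is
   available as `rblConvention = "remaining"` and changes only the reported
   column, never the stage.
6. **Stage.** `< 15% → 1`, `15–33% → 2`, `> 33% → 3`. The boundaries follow
   the strict inequalities of stages 1 and 3, so exactly 15% and exactly
   33% are stage 2. Stage 4 involves non-radiographic criteria and is never
   emitted.

Per-instance failures (no curve crossing, near-isotropic shape, horizontal
axis, degenerate root) are reported as rows with an `NA` stage and a
reason — a batch over a whole jaw must not abort because one tooth is
unstageable.

## Tunable parameters

| parameter | default | unit | why this value |
|---|---|---|---|
| `binarizeThreshold` | 0.5 | probability | symmetric point of a calibrated detector |
| `lateralTrimFraction` | 0.05 | fraction of columns | lateral walls are irrelevant but no principled number exists; small enough to keep outermost teeth |
| `smoothingWindow` | 1 (off) | columns | per-column extraction is already single-valued; jaggies rarely move intersections, so smoothing is opt-in |
| `isotropyThreshold` | 1.2 | eigenvalue ratio | below this the orientation is numerically meaningless (near-fourfold symmetry) |
| `gapInterpolationSpanPx` | 40 | px | bridges inter-crown CEJ gaps (≈ one tooth width) but not missing structures |
| `rblConvention` | `"loss"` | — | see step 5 |
| `momentSource` | `"boundary"` | — | boundary-image moments; `"filled"` provided for comparison (the two agree within 2° on phantom teeth) |
| `iccModel` | `"ICC2"` (2,1 single) | — | stages are absolute clinical categories, so absolute agreement is the right default; ICC1/ICC3 and average-measure forms selectable |

## The synthetic phantom

Real panoramic radiographs (and a trained detector) are out of scope, so
the package generates its own study conditions: a **flattened arch** — one
horizontal row of teeth per jaw on a single raster, maxilla above mandible.
The curved arch, grayscale texture, vertebra overlap and multi-root molars
are deliberately *not* emulated; none of them change the geometry the
formulas act on, which is the thing under test. Consequences: passing tests
demonstrate correctness of the measurement geometry on known ground truth,
not clinical performance of any detector.

Defaults emulate a mid-resolution panoramic crop: 640×400 px, 8 teeth per
jaw, 40 px crowns, 72 px roots with 36 px crowns (2:1 root:crown height),
2 px of sinusoidal waviness on the inter-dental bone curve (period
`0.8 · rootLength` so scaled specs stay geometrically similar), and — in
`randomPhantomSpec()` — per-tooth loss fractions drawn uniformly from
[0.02, 0.95] and tilts from ±8°, spanning all three stages and realistic
axis inclinations. Teeth are tapered polygons (crown wider than root, root
narrowing to a ~2 px apex) so the apex is unambiguous; implants are
straight-sided rectangles whose flat coronal end, the fixture top, is the
CEJ-equivalent reference. The bone curve interpolates per-tooth bone
anchors linearly with added waviness that vanishes at every anchor, so the
true RBL is exact by construction while multiple-crossing cases still
occur between teeth. Each jaw's CEJ band is the union of the crown
polygons plus a thin (5 px) connecting band across the image width,
mimicking the single contiguous per-jaw annotation style.

All randomness flows from one integer seed through a scoped RNG (the
caller's random state is saved and restored), so scenes and perturbations
are bit-reproducible.

`perturbMasks()` degrades masks the way an imperfect detector would:
boundary displacement by a smooth seeded noise field (thresholding the
signed distance transform plus the field) and whole-instance dropout.
Because the field is drawn as `rnorm(sd = σ)` from a fixed seed, it scales
exactly linearly in σ, so a noise sweep at one seed displaces every
boundary coherently — degradation curves are monotone per scene, not just
on average.

## Numerical choices and degenerate inputs

* **Coordinates** are 0-based, x = column rightward, y = row downward,
  pixel centers at integer coordinates; `(x, y)` lives at matrix element
  `[y+1, x+1]`.
* **Polygon rasterization** uses even-odd pixel-center containment with
  half-open boundaries (smaller-coordinate edges included), making pixel
  counts exact: a 10×10 square covers exactly 100 pixels. Self-intersecting
  polygons are rejected.
* **Intersection selection**: all curve-segment crossings of the axis line
  are enumerated; candidates are restricted to the tooth's column extent
  expanded by 25%, then the crossing nearest the centroid wins. Segments
  are half-open in their parameter so shared vertices are counted once.
  Multiple candidates and bridged-gap crossings are flagged, not hidden.
* **Ties at the apex** break deterministically (axis proximity, then
  smaller x), so reports are bit-reproducible.
* **Near-circular instances** (eigenvalue ratio < 1.2) fail with an
  isotropic-shape error rather than returning an arbitrary axis.
* **Clamping**: raw RBL outside [0, 100] (noisy masks can put the bone
  crossing apical of the apex or coronal of the CEJ) is clamped and
  flagged, never silently dropped.
* **Empty/degenerate inputs** (empty masks, < 3 moment pixels,
  `d_cej ≤ 1 px`, split oral-cavity masks) raise classed errors naming the
  offending structure or instance.

## Evaluation suite

Pixel accuracy is implemented exactly as printed in the source protocol —
`TP / (TP + FN)`, i.e. recall over ground-truth pixels — and is therefore
intentionally asymmetric; a config flag adds conventional
`(TP + TN) / total` as a secondary output. Dice and Jaccard obey
`D = 2J/(1+J)` to 1e-12 (property-tested). Stage agreement uses the mean
absolute stage difference, Pearson correlation (via `stats::cor`), and an
ICC computed from two-way ANOVA mean squares, default ICC(2,1); tests
cross-check it against mean squares extracted from `stats::aov`.
`evaluateRun()` also emits raw per-case stage differences so downstream
significance testing remains possible without re-running the pipeline.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script use 20 clean full-size phantoms
(8 teeth per jaw) for recovery properties, 20 seeds × 4 noise levels
(0/1/2/4 px) for degradation monotonicity, 100 random blobs/mask pairs for
the axis and metric oracles, 50 masks for the edge-extraction oracle and a
single 2× magnification pair for scale invariance — sizes chosen so every
property is exercised across its input range while a full run stays
comfortable on a laptop.

## Known limitations

* Single-root geometry only; mesial/distal roots of molars with unequal
  bone levels are not modelled, and no multi-root axis decomposition is
  attempted.
* The apex is a mask pixel, not a sub-pixel estimate; level curves are not
  sub-pixel either.
* The phantom cannot certify a real detector: it has no texture, occlusion
  or contrast variation. The segmenter contract exists precisely so a real
  detector can be dropped in and evaluated with the same metric suite.
* Staging covers stages 1–3 from RBL only; grading, extent descriptors and
  tooth numbering are out of scope.
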