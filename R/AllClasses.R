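## Central S4 classes. All raster slots are plain integer/numeric matrices of
## dimension height x width; see package doc for the 0-based (x, y) convention.

#' PhantomSpec: parameters of a synthetic two-jaw scene
#'
#' Describes a "flattened arch" phantom: one horizontal row of teeth per jaw
#' on a single raster, maxilla above mandible. Per-tooth parameters are
#' stored as `teethPerJaw x 2` matrices with columns `maxilla`, `mandible`.
#'
#' @slot imageHeight,imageWidth raster dimensions in pixels.
#' @slot teethPerJaw number of instances per jaw.
#' @slot toothWidth crown width in pixels.
#' @slot rootLength apex-to-CEJ distance along the tooth axis, pixels.
#' @slot crownLength CEJ-to-incisal-edge distance along the axis, pixels.
#' @slot lossFractions per-tooth bone-loss fraction in [0, 1].
#' @slot tiltDegrees per-tooth long-axis tilt from vertical, degrees.
#' @slot implantFlags per-tooth logical; `TRUE` renders an implant fixture.
#' @slot curveWaviness sinusoidal bone-curve amplitude between teeth, pixels.
#' @slot seed integer seed driving all randomness in the generator.
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", slots = c(
  imageHeight = "integer", imageWidth = "integer", teethPerJaw = "integer",
  toothWidth = "numeric", rootLength = "numeric", crownLength = "numeric",
  lossFractions = "matrix", tiltDegrees = "matrix", implantFlags = "matrix",
  curveWaviness = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  h <- object@imageHeight; w <- object@imageWidth; n <- object@teethPerJaw
  msg <- character()
  if (h < 1L || w < 1L) msg <- c(msg, "imageHeight/imageWidth must be positive")
  if (n < 1L) msg <- c(msg, "teethPerJaw must be positive")
  if (object@toothWidth <= 0 || object@rootLength <= 0 ||
      object@crownLength <= 0)
    msg <- c(msg, "toothWidth, rootLength and crownLength must be positive")
  for (nm in c("lossFractions", "tiltDegrees", "implantFlags")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(n, 2L)))
      msg <- c(msg, sprintf("%s must be a %d x 2 matrix", nm, n))
  }
  if (any(object@lossFractions < 0 | object@lossFractions > 1))
    msg <- c(msg, "lossFractions must lie in [0, 1]")
  if (any(abs(object@tiltDegrees) >= 45))
    msg <- c(msg, "tiltDegrees must satisfy |tilt| < 45")
  gap <- (w - n * object@toothWidth) / (n + 1)
  if (gap < 3)
    msg <- c(msg, sprintf(
      "teeth do not fit: inter-tooth gap %.1f px < 3 px (teethPerJaw x toothWidth too large for imageWidth)",
      gap))
  apexMargin <- round(0.1 * h)
  if (2 * (apexMargin + object@rootLength + object@crownLength) + 10 > h)
    msg <- c(msg, "crown band exceeds image: rootLength + crownLength too large for imageHeight")
  if (object@curveWaviness < 0) msg <- c(msg, "curveWaviness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StructureMaskSet: the raster inputs of the staging pipeline
#'
#' Holds the four co-registered rasters the pipeline consumes: the
#' oral-cavity region enclosed by the two periodontal bone levels, one
#' crown-band (CEJ) mask per jaw, and a labeled instance raster
#' (background 0, instance ids 1..N). Binary slots may also carry
#' probability values in [0, 1] produced by a segmenter; they are
#' binarized downstream.
#'
#' @slot oralCavity,cejMaxilla,cejMandible numeric/integer matrices in [0, 1].
#' @slot instances integer matrix of non-negative instance labels.
#' @export
setClass("StructureMaskSet", slots = c(
  oralCavity = "matrix", cejMaxilla = "matrix", cejMandible = "matrix",
  instances = "matrix"))

setValidity("StructureMaskSet", function(object) {
  d <- dim(object@oralCavity)
  msg <- character()
  for (nm in c("cejMaxilla", "cejMandible", "instances"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("dimension mismatch: %s is %s, oralCavity is %s",
                            nm, paste(dim(slot(object, nm)), collapse = "x"),
                            paste(d, collapse = "x")))
  for (nm in c("oralCavity", "cejMaxilla", "cejMandible")) {
    v <- slot(object, nm)
    if (any(v < 0 | v > 1)) msg <- c(msg, sprintf("%s has values outside [0, 1]", nm))
  }
  inst <- object@instances
  if (any(inst < 0) || any(inst != round(inst)))
    msg <- c(msg, "instances must contain non-negative integer labels")
  if (length(msg)) msg else TRUE
})

#' PhantomScene: a generated scene plus its ground truth
#'
#' @slot masks a [StructureMaskSet-class] with the generated rasters.
#' @slot truth per-tooth ground truth `data.frame` with columns
#'   `id, jaw, kind, loss_fraction, rbl_percent, stage, axis_angle_deg,
#'   apex_x, apex_y`.
#' @slot spec the [PhantomSpec-class] the scene was generated from.
#' @export
setClass("PhantomScene", slots = c(
  masks = "StructureMaskSet", truth = "data.frame", spec = "PhantomSpec"))

setValidity("PhantomScene", function(object) {
  need <- c("id", "jaw", "kind", "loss_fraction", "rbl_percent", "stage",
            "axis_angle_deg", "apex_x", "apex_y")
  miss <- setdiff(need, names(object@truth))
  if (length(miss))
    return(sprintf("truth lacks columns: %s", paste(miss, collapse = ", ")))
  tr <- object@truth
  if (any(tr$rbl_percent != 100 * tr$loss_fraction))
    return("truth rbl_percent must equal 100 * loss_fraction exactly")
  TRUE
})

#' LevelCurve: an ordered per-column level polyline
#'
#' One bone or CEJ level for one jaw: at most one `y` per retained image
#' column, strictly increasing `x`. Columns with no mask support are absent,
#' so a curve may consist of several monotone runs (gaps are bridged later,
#' at intersection time, up to a configurable span).
#'
#' @slot jaw `"maxilla"` or `"mandible"`.
#' @slot kind `"bone_level"` or `"cej_level"`.
#' @slot x integer 0-based column indices, strictly increasing.
#' @slot y numeric 0-based row per column.
#' @export
setClass("LevelCurve", slots = c(
  jaw = "character", kind = "character", x = "integer", y = "numeric"))

setValidity("LevelCurve", function(object) {
  msg <- character()
  if (!object@jaw %in% c("maxilla", "mandible"))
    msg <- c(msg, "jaw must be 'maxilla' or 'mandible'")
  if (!object@kind %in% c("bone_level", "cej_level"))
    msg <- c(msg, "kind must be 'bone_level' or 'cej_level'")
  if (length(object@x) == 0L) msg <- c(msg, "curve is empty")
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y lengths differ")
  if (length(object@x) > 1L && any(diff(object@x) <= 0L))
    msg <- c(msg, "x must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' CentralMoments: second-order central moments of a pixel set
#'
#' @slot m00 number of pixels.
#' @slot centroid `(x, y)` arithmetic mean of pixel coordinates.
#' @slot mu20,mu11,mu02 second central moments in px^2, plain sums
#'   `sum((x - xbar)^p * (y - ybar)^q)` over the pixel set.
#' @export
setClass("CentralMoments", slots = c(
  m00 = "numeric", centroid = "numeric",
  mu20 = "numeric", mu11 = "numeric", mu02 = "numeric"))

setValidity("CentralMoments", function(object) {
  msg <- character()
  if (object@m00 < 3) msg <- c(msg, "m00 must be >= 3")
  if (object@mu20 < 0 || object@mu02 < 0)
    msg <- c(msg, "mu20 and mu02 must be non-negative")
  if (object@mu11^2 > object@mu20 * object@mu02 * (1 + 1e-9) + 1e-9)
    msg <- c(msg, "mu11^2 must not exceed mu20 * mu02")
  if (length(msg)) msg else TRUE
})

#' ToothAxis: long-axis geometry of one instance
#'
#' @slot id instance label.
#' @slot jaw `"maxilla"` or `"mandible"`.
#' @slot centroid `(x, y)` centroid of the pixels the moments were taken over.
#' @slot direction apical-pointing unit vector of the long axis.
#' @slot elongation major/minor inertia eigenvalue ratio, >= 1.
#' @slot apex `(x, y)` root-apex pixel (always a pixel of the instance mask).
#' @export
setClass("ToothAxis", slots = c(
  id = "integer", jaw = "character", centroid = "numeric",
  direction = "numeric", elongation = "numeric", apex = "numeric"))

setValidity("ToothAxis", function(object) {
  msg <- character()
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    msg <- c(msg, "direction must be a unit vector")
  if (object@elongation < 1) msg <- c(msg, "elongation must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SegmenterOutput: the pluggable-segmenter contract
#'
#' Any segmenter (including a learned detector attached later) must return
#' this: probability rasters in [0, 1] for the three structures plus a hard
#' instance label raster. [asMaskSet()] binarizes it into a
#' [StructureMaskSet-class] for the staging pipeline.
#'
#' @slot oralCavity,cejMaxilla,cejMandible numeric matrices in [0, 1].
#' @slot instances integer label matrix.
#' @export
setClass("SegmenterOutput", slots = c(
  oralCavity = "matrix", cejMaxilla = "matrix", cejMandible = "matrix",
  instances = "matrix"))

setValidity("SegmenterOutput", function(object) {
  d <- dim(object@oralCavity)
  msg <- character()
  for (nm in c("cejMaxilla", "cejMandible", "instances"))
    if (!identical(dim(slot(object, nm)), d))
      msg <- c(msg, sprintf("%s dimensions differ from oralCavity", nm))
  for (nm in c("oralCavity", "cejMaxilla", "cejMandible"))
    if (any(slot(object, nm) < 0 | slot(object, nm) > 1))
      msg <- c(msg, sprintf("%s has values outside [0, 1]", nm))
  if (length(msg)) msg else TRUE
})

#' PipelineConfig: tunable parameters of the staging pipeline
#'
#' @slot binarizeThreshold probability threshold, in (0, 1); default 0.5.
#' @slot lateralTrimFraction fraction of each curve's column extent dropped
#'   at each lateral end; default 0.05.
#' @slot smoothingWindow odd median-filter window in columns; 1 = off.
#' @slot isotropyThreshold minimum inertia-eigenvalue ratio below which an
#'   instance is flagged orientation-undefined; default 1.2.
#' @slot gapInterpolationSpanPx largest curve gap (columns) bridged linearly
#'   during axis-curve intersection; default 40.
#' @slot rblConvention `"loss"` (default) reports
#'   `100 * (d_cej - d_pbl) / d_cej`; `"remaining"` reports the literal ratio
#'   `100 * d_pbl / d_cej`. Staging always uses the loss value.
#' @slot iccModel `"ICC1"`, `"ICC2"` (default, two-way random, absolute
#'   agreement) or `"ICC3"`.
#' @slot momentSource `"boundary"` (default) or `"filled"`: which pixel set
#'   the axis moments are computed over.
#' @slot conventionalAccuracy if `TRUE`, evaluation reports also include
#'   conventional (TP+TN)/total accuracy next to pixel accuracy.
#' @slot seed integer seed for seeded helpers.
#' @export
setClass("PipelineConfig", slots = c(
  binarizeThreshold = "numeric", lateralTrimFraction = "numeric",
  smoothingWindow = "integer", isotropyThreshold = "numeric",
  gapInterpolationSpanPx = "numeric", rblConvention = "character",
  iccModel = "character", momentSource = "character",
  conventionalAccuracy = "logical", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@binarizeThreshold <= 0 || object@binarizeThreshold >= 1)
    msg <- c(msg, "binarizeThreshold must lie in (0, 1)")
  if (object@lateralTrimFraction < 0 || object@lateralTrimFraction >= 0.5)
    msg <- c(msg, "lateralTrimFraction must lie in [0, 0.5)")
  if (object@smoothingWindow < 1L || object@smoothingWindow %% 2L == 0L)
    msg <- c(msg, "smoothingWindow must be odd and >= 1")
  if (object@isotropyThreshold < 1)
    msg <- c(msg, "isotropyThreshold must be >= 1")
  if (object@gapInterpolationSpanPx < 0)
    msg <- c(msg, "gapInterpolationSpanPx must be >= 0")
  if (!object@rblConvention %in% c("loss", "remaining"))
    msg <- c(msg, "rblConvention must be 'loss' or 'remaining'")
  if (!object@iccModel %in% c("ICC1", "ICC2", "ICC3"))
    msg <- c(msg, "iccModel must be one of ICC1, ICC2, ICC3")
  if (!object@momentSource %in% c("boundary", "filled"))
    msg <- c(msg, "momentSource must be 'boundary' or 'filled'")
  if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px, %d teeth/jaw (%d implants)\n",
              object@imageHeight, object@imageWidth, object@teethPerJaw,
              sum(object@implantFlags)))
  cat(sprintf("  tooth %g px wide, root %g px, crown %g px, waviness %g px, seed %d\n",
              object@toothWidth, object@rootLength, object@crownLength,
              object@curveWaviness, object@seed))
  cat(sprintf("  loss fractions: maxilla %s | mandible %s\n",
              paste(format(object@lossFractions[, 1L], digits = 2), collapse = " "),
              paste(format(object@lossFractions[, 2L], digits = 2), collapse = " ")))
})

setMethod("show", "StructureMaskSet", function(object) {
  d <- dim(object@oralCavity)
  ids <- instanceIds(object)
  cat(sprintf("StructureMaskSet: %d x %d px, %d instances (ids %s)\n",
              d[1L], d[2L], length(ids),
              if (length(ids)) paste(range(ids), collapse = "..") else "-"))
})

setMethod("show", "PhantomScene", function(object) {
  d <- dim(object@masks@oralCavity)
  cat(sprintf("PhantomScene: %d x %d px, %d instances, seed %d\n",
              d[1L], d[2L], nrow(object@truth), object@spec@seed))
  cat(sprintf("  true RBL%%: %s\n",
              paste(format(object@truth$rbl_percent, digits = 3), collapse = " ")))
})

setMethod("show", "LevelCurve", function(object) {
  cat(sprintf("LevelCurve (%s %s): %d columns on [%d, %d], y in [%.1f, %.1f]\n",
              object@jaw, object@kind, length(object@x),
              min(object@x), max(object@x), min(object@y), max(object@y)))
})

setMethod("show", "CentralMoments", function(object) {
  cat(sprintf("CentralMoments: m00=%g centroid=(%.2f, %.2f) mu20=%.3g mu11=%.3g mu02=%.3g\n",
              object@m00, object@centroid[1L], object@centroid[2L],
              object@mu20, object@mu11, object@mu02))
})

setMethod("show", "ToothAxis", function(object) {
  cat(sprintf(
    "ToothAxis id=%d (%s): angle %.2f deg from vertical, elongation %.2f, apex (%g, %g)\n",
    object@id, object@jaw, axisAngleFromVertical(object@direction),
    object@elongation, object@apex[1L], object@apex[2L]))
})

setMethod("show", "SegmenterOutput", function(object) {
  d <- dim(object@oralCavity)
  cat(sprintf("SegmenterOutput: %d x %d px probability rasters + labels\n",
              d[1L], d[2L]))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (nm in slotNames(object))
    cat(sprintf("  %s: %s\n", nm, format(slot(object, nm))))
})

## ---- accessors --------------------------------------------------------

#' Accessors for mask sets, scenes and curves
#'
#' `oralCavity()`, `cejMask()`, `instanceLabels()` return the raw rasters;
#' `instanceIds()` the sorted non-zero labels present; `instanceMask()` the
#' binary mask of one instance. `sceneMasks()`, `sceneTruth()`, `sceneSpec()`
#' unpack a [PhantomScene-class]. `curveSamples()` returns a curve as a
#' two-column `data.frame(x, y)`.
#'
#' @param x a [StructureMaskSet-class], [PhantomScene-class] or
#'   [LevelCurve-class] as appropriate.
#' @param jaw `"maxilla"` or `"mandible"` for `cejMask()`.
#' @param id instance label for `instanceMask()`.
#' @return matrices, ids, or data frames as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
oralCavity <- function(x) {
  if (is(x, "PhantomScene")) x <- x@masks
  x@oralCavity
}

#' @rdname accessors
#' @export
cejMask <- function(x, jaw = c("maxilla", "mandible")) {
  jaw <- match.arg(jaw)
  if (is(x, "PhantomScene")) x <- x@masks
  if (jaw == "maxilla") x@cejMaxilla else x@cejMandible
}

#' @rdname accessors
#' @export
instanceLabels <- function(x) {
  if (is(x, "PhantomScene")) x <- x@masks
  x@instances
}

#' @rdname accessors
#' @export
instanceIds <- function(x) {
  lab <- instanceLabels(x)
  ids <- sort(unique(as.vector(lab)))
  as.integer(ids[ids > 0L])
}

#' @rdname accessors
#' @export
instanceMask <- function(x, id) {
  lab <- instanceLabels(x)
  matrix(as.integer(lab == id), nrow(lab), ncol(lab))
}

#' @rdname accessors
#' @export
sceneMasks <- function(x) x@masks

#' @rdname accessors
#' @export
sceneTruth <- function(x) x@truth

#' @rdname accessors
#' @export
sceneSpec <- function(x) x@spec

#' @rdname accessors
#' @export
curveSamples <- function(x) data.frame(x = x@x, y = x@y)
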