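## Synthetic two-jaw phantom generator.
##
## The phantom is a "flattened arch": one horizontal row of teeth per jaw on
## a single raster, maxilla above mandible, apex-up for maxillary and
## apex-down for mandibular instances. The curved panoramic arch is not
## needed to exercise any of the downstream geometry. Teeth are tapered
## polygons (crown wider than root, root tapering to a narrow apex) so the
## apex is unambiguous; implants are straight-sided rectangles whose flat
## coronal end is the fixture top, the CEJ-equivalent reference.

#' Construct a phantom scene specification
#'
#' Per-tooth arguments (`lossFractions`, `tiltDegrees`, `implantFlags`)
#' accept a scalar, a length-`teethPerJaw` vector applied to both jaws, or a
#' `teethPerJaw x 2` matrix (columns maxilla, mandible).
#'
#' Defaults emulate a mid-resolution panoramic crop: 8 teeth per jaw,
#' 40 px crowns, a 72 px root and 36 px crown (2:1 root:crown height), and
#' 2 px of sinusoidal waviness on the inter-dental bone curve.
#'
#' @param imageHeight,imageWidth raster size in pixels.
#' @param teethPerJaw instances per jaw.
#' @param toothWidth,rootLength,crownLength tooth geometry in pixels.
#' @param lossFractions per-tooth bone-loss fraction in [0, 1].
#' @param tiltDegrees per-tooth axis tilt from vertical, degrees, |tilt| < 45.
#' @param implantFlags per-tooth logical.
#' @param curveWaviness bone-curve sinusoid amplitude between teeth, pixels.
#' @param seed integer seed; the only source of randomness.
#' @return a validated [PhantomSpec-class].
#' @export
#' @examples
#' spec <- phantomSpec(lossFractions = c(0, 0.1, 0.25, 0.5), teethPerJaw = 4L)
#' sceneTruth(generatePhantom(spec))$stage
phantomSpec <- function(imageHeight = 400L, imageWidth = 640L,
                        teethPerJaw = 8L, toothWidth = 40,
                        rootLength = 72, crownLength = 36,
                        lossFractions = 0.2, tiltDegrees = 0,
                        implantFlags = FALSE, curveWaviness = 2,
                        seed = 1L) {
  n <- as.integer(teethPerJaw)
  perTooth <- function(v, mode) {
    if (is.matrix(v)) m <- v
    else m <- matrix(rep_len(v, n), n, 2L)
    colnames(m) <- c("maxilla", "mandible")
    storage.mode(m) <- mode
    m
  }
  new("PhantomSpec",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      teethPerJaw = n, toothWidth = as.numeric(toothWidth),
      rootLength = as.numeric(rootLength), crownLength = as.numeric(crownLength),
      lossFractions = perTooth(lossFractions, "double"),
      tiltDegrees = perTooth(tiltDegrees, "double"),
      implantFlags = perTooth(implantFlags, "logical"),
      curveWaviness = as.numeric(curveWaviness), seed = as.integer(seed))
}

#' Draw a randomized phantom specification
#'
#' Losses are drawn uniformly from `lossRange` and tilts from `tiltRange`,
#' independently per tooth and jaw; all other parameters are the
#' [phantomSpec()] defaults unless overridden through `...`.
#'
#' @param seed integer seed.
#' @param teethPerJaw instances per jaw.
#' @param lossRange range the per-tooth loss fractions are drawn from.
#' @param tiltRange range (degrees) the per-tooth tilts are drawn from.
#' @param ... further arguments passed to [phantomSpec()].
#' @return a [PhantomSpec-class].
#' @export
randomPhantomSpec <- function(seed, teethPerJaw = 8L,
                              lossRange = c(0.02, 0.95),
                              tiltRange = c(-8, 8), ...) {
  n <- as.integer(teethPerJaw)
  .withLocalSeed(seed, {
    loss <- matrix(runif(2L * n, lossRange[1L], lossRange[2L]), n, 2L)
    tilt <- matrix(runif(2L * n, tiltRange[1L], tiltRange[2L]), n, 2L)
    phantomSpec(teethPerJaw = n, lossFractions = loss, tiltDegrees = tilt,
                seed = as.integer(seed), ...)
  })
}

#' Uniformly scale all pixel dimensions of a specification
#'
#' Multiplies every length-valued field (image size, tooth geometry,
#' waviness) by `factor`, keeping loss fractions, tilts, flags and seed.
#' Used to probe scale invariance of the dimensionless RBL ratio.
#'
#' @param spec a [PhantomSpec-class].
#' @param factor positive scale factor.
#' @return a [PhantomSpec-class].
#' @export
scalePhantomSpec <- function(spec, factor) {
  stopifnot(is(spec, "PhantomSpec"), factor > 0)
  phantomSpec(imageHeight = round(spec@imageHeight * factor),
              imageWidth = round(spec@imageWidth * factor),
              teethPerJaw = spec@teethPerJaw,
              toothWidth = spec@toothWidth * factor,
              rootLength = spec@rootLength * factor,
              crownLength = spec@crownLength * factor,
              lossFractions = spec@lossFractions,
              tiltDegrees = spec@tiltDegrees,
              implantFlags = spec@implantFlags,
              curveWaviness = spec@curveWaviness * factor,
              seed = spec@seed)
}

#' Per-tooth analytic geometry of a spec: apex, CEJ and bone anchor points.
#' Tilt is the signed angle of the axis line from vertical; the apical
#' direction is the orientation with negative y for maxilla (apex up) and
#' positive y for mandible (apex down).
#' @noRd
.phantomLayout <- function(spec) {
  n <- spec@teethPerJaw; w <- spec@toothWidth
  W <- spec@imageWidth; H <- spec@imageHeight
  gap <- (W - n * w) / (n + 1)
  centers <- gap * seq_len(n) + w * (seq_len(n) - 1L) + w / 2
  apexMargin <- round(0.1 * H)
  out <- vector("list", 2L * n)
  for (j in 1:2) {
    jaw <- c("maxilla", "mandible")[j]
    for (i in seq_len(n)) {
      t <- spec@tiltDegrees[i, j] * pi / 180
      u <- c(sin(t), cos(t))                      # axis line, downward-ish
      apical <- if (jaw == "maxilla") -u else u
      coronal <- -apical
      apex <- c(centers[i],
                if (jaw == "maxilla") apexMargin else H - 1 - apexMargin)
      loss <- spec@lossFractions[i, j]
      out[[(j - 1L) * n + i]] <- list(
        id = (j - 1L) * n + i, jaw = jaw, index = i,
        kind = if (spec@implantFlags[i, j]) "implant" else "tooth",
        loss = loss, tiltDeg = spec@tiltDegrees[i, j],
        apical = apical, coronal = coronal, apex = apex,
        cej = apex + spec@rootLength * coronal,
        bone = apex + (1 - loss) * spec@rootLength * coronal)
    }
  }
  out
}

#' Tooth/implant outline polygon in image coordinates.
#' @noRd
.toothPolygon <- function(tooth, spec, part = c("full", "crown")) {
  part <- match.arg(part)
  w <- spec@toothWidth; rl <- spec@rootLength; cl <- spec@crownLength
  crownHalf <- w / 2
  if (tooth$kind == "implant") {
    half <- 0.35 * w                      # straight-sided fixture
    local <- if (part == "full")
      cbind(c(-half, half, half, -half), c(0, 0, rl + cl, rl + cl))
    else
      cbind(c(-half, half, half, -half), c(rl, rl, rl + cl, rl + cl))
  } else {
    rootHalf <- 0.3 * w; apexHalf <- 1
    local <- if (part == "full")
      cbind(c(-apexHalf, apexHalf, rootHalf, crownHalf, crownHalf,
              -crownHalf, -crownHalf, -rootHalf),
            c(0, 0, rl, rl, rl + cl, rl + cl, rl, rl))
    else
      cbind(c(crownHalf, crownHalf, -crownHalf, -crownHalf),
            c(rl, rl + cl, rl + cl, rl))
  }
  nvec <- c(tooth$coronal[2L], -tooth$coronal[1L])  # across-axis unit vector
  t(tooth$apex + tooth$coronal %o% local[, 2L] + nvec %o% local[, 1L])
}

#' Piecewise-linear curve through anchors, flat beyond the outermost ones,
#' with a sinusoid between anchors that vanishes at every anchor. The
#' sinusoid period is a length (pixels) so that uniformly scaled specs
#' produce geometrically similar curves.
#' @noRd
.boneCurveY <- function(anchors, xs, amplitude, phase, period = 57) {
  ord <- order(anchors[, 1L])
  ax <- anchors[ord, 1L]; ay <- anchors[ord, 2L]
  y <- approx(ax, ay, xout = pmin(pmax(xs, ax[1L]), ax[length(ax)]),
              rule = 2, ties = "ordered")$y
  if (amplitude > 0) {
    seg <- findInterval(xs, ax)
    inside <- seg >= 1L & seg < length(ax)
    if (any(inside)) {
      x0 <- ax[seg[inside]]; x1 <- ax[seg[inside] + 1L]
      frac <- (xs[inside] - x0) / (x1 - x0)
      y[inside] <- y[inside] +
        amplitude * sin(pi * frac) * sin(2 * pi * xs[inside] / period + phase)
    }
  }
  y
}

#' Magnify a mask set by integer pixel replication
#'
#' Replicates every pixel into a `factor x factor` block, emulating a
#' uniformly magnified acquisition of the same scene. All lengths scale by
#' `factor`, so dimensionless quantities (RBL percentages, stages) must be
#' unaffected up to rasterization error.
#'
#' @param maskSet a [StructureMaskSet-class] (or [PhantomScene-class], in
#'   which case its masks are scaled).
#' @param factor positive integer magnification.
#' @return a [StructureMaskSet-class].
#' @export
scaleMaskSet <- function(maskSet, factor) {
  if (is(maskSet, "PhantomScene")) maskSet <- maskSet@masks
  stopifnot(is(maskSet, "StructureMaskSet"), factor >= 1,
            factor == round(factor))
  up <- function(m) m[rep(seq_len(nrow(m)), each = factor),
                      rep(seq_len(ncol(m)), each = factor)]
  new("StructureMaskSet", oralCavity = up(maskSet@oralCavity),
      cejMaxilla = up(maskSet@cejMaxilla),
      cejMandible = up(maskSet@cejMandible),
      instances = up(maskSet@instances))
}

#' Generate a synthetic two-jaw scene with known ground truth
#'
#' Renders the four pipeline rasters (oral cavity enclosed by the two
#' periodontal bone level curves, one crown band per jaw, labeled
#' instances) plus a per-tooth truth table. Deterministic for a fixed seed.
#' By construction the bone-level curve passes through each tooth's axis at
#' distance `(1 - loss) * rootLength` from the apex, so the true RBL
#' percentage is exactly `100 * loss`.
#'
#' Instance ids are 1..n for the maxilla (left to right) and n+1..2n for
#' the mandible. The crown band of each jaw is the union of the crown
#' polygons plus a thin connecting band following the CEJ level across the
#' whole image width, mimicking the single contiguous per-jaw annotation
#' the pipeline expects.
#'
#' @param spec a valid [PhantomSpec-class].
#' @return a [PhantomScene-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  H <- spec@imageHeight; W <- spec@imageWidth
  teeth <- .phantomLayout(spec)
  phase <- .withLocalSeed(spec@seed, runif(1L, 0, 2 * pi))
  xs <- 0:(W - 1L)

  ## bone-level curves through the per-tooth bone anchors
  curves <- list()
  for (jaw in c("maxilla", "mandible")) {
    anchors <- do.call(rbind, lapply(Filter(function(t) t$jaw == jaw, teeth),
                                     function(t) t$bone))
    curves[[jaw]] <- .boneCurveY(anchors, xs, spec@curveWaviness, phase,
                                 period = 0.8 * spec@rootLength)
  }

  ## oral cavity: per-column fill between the two bone curves
  ocav <- matrix(0L, H, W)
  top <- pmax(0L, as.integer(ceiling(curves$maxilla - 0.5)))
  bot <- pmin(H - 1L, as.integer(floor(curves$mandible + 0.5)))
  for (x in xs) if (top[x + 1L] <= bot[x + 1L])
    ocav[(top[x + 1L]:bot[x + 1L]) + 1L, x + 1L] <- 1L

  ## instances and crown bands
  inst <- matrix(0L, H, W)
  cej <- list(maxilla = matrix(0L, H, W), mandible = matrix(0L, H, W))
  for (tooth in teeth) {
    full <- rasterizePolygon(.toothPolygon(tooth, spec, "full"), H, W)
    clash <- unique(inst[full > 0L])
    clash <- clash[clash > 0L]
    if (length(clash))
      .perioStop("perio_bad_spec",
                 "teeth overlap: instance %d intersects instance(s) %s (tilt/toothWidth too large for the spacing)",
                 tooth$id, paste(clash, collapse = ", "))
    inst[full > 0L] <- tooth$id
    crown <- rasterizePolygon(.toothPolygon(tooth, spec, "crown"), H, W)
    cej[[tooth$jaw]][crown > 0L] <- 1L
  }

  ## thin connecting band along the CEJ level, full image width
  bandPx <- 5L
  for (jaw in c("maxilla", "mandible")) {
    anchors <- do.call(rbind, lapply(Filter(function(t) t$jaw == jaw, teeth),
                                     function(t) t$cej))
    yl <- round(.boneCurveY(anchors, xs, 0, 0))
    for (x in xs) {
      rows <- if (jaw == "maxilla") yl[x + 1L] + 0:(bandPx - 1L)
              else yl[x + 1L] - 0:(bandPx - 1L)
      rows <- rows[rows >= 0L & rows <= H - 1L]
      cej[[jaw]][rows + 1L, x + 1L] <- 1L
    }
  }

  truth <- do.call(rbind, lapply(teeth, function(t) data.frame(
    id = t$id, jaw = t$jaw, kind = t$kind,
    loss_fraction = t$loss, rbl_percent = 100 * t$loss,
    stage = stageFromRbl(100 * t$loss),
    axis_angle_deg = t$tiltDeg, apex_x = t$apex[1L], apex_y = t$apex[2L],
    stringsAsFactors = FALSE)))
  rownames(truth) <- NULL

  new("PhantomScene",
      masks = new("StructureMaskSet", oralCavity = ocav,
                  cejMaxilla = cej$maxilla, cejMandible = cej$mandible,
                  instances = inst),
      truth = truth, spec = spec)
}
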