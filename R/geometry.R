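## Tooth long-axis estimation by principal axes of inertia.
##
## The long axis of an elongated shape is its minimum-inertia principal
## axis: the eigendirection of the 2x2 central second-moment matrix with
## the LARGER eigenvalue (mass spread furthest along it). Moments are taken
## over boundary pixels; a config switch allows filled-region moments for
## comparison.

#' Boundary pixels of an instance mask
#'
#' A mask pixel is boundary when at least one of its 4-neighbors is
#' background, or it lies on the raster border.
#'
#' @param instanceMask binary matrix, non-empty, single connected
#'   component.
#' @return two-column matrix of 0-based `(x, y)` pixel coordinates.
#' @export
boundaryPixels <- function(instanceMask) {
  m <- instanceMask > 0
  if (!any(m)) .perioStop("perio_empty_mask", "instance mask is empty")
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  interior <- core &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  .maskPixels(core & !interior)
}

#' Central geometric moments of a pixel set
#'
#' Plain sums over the points: `m00` is the count, the centroid the
#' arithmetic mean, and `mu_pq = sum((x - xbar)^p (y - ybar)^q)`.
#' Coordinates may be real-valued (rotated point sets are fine).
#'
#' @param pixels two-column matrix of `(x, y)` coordinates, >= 3 rows.
#' @return a [CentralMoments-class].
#' @export
computeMoments <- function(pixels) {
  p <- as.matrix(pixels)
  if (nrow(p) < 3L)
    .perioStop("perio_degenerate",
               "need >= 3 pixels for moments, got %d", nrow(p))
  xb <- mean(p[, 1L]); yb <- mean(p[, 2L])
  dx <- p[, 1L] - xb; dy <- p[, 2L] - yb
  new("CentralMoments", m00 = nrow(p), centroid = c(xb, yb),
      mu20 = sum(dx * dx), mu11 = sum(dx * dy), mu02 = sum(dy * dy))
}

#' Principal axes of inertia from central moments
#'
#' Eigendecomposition of `[[mu20, mu11], [mu11, mu02]]`. The long axis is
#' the eigendirection with the larger eigenvalue — the axis of minimum
#' moment of inertia of the point set. Elongation is the eigenvalue ratio;
#' shapes below the isotropy threshold have no well-defined orientation
#' (near-fourfold symmetry) and raise an error. The sign of the returned
#' directions is unresolved here; [apicalDirection()] fixes it.
#'
#' @param moments a [CentralMoments-class].
#' @param isotropyThreshold minimum eigenvalue ratio (default 1.2).
#' @return list with `longDir`, `shortDir` (unit vectors) and `elongation`.
#' @export
principalAxes <- function(moments, isotropyThreshold = 1.2) {
  stopifnot(is(moments, "CentralMoments"))
  M <- matrix(c(moments@mu20, moments@mu11, moments@mu11, moments@mu02), 2L, 2L)
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values                       # decreasing
  elongation <- if (lam[2L] <= 0) Inf else lam[1L] / lam[2L]
  if (elongation < isotropyThreshold)
    .perioStop("perio_isotropic",
               "shape is near-isotropic (elongation %.3f < %.3f): long-axis orientation undefined",
               elongation, isotropyThreshold)
  longDir <- e$vectors[, 1L]; shortDir <- e$vectors[, 2L]
  list(longDir = longDir / sqrt(sum(longDir^2)),
       shortDir = shortDir / sqrt(sum(shortDir^2)),
       elongation = elongation)
}

#' Assign an instance to the maxilla or mandible
#'
#' The instance belongs to the maxilla when its centroid lies above the
#' midcurve — the per-column mean of the two bone-level curves, linearly
#' extended beyond their trimmed ends.
#'
#' @param centroid `(x, y)` instance centroid.
#' @param boneCurves list with `maxilla` and `mandible`
#'   [LevelCurve-class] objects.
#' @param imageWidth raster width, used to validate the centroid column.
#' @return `"maxilla"` or `"mandible"`.
#' @export
assignJawSide <- function(centroid, boneCurves, imageWidth = Inf) {
  x <- centroid[[1L]]
  if (x < 0 || x > imageWidth - 1)
    .perioStop("perio_bad_input", "centroid column %.1f outside image", x)
  mid <- (.curveValueAt(boneCurves$maxilla, x) +
            .curveValueAt(boneCurves$mandible, x)) / 2
  if (centroid[[2L]] < mid) "maxilla" else "mandible"
}

#' Resolve the apical orientation of a long axis
#'
#' Flips the unit long-axis direction so that it points toward the root
#' apex: negative y (up) for maxillary instances, positive y (down) for
#' mandibular ones. A horizontal axis cannot belong to a stageable tooth
#' and raises an error.
#'
#' @param longDir unit direction (either orientation).
#' @param jaw `"maxilla"` or `"mandible"`.
#' @return apical-pointing unit vector.
#' @export
apicalDirection <- function(longDir, jaw = c("maxilla", "mandible")) {
  jaw <- match.arg(jaw)
  if (longDir[[2L]] == 0)
    .perioStop("perio_horizontal_axis",
               "long axis is horizontal: apical direction undefined")
  wantNeg <- jaw == "maxilla"
  if ((longDir[[2L]] < 0) == wantNeg) longDir else -longDir
}

#' Find the root apex pixel
#'
#' The mask pixel with maximal scalar projection onto the apical
#' direction; ties are broken by minimal perpendicular distance to the
#' long-axis line through the centroid, then by smaller x. Constraining
#' the apex to mask pixels keeps it inside the instance even for tilted
#' teeth. For implants this returns the apical-extreme fixture pixel.
#'
#' @param instanceMask binary matrix.
#' @param apicalDir unit apical direction.
#' @param centroid `(x, y)` centroid defining the axis line.
#' @return `(x, y)` of the apex pixel.
#' @export
findApex <- function(instanceMask, apicalDir, centroid) {
  px <- .maskPixels(instanceMask)
  if (!nrow(px)) .perioStop("perio_empty_mask", "instance mask is empty")
  proj <- px[, 1L] * apicalDir[[1L]] + px[, 2L] * apicalDir[[2L]]
  cand <- which(proj > max(proj) - 1e-9)
  if (length(cand) > 1L) {
    perp <- abs((px[cand, 1L] - centroid[[1L]]) * apicalDir[[2L]] -
                  (px[cand, 2L] - centroid[[2L]]) * apicalDir[[1L]])
    cand <- cand[perp < min(perp) + 1e-9]
    if (length(cand) > 1L) cand <- cand[which.min(px[cand, 1L])]
  }
  unname(c(px[cand[1L], 1L], px[cand[1L], 2L]))
}

#' Full long-axis geometry of one instance
#'
#' Chains [boundaryPixels()] (or the filled mask, per
#' `config@momentSource`), [computeMoments()], [principalAxes()],
#' [assignJawSide()], [apicalDirection()] and [findApex()].
#'
#' @param instanceMask binary matrix of the instance.
#' @param id instance label.
#' @param boneCurves list of the two bone-level curves (for jaw
#'   assignment).
#' @param config a [PipelineConfig-class].
#' @return a [ToothAxis-class].
#' @export
computeToothAxis <- function(instanceMask, id, boneCurves,
                             config = pipelineConfig()) {
  px <- if (config@momentSource == "boundary") boundaryPixels(instanceMask)
        else .maskPixels(instanceMask)
  mom <- computeMoments(px)
  axes <- principalAxes(mom, config@isotropyThreshold)
  jaw <- assignJawSide(mom@centroid, boneCurves, ncol(instanceMask))
  apical <- apicalDirection(axes$longDir, jaw)
  apex <- findApex(instanceMask, apical, mom@centroid)
  new("ToothAxis", id = as.integer(id), jaw = jaw, centroid = mom@centroid,
      direction = apical, elongation = axes$elongation, apex = apex)
}
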