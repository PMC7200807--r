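## RBL measurement and periodontitis staging.
##
## RBL convention: the printed ratio of the two intersection lengths
## (d_pbl / d_cej) equals 1 for a healthy tooth, which contradicts
## "RBL < 15%" describing near-health, so the default reports the loss
## 100 * (d_cej - d_pbl) / d_cej; `rblConvention = "remaining"` gives the
## literal ratio. Staging always uses the loss value, so both conventions
## assign identical stages.

#' Intersect a tooth's long axis with a level curve
#'
#' Intersects the infinite line through `centroid` with direction
#' `apicalDir` against the piecewise-linear curve (gaps up to `gapSpan`
#' columns are bridged linearly). Among all crossings whose x lies within
#' the tooth's column extent expanded by 25% on each side, the one closest
#' to the centroid is returned; several candidates set the
#' `multiple_crossings` flag, and a crossing on a bridged gap segment sets
#' `gap_interpolated`.
#'
#' @param centroid `(x, y)` point on the axis.
#' @param apicalDir unit axis direction.
#' @param curve a [LevelCurve-class].
#' @param toothXExtent numeric length-2, the instance's column range.
#' @param gapSpan largest bridged gap in columns (default 40).
#' @param id optional instance id used in error messages.
#' @return list with `point` (`(x, y)`) and `flags` (character vector).
#' @export
intersectAxisCurve <- function(centroid, apicalDir, curve, toothXExtent,
                               gapSpan = 40, id = NULL) {
  stopifnot(is(curve, "LevelCurve"))
  segs <- .curveSegments(curve, gapSpan)
  who <- if (is.null(id)) "" else sprintf(" (instance %s)", id)
  if (!nrow(segs))
    .perioStop("perio_no_intersection",
               "curve has no segments to intersect%s", who)
  dx <- apicalDir[[1L]]; dy <- apicalDir[[2L]]
  ex <- segs$x1 - segs$x0; ey <- segs$y1 - segs$y0
  det <- ex * dy - ey * dx
  ok <- abs(det) > 1e-12
  bx <- segs$x0 - centroid[[1L]]; by <- segs$y0 - centroid[[2L]]
  t <- rep(NA_real_, nrow(segs)); s <- t
  ## solve centroid + t*d = P0 + s*e
  t[ok] <- (ex[ok] * by[ok] - ey[ok] * bx[ok]) / det[ok]
  s[ok] <- (dx * by[ok] - dy * bx[ok]) / det[ok]
  hit <- which(ok & s >= 0 & s < 1)           # half-open: shared vertices once
  if (length(hit)) {
    pxs <- centroid[[1L]] + t[hit] * dx
    w <- diff(range(toothXExtent))
    win <- c(min(toothXExtent) - 0.25 * w, max(toothXExtent) + 0.25 * w)
    inWin <- pxs >= win[1L] & pxs <= win[2L]
    hit <- hit[inWin]; pxs <- pxs[inWin]
  }
  if (!length(hit))
    .perioStop("perio_no_intersection",
               "axis does not cross the %s %s curve within the tooth extent%s",
               curve@jaw, curve@kind, who)
  pys <- centroid[[2L]] + t[hit] * dy
  pts <- cbind(pxs, pys)
  dup <- duplicated(round(pts, 9L))
  hit <- hit[!dup]; pts <- pts[!dup, , drop = FALSE]
  best <- which.min(abs(t[hit]))
  flags <- character(0)
  if (length(hit) > 1L) flags <- c(flags, "multiple_crossings")
  if (segs$gap[hit[best]]) flags <- c(flags, "gap_interpolated")
  list(point = unname(c(pts[best, 1L], pts[best, 2L])), flags = flags)
}

#' Compute the RBL percentage from apex and intersection points
#'
#' `d_cej` and `d_pbl` are the Euclidean distances from the root apex to
#' the CEJ-level and bone-level intersection points. The loss percentage
#' `100 * (d_cej - d_pbl) / d_cej` is clamped to [0, 100] with
#' `clamped_low` / `clamped_high` flags when the raw value falls outside
#' (possible with noisy masks).
#'
#' @param apex,pblPoint,cejPoint `(x, y)` points.
#' @param convention `"loss"` (default) or `"remaining"` for the reported
#'   `rbl_percent`; staging semantics are unaffected.
#' @param eps minimum admissible `d_cej` in pixels (default 1).
#' @return list with `d_pbl`, `d_cej`, `rbl_percent`, `loss_percent`,
#'   `flags`.
#' @export
computeRbl <- function(apex, pblPoint, cejPoint,
                       convention = c("loss", "remaining"), eps = 1) {
  convention <- match.arg(convention)
  dCej <- sqrt(sum((apex - cejPoint)^2))
  if (dCej <= eps)
    .perioStop("perio_degenerate_root",
               "apex-to-CEJ length %.3f px <= %g px: degenerate root", dCej, eps)
  dPbl <- sqrt(sum((apex - pblPoint)^2))
  raw <- 100 * (dCej - dPbl) / dCej
  flags <- character(0)
  if (raw < 0) flags <- c(flags, "clamped_low")
  if (raw > 100) flags <- c(flags, "clamped_high")
  loss <- min(max(raw, 0), 100)
  list(d_pbl = dPbl, d_cej = dCej,
       rbl_percent = if (convention == "loss") loss else 100 - loss,
       loss_percent = loss, flags = flags)
}

#' Stage periodontitis from the RBL percentage
#'
#' 2017 World Workshop radiographic criteria: RBL below 15% (coronal third
#' of the root) is stage 1; between 15% and 33% stage 2; above 33%
#' (middle third and beyond) stage 3. Boundaries follow the strict
#' inequalities of stages 1 and 3, so exactly 15 and exactly 33 are stage
#' 2. Stages beyond 3 are not determinable from RBL alone and are never
#' emitted.
#'
#' @param rblPercent numeric vector in [0, 100] (loss convention).
#' @return integer vector of stages in \{1, 2, 3\}.
#' @export
#' @examples
#' stageFromRbl(c(10, 20, 40))  # 1 2 3
stageFromRbl <- function(rblPercent) {
  if (any(!is.finite(rblPercent)) || any(rblPercent < 0 | rblPercent > 100))
    .perioStop("perio_bad_input", "rblPercent must lie in [0, 100]")
  ifelse(rblPercent < 15, 1L, ifelse(rblPercent <= 33, 2L, 3L))
}

#' Stage every instance of a mask set
#'
#' Orchestrates the full conventional-CAD half of the pipeline:
#' binarization, bone and CEJ level-curve extraction (with optional median
#' smoothing), per-instance long-axis estimation, axis-curve
#' intersections, RBL computation and staging. Instances that fail
#' (no intersection, isotropic shape, horizontal axis, degenerate root)
#' are reported with an `NA` stage and the error reason instead of
#' aborting the batch; global failures (no usable oral-cavity mask) abort.
#'
#' @param maskSet a [StructureMaskSet-class] (binary or probability
#'   rasters).
#' @param config a [PipelineConfig-class].
#' @param kinds optional named character vector mapping instance ids to
#'   `"tooth"` / `"implant"`; unknown ids default to `"tooth"`.
#' @return `data.frame` with one row per instance: `id, jaw, kind,
#'   d_cej_px, d_pbl_px, rbl_percent, stage, flags, error` plus the
#'   intersection points (`pbl_x, pbl_y, cej_x, cej_y`), `apex_x, apex_y`
#'   and `axis_angle_deg`.
#' @export
stageAll <- function(maskSet, config = pipelineConfig(), kinds = NULL) {
  stopifnot(is(maskSet, "StructureMaskSet"))
  ocav <- binarize(maskSet@oralCavity, config@binarizeThreshold)
  boneCurves <- extractBoneLevelCurves(ocav, config@lateralTrimFraction)
  cejCurves <- list(
    maxilla = extractCejCurve(binarize(maskSet@cejMaxilla,
                                       config@binarizeThreshold),
                              "maxilla", config@lateralTrimFraction),
    mandible = extractCejCurve(binarize(maskSet@cejMandible,
                                        config@binarizeThreshold),
                               "mandible", config@lateralTrimFraction))
  if (config@smoothingWindow > 1L) {
    boneCurves <- lapply(boneCurves, smoothCurve, window = config@smoothingWindow)
    cejCurves <- lapply(cejCurves, smoothCurve, window = config@smoothingWindow)
  }
  ids <- instanceIds(maskSet)
  rows <- lapply(ids, function(id) {
    kind <- if (!is.null(kinds) && as.character(id) %in% names(kinds))
      kinds[[as.character(id)]] else "tooth"
    base <- data.frame(id = id, jaw = NA_character_, kind = kind,
                       d_cej_px = NA_real_, d_pbl_px = NA_real_,
                       rbl_percent = NA_real_, stage = NA_integer_,
                       flags = "", error = NA_character_,
                       pbl_x = NA_real_, pbl_y = NA_real_,
                       cej_x = NA_real_, cej_y = NA_real_,
                       apex_x = NA_real_, apex_y = NA_real_,
                       axis_angle_deg = NA_real_, stringsAsFactors = FALSE)
    tryCatch({
      m <- instanceMask(maskSet, id)
      axis <- computeToothAxis(m, id, boneCurves, config)
      xext <- range(.maskPixels(m)[, 1L])
      pbl <- intersectAxisCurve(axis@centroid, axis@direction,
                                boneCurves[[axis@jaw]], xext,
                                config@gapInterpolationSpanPx, id)
      cej <- intersectAxisCurve(axis@centroid, axis@direction,
                                cejCurves[[axis@jaw]], xext,
                                config@gapInterpolationSpanPx, id)
      rbl <- computeRbl(axis@apex, pbl$point, cej$point,
                        config@rblConvention)
      offAxis <- abs((axis@apex[1L] - axis@centroid[1L]) * axis@direction[2L] -
                       (axis@apex[2L] - axis@centroid[2L]) * axis@direction[1L])
      .log("INFO", "instance %d (%s, %s): d_cej=%.2f d_pbl=%.2f rbl=%.2f stage=%d apex-axis offset=%.2f px",
           id, axis@jaw, kind, rbl$d_cej, rbl$d_pbl, rbl$rbl_percent,
           stageFromRbl(rbl$loss_percent), offAxis)
      base$jaw <- axis@jaw
      base$d_cej_px <- rbl$d_cej; base$d_pbl_px <- rbl$d_pbl
      base$rbl_percent <- rbl$rbl_percent
      base$stage <- stageFromRbl(rbl$loss_percent)
      base$flags <- paste(unique(c(pbl$flags, cej$flags, rbl$flags)),
                          collapse = "|")
      base$pbl_x <- pbl$point[1L]; base$pbl_y <- pbl$point[2L]
      base$cej_x <- cej$point[1L]; base$cej_y <- cej$point[2L]
      base$apex_x <- axis@apex[1L]; base$apex_y <- axis@apex[2L]
      base$axis_angle_deg <- axisAngleFromVertical(axis@direction)
      base
    }, perioError = function(e) {
      .log("WARN", "instance %d failed: %s", id, conditionMessage(e))
      base$error <- conditionMessage(e)
      base
    })
  })
  do.call(rbind, rows)
}
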