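## Level-curve extraction: binarization, per-column edge extraction of the
## oral-cavity and crown-band masks, optional median smoothing.
##
## "Edge of the binary image" is realized as per-column extremal boundary
## rows rather than a generic contour trace: that yields exactly one y per
## column, which the axis-intersection step requires, and ignores the
## lateral walls of the enclosed region, which carry no bone-level
## information.

#' Threshold a probability raster
#'
#' @param probRaster numeric matrix with values in [0, 1].
#' @param threshold scalar in (0, 1); pixels with value `>= threshold`
#'   become 1 (ties at the threshold are foreground).
#' @return integer matrix in \{0, 1\}.
#' @export
binarize <- function(probRaster, threshold = 0.5) {
  .checkProbRaster(probRaster, "probRaster")
  if (threshold <= 0 || threshold >= 1)
    .perioStop("perio_bad_input", "threshold must lie in (0, 1), got %g",
               threshold)
  matrix(as.integer(probRaster >= threshold),
         nrow(probRaster), ncol(probRaster))
}

#' Locate the single dominant component; error when several large ones.
#' Specks below 1% of the largest component (or < 10 px) are ignored.
#' @noRd
.dominantComponent <- function(mask, what) {
  lab <- .labelComponents(mask)
  ncomp <- max(lab)
  if (ncomp == 0L)
    .perioStop("perio_empty_mask", "%s mask is empty", what)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  big <- which(sizes >= max(10, 0.01 * max(sizes)))
  if (length(big) > 1L)
    .perioStop("perio_multi_component",
               "%s mask has %d large components (sizes: %s)", what,
               length(big), paste(sort(sizes, decreasing = TRUE), collapse = ", "))
  matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
}

#' Per-column extremal rows of a mask over a retained column range.
#' @noRd
.columnExtremes <- function(mask, trimFraction) {
  colsWith <- which(colSums(mask) > 0L)
  x0 <- min(colsWith) - 1L; x1 <- max(colsWith) - 1L      # 0-based extent
  ncols <- x1 - x0 + 1L
  k <- round(trimFraction * ncols)
  xs <- seq.int(x0 + k, x1 - k)
  top <- rep(NA_integer_, length(xs)); bot <- top
  for (i in seq_along(xs)) {
    rows <- which(mask[, xs[i] + 1L] > 0L)
    if (length(rows)) { top[i] <- rows[1L] - 1L; bot[i] <- rows[length(rows)] - 1L }
  }
  keep <- !is.na(top)
  list(x = xs[keep], top = top[keep], bottom = bot[keep])
}

#' Extract the two periodontal bone level curves
#'
#' The oral-cavity mask is the region enclosed by the maxillary and
#' mandibular periodontal bone levels, so for each retained column its
#' topmost mask row is the maxillary bone level and its bottommost row the
#' mandibular one. Columns within `lateralTrimFraction` of each end of the
#' component's column extent are dropped: detection errors concentrate at
#' the lateral walls, which carry no bone-level information.
#'
#' @param oralCavityMask binary matrix with one dominant connected
#'   component spanning more than 10 columns.
#' @param lateralTrimFraction fraction of the column extent trimmed at each
#'   side (default 0.05).
#' @return list with elements `maxilla` and `mandible`, each a
#'   [LevelCurve-class] of kind `"bone_level"`.
#' @export
extractBoneLevelCurves <- function(oralCavityMask, lateralTrimFraction = 0.05) {
  comp <- .dominantComponent(oralCavityMask, "oral cavity")
  if (diff(range(which(colSums(comp) > 0L))) + 1L <= 10L)
    .perioStop("perio_bad_input", "oral cavity component spans <= 10 columns")
  ext <- .columnExtremes(comp, lateralTrimFraction)
  if (!length(ext$x))
    .perioStop("perio_bad_input", "no columns left after lateral trimming")
  list(maxilla = new("LevelCurve", jaw = "maxilla", kind = "bone_level",
                     x = as.integer(ext$x), y = as.numeric(ext$top)),
       mandible = new("LevelCurve", jaw = "mandible", kind = "bone_level",
                      x = as.integer(ext$x), y = as.numeric(ext$bottom)))
}

#' Extract a CEJ level curve from a crown-band mask
#'
#' Crowns hang toward the occlusal plane, so the CEJ (apical) edge of the
#' band is its topmost row per column for the maxilla and its bottommost
#' row for the mandible. Lateral trimming matches
#' [extractBoneLevelCurves()]. Columns with no band pixels are absent from
#' the curve, so the result may consist of several monotone runs.
#'
#' @param cejBandMask binary matrix (may have several components).
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param lateralTrimFraction fraction trimmed at each lateral end.
#' @return a [LevelCurve-class] of kind `"cej_level"`.
#' @export
extractCejCurve <- function(cejBandMask, jaw = c("maxilla", "mandible"),
                            lateralTrimFraction = 0.05) {
  jaw <- match.arg(jaw)
  if (!any(cejBandMask > 0))
    .perioStop("perio_empty_mask", "CEJ band mask is empty")
  ext <- .columnExtremes(cejBandMask, lateralTrimFraction)
  if (!length(ext$x))
    .perioStop("perio_bad_input", "no CEJ columns left after lateral trimming")
  new("LevelCurve", jaw = jaw, kind = "cej_level",
      x = as.integer(ext$x),
      y = as.numeric(if (jaw == "maxilla") ext$top else ext$bottom))
}

#' Median-smooth a level curve
#'
#' Per-sample running median over the curve's sample sequence (column gaps
#' are ignored; the window counts samples). Endpoints use symmetric
#' shrunken windows. `window = 1` is the identity; smoothing is off by
#' default in the pipeline.
#'
#' @param curve a [LevelCurve-class].
#' @param window odd integer >= 1.
#' @return a [LevelCurve-class] with smoothed `y`.
#' @export
smoothCurve <- function(curve, window) {
  stopifnot(is(curve, "LevelCurve"))
  if (window < 1 || window %% 2 == 0)
    .perioStop("perio_bad_input", "window must be odd and >= 1, got %g", window)
  if (window == 1) return(curve)
  h <- (window - 1L) %/% 2L
  n <- length(curve@y)
  y <- vapply(seq_len(n), function(i) {
    r <- max(1L, i - h):min(n, i + h)
    median(curve@y[r])
  }, numeric(1L))
  initialize(curve, y = y)
}

#' Export a curve as two-column CSV
#'
#' @param curve a [LevelCurve-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  write.csv(curveSamples(curve), path, row.names = FALSE)
  invisible(path)
}

#' Curve y-value at arbitrary x: linear interpolation inside the sampled
#' range (across gaps too), linear extrapolation with the end slope
#' outside it.
#' @noRd
.curveValueAt <- function(curve, x) {
  cx <- curve@x; cy <- curve@y
  n <- length(cx)
  if (n == 1L) return(rep(cy, length(x)))
  y <- approx(cx, cy, xout = x, rule = 2, ties = "ordered")$y
  lo <- x < cx[1L]; hi <- x > cx[n]
  if (any(lo)) {
    s <- (cy[2L] - cy[1L]) / (cx[2L] - cx[1L])
    y[lo] <- cy[1L] + s * (x[lo] - cx[1L])
  }
  if (any(hi)) {
    s <- (cy[n] - cy[n - 1L]) / (cx[n] - cx[n - 1L])
    y[hi] <- cy[n] + s * (x[hi] - cx[n])
  }
  y
}

#' Decompose a curve into line segments connecting consecutive samples.
#' Adjacent columns always connect; gaps of up to `gapSpan` columns are
#' bridged (marked `gap = TRUE`); larger gaps break the polyline.
#' @noRd
.curveSegments <- function(curve, gapSpan) {
  n <- length(curve@x)
  if (n < 2L)
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), gap = logical(0)))
  dx <- diff(curve@x)
  keep <- dx <= pmax(1, gapSpan)
  data.frame(x0 = curve@x[-n][keep], y0 = curve@y[-n][keep],
             x1 = curve@x[-1L][keep], y1 = curve@y[-1L][keep],
             gap = dx[keep] > 1L)
}
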