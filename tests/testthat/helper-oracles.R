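# Independent oracles used across the suite. Each re-derives the quantity
# it checks by a different route than the implementation (per-pixel
# parity instead of scanline pairing, aov() instead of mean-square
# algebra, per-segment solve() instead of the vectorized Cramer form).

# Small phantom used where full-size scenes would be wasteful.
smallSpec <- function(seed = 1L, teethPerJaw = 4L, loss = 0.3, tilt = 0,
                      ...) {
  phantomSpec(imageHeight = 300L, imageWidth = 320L,
              teethPerJaw = teethPerJaw, toothWidth = 30,
              rootLength = 60, crownLength = 30,
              lossFractions = loss, tiltDegrees = tilt, seed = seed, ...)
}

mkCurve <- function(x, y, jaw = "maxilla", kind = "bone_level") {
  new("LevelCurve", jaw = jaw, kind = kind, x = as.integer(x),
      y = as.numeric(y))
}

# Per-pixel even-odd parity point-in-polygon with the same half-open
# boundary semantics as the rasterizer: an edge spans [ymin, ymax) and a
# crossing strictly right of the pixel center flips parity.
pipOracle <- function(poly, height, width) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- x1[c(2:n, 1)]; y2 <- y1[c(2:n, 1)]
  px <- matrix(rep(0:(width - 1), each = height), height, width)
  py <- matrix(rep(0:(height - 1), width), height, width)
  crossings <- matrix(0L, height, width)
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next
    inY <- (pmin(y1[e], y2[e]) <= py) & (py < pmax(y1[e], y2[e]))
    xc <- x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
    crossings <- crossings + (inY & xc > px)
  }
  matrix(as.integer(crossings %% 2L == 1L), height, width)
}

# Random simple (star-shaped) polygon in a 64x64 frame.
randomStarPolygon <- function(k = 8L) {
  ang <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, 5, 26)
  cbind(31.5 + r * cos(ang), 31.5 + r * sin(ang))
}

# Per-column scan: first/last foreground row of each column, no trimming.
columnScanOracle <- function(mask) {
  cols <- which(colSums(mask) > 0)
  top <- integer(0); bot <- integer(0); xs <- integer(0)
  for (cc in cols) {
    rows <- which(mask[, cc] > 0)
    xs <- c(xs, cc - 1L)
    top <- c(top, rows[1] - 1L)
    bot <- c(bot, rows[length(rows)] - 1L)
  }
  list(x = xs, top = top, bottom = bot)
}

# TRUE when pixel (x, y) is foreground and touches background through a
# 4-neighbor or the raster border.
onBoundary4 <- function(mask, x, y) {
  h <- nrow(mask); w <- ncol(mask)
  if (mask[y + 1, x + 1] == 0) return(FALSE)
  if (x == 0 || y == 0 || x == w - 1 || y == h - 1) return(TRUE)
  mask[y, x + 1] == 0 || mask[y + 2, x + 1] == 0 ||
    mask[y + 1, x] == 0 || mask[y + 1, x + 2] == 0
}

# Naive two-pass product-moment correlation.
pearsonOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# ICC(2,1) from the mean squares of a fitted two-way aov().
iccOracleAov <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  case = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ case + rater, data = d))[[1]]
  ms <- stats::setNames(a[["Mean Sq"]], trimws(rownames(a)))
  (ms[["case"]] - ms[["Residuals"]]) /
    (ms[["case"]] + (k - 1) * ms[["Residuals"]] +
       k / n * (ms[["rater"]] - ms[["Residuals"]]))
}

# Exhaustive per-segment line/polyline intersection with the stated
# selection rule (window filter, then closest to the centroid).
segIntersectOracle <- function(centroid, dir, curve, xext, gapSpan = 40) {
  df <- curveSamples(curve)
  cand <- NULL
  for (i in seq_len(nrow(df) - 1)) {
    if (df$x[i + 1] - df$x[i] > gapSpan) next
    A <- matrix(c(dir[1], dir[2],
                  -(df$x[i + 1] - df$x[i]), -(df$y[i + 1] - df$y[i])), 2, 2)
    if (abs(det(A)) < 1e-12) next
    ts <- solve(A, c(df$x[i] - centroid[1], df$y[i] - centroid[2]))
    if (ts[2] >= 0 && ts[2] < 1)
      cand <- rbind(cand, c(t = ts[1],
                            x = centroid[1] + ts[1] * dir[1],
                            y = centroid[2] + ts[1] * dir[2]))
  }
  if (is.null(cand)) return(NULL)
  w <- diff(range(xext))
  inWin <- cand[, "x"] >= min(xext) - 0.25 * w &
    cand[, "x"] <= max(xext) + 0.25 * w
  cand <- cand[inWin, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  best <- which.min(abs(cand[, "t"]))
  list(point = unname(cand[best, c("x", "y")]), n = nrow(cand))
}

# Elongated Gaussian point cloud with a known long-axis angle from
# vertical (degrees).
elongatedBlob <- function(n = 400L, angleDeg = 0, sdLong = 10, sdShort = 2) {
  a <- angleDeg * pi / 180
  long <- rnorm(n, 0, sdLong); short <- rnorm(n, 0, sdShort)
  # long axis at angleDeg from vertical: direction (sin a, cos a)
  cbind(x = long * sin(a) + short * cos(a),
        y = long * cos(a) - short * sin(a))
}
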