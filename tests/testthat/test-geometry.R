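# Boundary pixels, central moments, principal axes, jaw/apex resolution.

test_that("boundary pixels are the 4-neighbor rim", {
  bar <- matrix(0L, 5, 9)
  bar[3, 3:7] <- 1L                          # 1x5 horizontal bar
  expect_equal(nrow(boundaryPixels(bar)), 5)

  sq <- matrix(0L, 9, 9)
  sq[3:7, 3:7] <- 1L                         # 5x5 filled square
  bp <- boundaryPixels(sq)
  expect_equal(nrow(bp), 16)                 # 25 - 9 interior

  one <- matrix(0L, 4, 4); one[2, 3] <- 1L
  expect_equal(boundaryPixels(one), cbind(x = 2, y = 1))

  expect_error(boundaryPixels(matrix(0L, 3, 3)), "empty")
})

test_that("central moments match hand arithmetic and are translation invariant", {
  m <- computeMoments(cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_equal(m@centroid, c(1, 0))
  expect_equal(m@mu20, 2)
  expect_equal(m@mu11, 0)
  expect_equal(m@mu02, 0)
  expect_error(computeMoments(cbind(0:1, 0:1)), ">= 3")

  set.seed(1)
  for (i in 1:20) {
    pts <- cbind(runif(30, 0, 50), runif(30, 0, 50))
    shifted <- sweep(pts, 2, c(13.7, -4.2), "+")
    a <- computeMoments(pts); b <- computeMoments(shifted)
    expect_equal(c(a@mu20, a@mu11, a@mu02), c(b@mu20, b@mu11, b@mu02),
                 tolerance = 1e-9)
  }
})

test_that("moments equal a naive two-pass summation oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    m <- computeMoments(pts)
    xb <- sum(pts[, 1]) / nrow(pts); yb <- sum(pts[, 2]) / nrow(pts)
    expect_equal(m@mu20, sum((pts[, 1] - xb)^2), tolerance = 1e-9)
    expect_equal(m@mu11, sum((pts[, 1] - xb) * (pts[, 2] - yb)), tolerance = 1e-9)
    expect_equal(m@mu02, sum((pts[, 2] - yb)^2), tolerance = 1e-9)
  }
})

test_that("principal axes recover bar, rotated rectangle and reject squares", {
  bar <- new("CentralMoments", m00 = 3, centroid = c(1, 0),
             mu20 = 2, mu11 = 0, mu02 = 0)
  ax <- principalAxes(bar)
  expect_equal(abs(ax$longDir), c(1, 0), tolerance = 1e-12)

  # 40x8 rectangle boundary rotated 30 deg about its center
  xs <- c(seq(-20, 20, by = 0.25), seq(-20, 20, by = 0.25),
          rep(c(-20, 20), each = 31))
  ys <- c(rep(-4, 161), rep(4, 161), rep(seq(-4, 4, length.out = 31), 2))
  a <- 30 * pi / 180
  # rotate so the long (horizontal) axis ends up 30 deg from vertical
  rot <- cbind(xs * sin(a) + ys * cos(a), xs * cos(a) - ys * sin(a))
  ax2 <- principalAxes(computeMoments(rot))
  expect_lt(abs(axisAngleFromVertical(ax2$longDir) - 30), 0.5)

  sq <- matrix(0L, 12, 12); sq[2:10, 2:10] <- 1L   # 9x9 square: fourfold symmetry
  expect_error(principalAxes(computeMoments(boundaryPixels(sq))), "isotropic")
})

test_that("closed-form moment angle matches the eigenvector angle", {
  set.seed(11)
  for (i in 1:30) {
    m <- computeMoments(elongatedBlob(300, runif(1, -89, 89)))
    ax <- principalAxes(m)
    theta <- 0.5 * atan2(2 * m@mu11, m@mu20 - m@mu02)  # major-eigenvector angle from +x
    closed <- axisAngleFromVertical(c(cos(theta), sin(theta)))
    expect_lt(abs(closed - axisAngleFromVertical(ax$longDir)) %% 180, 1e-6 * 180 / pi)
  }
})

test_that("rotating a pixel set rotates the long axis with it", {
  set.seed(3)
  base <- elongatedBlob(500, 0, sdLong = 12, sdShort = 2)  # elongation ~ 36
  a0 <- axisAngleFromVertical(principalAxes(computeMoments(base))$longDir)
  for (theta in c(10, 20, 30)) {
    r <- theta * pi / 180
    rot <- cbind(base[, 1] * cos(r) + base[, 2] * sin(r),
                 -base[, 1] * sin(r) + base[, 2] * cos(r))
    a1 <- axisAngleFromVertical(principalAxes(computeMoments(rot))$longDir)
    expect_lt(abs(a1 - (a0 + theta)), 1)
  }
})

test_that("jaw side comes from the bone-level midcurve", {
  curves <- list(maxilla = mkCurve(0:99, rep(40, 100)),
                 mandible = mkCurve(0:99, rep(60, 100), jaw = "mandible"))
  expect_equal(assignJawSide(c(50, 20), curves), "maxilla")
  expect_equal(assignJawSide(c(50, 80), curves), "mandible")
  expect_error(assignJawSide(c(-3, 20), curves, imageWidth = 100), "outside")
})

test_that("apical direction flips by jaw and rejects horizontal axes", {
  expect_equal(apicalDirection(c(0, 1), "maxilla"), c(0, -1))
  expect_equal(apicalDirection(c(0, 1), "mandible"), c(0, 1))
  expect_equal(apicalDirection(c(0, -1), "mandible"), c(0, 1))
  expect_error(apicalDirection(c(1, 0), "maxilla"), "horizontal")
})

test_that("apex ties on a flat top break toward the axis line", {
  rect <- matrix(0L, 30, 40)
  rect[6:25, 11:21] <- 1L                    # flat top row 5, cols 10..20
  apex <- findApex(rect, c(0, -1), centroid = c(15, 15))
  expect_equal(apex, c(15, 5))
})

test_that("phantom teeth recover jaw, apex and axis angle", {
  for (seed in 1:5) {
    spec <- smallSpec(seed = seed, loss = runif(4, 0.1, 0.8),
                      tilt = runif(4, -8, 8))
    scene <- generatePhantom(spec)
    curves <- extractBoneLevelCurves(binarize(oralCavity(scene) * 1.0))
    tr <- sceneTruth(scene)
    for (i in seq_len(nrow(tr))) {
      m <- instanceMask(scene, tr$id[i])
      ax <- computeToothAxis(m, tr$id[i], curves)
      expect_equal(ax@jaw, tr$jaw[i])
      expect_lt(max(abs(ax@apex - c(tr$apex_x[i], tr$apex_y[i]))), 2)
      expect_lt(abs(axisAngleFromVertical(ax@direction) - tr$axis_angle_deg[i]), 2)
    }
  }
})

test_that("axis recovery holds to 2 degrees up to 30-degree tilts", {
  for (tilt in c(-30, -20, 10, 30)) {
    spec <- phantomSpec(teethPerJaw = 2L, tiltDegrees = tilt,
                        lossFractions = 0.3)
    scene <- generatePhantom(spec)
    curves <- extractBoneLevelCurves(binarize(oralCavity(scene) * 1.0))
    for (id in instanceIds(sceneMasks(scene))) {
      ax <- computeToothAxis(instanceMask(scene, id), id, curves)
      expect_lt(abs(axisAngleFromVertical(ax@direction) - tilt), 2)
    }
  }
})

test_that("boundary and filled moments give compatible orientations", {
  scene <- generatePhantom(smallSpec(seed = 2L, tilt = c(-6, -2, 3, 7)))
  curves <- extractBoneLevelCurves(binarize(oralCavity(scene) * 1.0))
  cfgF <- pipelineConfig(momentSource = "filled")
  for (id in instanceIds(sceneMasks(scene))) {
    m <- instanceMask(scene, id)
    aB <- computeToothAxis(m, id, curves)
    aF <- computeToothAxis(m, id, curves, cfgF)
    expect_lt(abs(axisAngleFromVertical(aB@direction) -
                    axisAngleFromVertical(aF@direction)), 2)
  }
})
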