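# Binarization, per-column level-curve extraction, smoothing.

test_that("binarize applies the >= threshold convention", {
  r <- matrix(c(0.3, 0.7, 0.5, 0.0), 2, 2)
  expect_identical(binarize(r, 0.5), matrix(c(0L, 1L, 1L, 0L), 2, 2))
  expect_identical(binarize(matrix(0, 3, 3)), matrix(0L, 3, 3))
  expect_error(binarize(r, 1.5), "threshold")
  expect_error(binarize(matrix(c(-0.1, 2), 1, 2)), "\\[0, 1\\]")
})

test_that("bone curves are the per-column extremal rows with lateral trim", {
  mask <- matrix(0L, 40, 100)
  mask[11:21, ] <- 1L                       # rows 10..20, cols 0..99 (0-based)
  curves <- extractBoneLevelCurves(mask, lateralTrimFraction = 0.10)
  expect_identical(curves$maxilla@x, 10:89)
  expect_true(all(curves$maxilla@y == 10))
  expect_true(all(curves$mandible@y == 20))
  expect_s4_class(curves$maxilla, "LevelCurve")
  expect_equal(curves$maxilla@kind, "bone_level")
})

test_that("the maxillary curve follows a notch cut into the top edge", {
  mask <- matrix(0L, 40, 100)
  mask[11:21, ] <- 1L
  mask[11:15, 41:50] <- 0L                  # notch floor at row 15, cols 40..49
  curves <- extractBoneLevelCurves(mask, lateralTrimFraction = 0)
  oracle <- columnScanOracle(mask)
  expect_equal(curves$maxilla@x, oracle$x)
  expect_equal(as.integer(curves$maxilla@y), oracle$top)
  expect_true(all(curves$maxilla@y[curves$maxilla@x %in% 40:49] == 15))
  expect_true(all(curves$maxilla@y[!curves$maxilla@x %in% 40:49] == 10))
})

test_that("empty masks and split masks raise the documented errors", {
  expect_error(extractBoneLevelCurves(matrix(0L, 20, 50)), "empty")
  two <- matrix(0L, 30, 80)
  two[5:15, 3:30] <- 1L
  two[5:15, 50:78] <- 1L
  expect_error(extractBoneLevelCurves(two), "components")
  # two touching blobs form one component: no error
  touching <- matrix(0L, 30, 80)
  touching[5:15, 3:40] <- 1L
  touching[10:25, 40:70] <- 1L
  expect_silent(extractBoneLevelCurves(touching, 0))
})

test_that("CEJ curves take the apical band edge for each jaw and keep gaps", {
  band <- matrix(0L, 100, 60)
  band[31:41, 6:55] <- 1L                   # rows 30..40
  up <- extractCejCurve(band, "maxilla", 0)
  expect_true(all(up@y == 30))
  down <- matrix(0L, 100, 60)
  down[61:71, 6:55] <- 1L                   # rows 60..70
  lo <- extractCejCurve(down, "mandible", 0)
  expect_true(all(lo@y == 70))

  gappy <- band
  gappy[, 21:25] <- 0L                      # 5-column gap at x = 20..24
  g <- extractCejCurve(gappy, "maxilla", 0)
  expect_identical(setdiff(up@x, g@x), 20:24)
  expect_error(extractCejCurve(matrix(0L, 10, 10), "maxilla"), "empty")
})

test_that("median smoothing removes spikes, keeps constants, rejects even windows", {
  c0 <- mkCurve(0:4, c(10, 10, 50, 10, 10))
  expect_identical(smoothCurve(c0, 1), c0)
  expect_equal(smoothCurve(c0, 3)@y, rep(10, 5))
  flat <- mkCurve(0:9, rep(7, 10))
  expect_equal(smoothCurve(flat, 5)@y, rep(7, 10))
  expect_error(smoothCurve(c0, 4), "odd")
})

test_that("extraction equals the per-column scan oracle on phantom masks", {
  for (seed in 1:5) {
    scene <- generatePhantom(smallSpec(seed = seed, loss = runif(4, 0.05, 0.9)))
    oc <- oralCavity(scene)
    curves <- extractBoneLevelCurves(oc, lateralTrimFraction = 0)
    oracle <- columnScanOracle(oc)
    expect_equal(curves$maxilla@x, oracle$x)
    expect_equal(as.integer(curves$maxilla@y), oracle$top)
    expect_equal(as.integer(curves$mandible@y), oracle$bottom)
    # every curve point sits on the 4-connected mask boundary
    idx <- seq(1, length(curves$maxilla@x), by = 17)
    for (i in idx) {
      expect_true(onBoundary4(oc, curves$maxilla@x[i], curves$maxilla@y[i]))
      expect_true(onBoundary4(oc, curves$mandible@x[i], curves$mandible@y[i]))
    }
  }
})

test_that("curves export as two-column CSV", {
  c0 <- mkCurve(3:7, c(5, 5, 6, 6, 7))
  path <- withr::local_tempfile(fileext = ".csv")
  writeCurve(c0, path)
  back <- read.csv(path)
  expect_identical(names(back), c("x", "y"))
  expect_equal(back$y, c0@y)
})
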