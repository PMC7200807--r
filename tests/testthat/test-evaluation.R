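# Detection metrics and agreement statistics.

mk <- function(idx, h = 10, w = 10) {
  m <- matrix(0L, h, w); m[idx] <- 1L; m
}

test_that("pixel accuracy is TP/(TP+FN) over ground-truth pixels", {
  gt <- mk(1:10)
  expect_equal(pixelAccuracy(gt, gt), 1)
  det <- mk(c(1:9, 50:60))                    # 9 of 10 gt pixels + extras
  expect_equal(pixelAccuracy(gt, det), 0.9)
  expect_equal(pixelAccuracy(gt, mk(90:99)), 0)
  expect_error(pixelAccuracy(mk(integer(0)), det), "empty")
  expect_error(pixelAccuracy(gt, matrix(0L, 5, 5)), "dimensions")
  # intentionally asymmetric (recall as printed); conventional form is symmetric
  expect_false(isTRUE(all.equal(pixelAccuracy(gt, det),
                                pixelAccuracy(det, gt))))
  expect_equal(pixelAccuracy(gt, det, conventional = TRUE),
               pixelAccuracy(det, gt, conventional = TRUE))
})

test_that("dice and jaccard match hand counts and the D = 2J/(1+J) identity", {
  a <- mk(1:4); b <- mk(2:7)                  # |A|=4 |B|=6 |A∩B|=3
  expect_equal(diceCoefficient(a, b), 0.6)
  expect_equal(jaccardIndex(a, b), 3 / 7)
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(jaccardIndex(mk(1:3), mk(50:52)), 0)
  expect_error(diceCoefficient(mk(integer(0)), mk(integer(0))), "empty")

  set.seed(9)
  for (i in 1:100) {
    x <- mk(sample(100, sample(1:60, 1)))
    y <- mk(sample(100, sample(1:60, 1)))
    d <- diceCoefficient(x, y); j <- jaccardIndex(x, y)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(d, diceCoefficient(y, x))    # symmetry
    expect_lte(j, d)
  }
})

test_that("MAD over stages matches hand arithmetic", {
  expect_equal(madStages(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(madStages(c(1, 2, 3), c(1, 3, 3)), 1 / 3)
  expect_equal(madStages(c(1, 1), c(3, 3)), 2)
  expect_equal(madStages(c(1, 3), c(3, 1)), madStages(c(3, 1), c(1, 3)))
  expect_error(madStages(1:3, 1:2), "length")
  expect_error(madStages(c(1, 5), c(1, 2)), "\\{1, 2, 3\\}")
})

test_that("pearson matches a naive two-pass oracle and guards variance", {
  expect_equal(pearsonStages(1:5, 1:5), 1)
  expect_equal(pearsonStages(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearsonStages(c(2, 2, 2), c(1, 2, 3)),
               class = "perio_constant_rater")
  expect_error(pearsonStages(1:2, 1:2), ">= 3")
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(pearsonStages(x, y), pearsonOracle(x, y), tolerance = 1e-12)
    expect_equal(pearsonStages(x, y), pearsonStages(y, x))
  }
})

test_that("ICC(2,1) matches an aov mean-squares oracle and penalizes offsets", {
  same <- cbind(c(1, 2, 3, 2, 1, 3), c(1, 2, 3, 2, 1, 3), c(1, 2, 3, 2, 1, 3))
  expect_equal(as.numeric(iccStages(same)), 1)

  shifted <- cbind(1:6, 1:6 + 1)
  icc2 <- as.numeric(iccStages(shifted, model = "ICC2"))
  expect_lt(icc2, 1)                          # absolute-agreement penalty
  expect_equal(as.numeric(iccStages(shifted, model = "ICC3")), 1)

  set.seed(17)
  for (i in 1:10) {
    m <- matrix(sample(1:3, 18, replace = TRUE), 6, 3) +
      matrix(rnorm(18, 0, 0.01), 6, 3)
    expect_equal(as.numeric(iccStages(m)), iccOracleAov(m), tolerance = 1e-10)
  }
  expect_error(iccStages(cbind(1:3, 1:3)), ">= 2 raters")
})

test_that("evaluateRun ties metrics and stages into one report", {
  scene <- generatePhantom(smallSpec(seed = 21L, loss = c(0.1, 0.3, 0.5, 0.7)))
  tr <- sceneTruth(scene)
  stages <- data.frame(id = tr$id, stage = tr$stage)
  perfect <- evaluateRun(scene, sceneMasks(scene), stages, stages)
  core <- perfect[perfect$metric %in% c("pixel_accuracy", "dice", "jaccard"), ]
  expect_true(all(core$value == 1))
  expect_equal(perfect$value[perfect$metric == "mad"], 0)

  noisy <- perturbMasks(scene, 2, 0, seed = 3L)
  degraded <- evaluateRun(scene, sceneMasks(noisy), stages, stages)
  dice <- degraded[degraded$metric == "dice", "value"]
  expect_true(all(dice < 1))

  bad <- data.frame(id = c(tr$id[-1], 99L), stage = tr$stage)
  expect_error(evaluateRun(scene, sceneMasks(scene), stages, bad),
               class = "perio_id_mismatch")

  # per-case raw differences are exposed for downstream testing
  expect_true(any(perfect$metric == "stage_diff"))
})
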