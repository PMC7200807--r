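## Detection metrics (pixel accuracy, Dice, Jaccard) and stage-agreement
## statistics (MAD, Pearson, ICC).

#' Pixel accuracy of a detected mask
#'
#' Computed as TP / (TP + FN) over the ground-truth-positive pixels — the
#' fraction of ground-truth pixels the detection recovers. Note this is
#' sensitivity/recall and is intentionally asymmetric in its arguments;
#' set `conventional = TRUE` for the symmetric (TP + TN) / total accuracy
#' as a secondary value.
#'
#' @param gtMask,detMask same-dimension matrices; non-zero = foreground.
#' @param conventional if `TRUE` return conventional overall accuracy
#'   instead.
#' @return fraction in [0, 1].
#' @export
pixelAccuracy <- function(gtMask, detMask, conventional = FALSE) {
  if (!identical(dim(gtMask), dim(detMask)))
    .perioStop("perio_bad_input", "mask dimensions differ: %s vs %s",
               paste(dim(gtMask), collapse = "x"),
               paste(dim(detMask), collapse = "x"))
  gt <- gtMask > 0; det <- detMask > 0
  if (!any(gt))
    .perioStop("perio_empty_mask", "ground-truth mask is empty")
  if (conventional) return(sum(gt == det) / length(gt))
  sum(gt & det) / sum(gt)
}

#' Dice coefficient and Jaccard index of two masks
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `jaccard = |A∩B| / |A∪B|`; related by
#' `D = 2J / (1 + J)`. Both masks empty is an error.
#'
#' @param gtMask,detMask same-dimension matrices; non-zero = foreground.
#' @return fraction in [0, 1].
#' @export
diceCoefficient <- function(gtMask, detMask) {
  if (!identical(dim(gtMask), dim(detMask)))
    .perioStop("perio_bad_input", "mask dimensions differ: %s vs %s",
               paste(dim(gtMask), collapse = "x"),
               paste(dim(detMask), collapse = "x"))
  a <- gtMask > 0; b <- detMask > 0
  denom <- sum(a) + sum(b)
  if (denom == 0)
    .perioStop("perio_empty_mask", "both masks are empty")
  2 * sum(a & b) / denom
}

#' @rdname diceCoefficient
#' @export
jaccardIndex <- function(gtMask, detMask) {
  if (!identical(dim(gtMask), dim(detMask)))
    .perioStop("perio_bad_input", "mask dimensions differ: %s vs %s",
               paste(dim(gtMask), collapse = "x"),
               paste(dim(detMask), collapse = "x"))
  a <- gtMask > 0; b <- detMask > 0
  uni <- sum(a | b)
  if (uni == 0)
    .perioStop("perio_empty_mask", "both masks are empty")
  sum(a & b) / uni
}

#' Mean absolute difference between two stage vectors
#'
#' @param stagesA,stagesB equal-length vectors of stages in \{1, 2, 3\}.
#' @return mean of `|a_i - b_i|`.
#' @export
madStages <- function(stagesA, stagesB) {
  if (length(stagesA) != length(stagesB))
    .perioStop("perio_bad_input", "stage vectors differ in length: %d vs %d",
               length(stagesA), length(stagesB))
  if (!length(stagesA))
    .perioStop("perio_bad_input", "stage vectors are empty")
  if (!all(c(stagesA, stagesB) %in% 1:3))
    .perioStop("perio_bad_input", "stages must lie in {1, 2, 3}")
  mean(abs(stagesA - stagesB))
}

#' Pearson correlation between two raters' stages
#'
#' Standard product-moment correlation (delegates to [stats::cor()]) with
#' the preconditions of a rating comparison: at least 3 paired values and
#' non-zero variance in both raters.
#'
#' @param x,y equal-length numeric vectors.
#' @return correlation in [-1, 1].
#' @export
pearsonStages <- function(x, y) {
  if (length(x) != length(y))
    .perioStop("perio_bad_input", "vectors differ in length")
  if (length(x) < 3L)
    .perioStop("perio_bad_input", "need >= 3 paired values, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .perioStop("perio_constant_rater",
               "zero variance in a rater: correlation undefined")
  cor(x, y, method = "pearson")
}

#' Intraclass correlation coefficient of a ratings table
#'
#' Computed from the two-way ANOVA mean squares of the cases-by-raters
#' table. The default is ICC(2,1): two-way random effects, absolute
#' agreement, single measure,
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`. One-way (ICC1)
#' and consistency (ICC3) forms plus average-measure units are available.
#' Rows containing missing values are dropped first.
#'
#' @param ratings numeric matrix, rows = cases, columns = raters.
#' @param model `"ICC1"`, `"ICC2"` (default) or `"ICC3"`.
#' @param unit `"single"` (default) or `"average"`.
#' @return the ICC value, with the model recorded in attribute `"model"`.
#' @export
iccStages <- function(ratings, model = c("ICC2", "ICC1", "ICC3"),
                      unit = c("single", "average")) {
  model <- match.arg(model); unit <- match.arg(unit)
  m <- as.matrix(ratings)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2L || n < 5L)
    .perioStop("perio_bad_input",
               "need >= 2 raters and >= 5 complete cases, got %d x %d", n, k)
  grand <- mean(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  ssr <- k * sum((rowM - grand)^2)          # between cases
  ssc <- n * sum((colM - grand)^2)          # between raters
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  msw <- (sst - ssr) / (n * (k - 1))        # one-way within-case MS
  val <- switch(paste(model, unit, sep = "."),
    ICC1.single  = (msr - msw) / (msr + (k - 1) * msw),
    ICC1.average = (msr - msw) / msr,
    ICC2.single  = (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse)),
    ICC2.average = (msr - mse) / (msr + (msc - mse) / n),
    ICC3.single  = (msr - mse) / (msr + (k - 1) * mse),
    ICC3.average = (msr - mse) / msr)
  structure(val, model = sprintf("%s,%s", model, unit))
}

#' Evaluate a detected scene against ground truth
#'
#' Emits one tidy report combining per-structure segmentation metrics
#' (pixel accuracy, Dice, Jaccard for the oral cavity, both CEJ bands and
#' the binarized instance union) with stage-agreement statistics (MAD,
#' Pearson, ICC) over the cases both stage tables share. Stage tables are
#' matched by `id`; ids present in one table but not the other raise an
#' error listing the offenders.
#'
#' @param gtMasks,detMasks [StructureMaskSet-class] objects (a
#'   [PhantomScene-class] is accepted for `gtMasks`).
#' @param gtStages,detStages optional `data.frame`s with columns `id` and
#'   `stage`; rows with `NA` stages are dropped before matching.
#' @param config a [PipelineConfig-class] (ICC model, conventional
#'   accuracy flag).
#' @return `data.frame` with columns `metric, structure, value, n`.
#' @export
evaluateRun <- function(gtMasks, detMasks, gtStages = NULL, detStages = NULL,
                        config = pipelineConfig()) {
  if (is(gtMasks, "PhantomScene")) gtMasks <- gtMasks@masks
  if (is(detMasks, "PhantomScene")) detMasks <- detMasks@masks
  thr <- config@binarizeThreshold
  structures <- list(
    oral_cavity = list(gt = binarize(gtMasks@oralCavity, thr),
                       det = binarize(detMasks@oralCavity, thr)),
    cej_maxilla = list(gt = binarize(gtMasks@cejMaxilla, thr),
                       det = binarize(detMasks@cejMaxilla, thr)),
    cej_mandible = list(gt = binarize(gtMasks@cejMandible, thr),
                        det = binarize(detMasks@cejMandible, thr)),
    teeth = list(gt = (gtMasks@instances > 0) * 1L,
                 det = (detMasks@instances > 0) * 1L))
  rows <- list()
  for (nm in names(structures)) {
    gt <- structures[[nm]]$gt; det <- structures[[nm]]$det
    npix <- sum(gt > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("pixel_accuracy", "dice", "jaccard"), structure = nm,
      value = c(pixelAccuracy(gt, det), diceCoefficient(gt, det),
                jaccardIndex(gt, det)), n = npix, stringsAsFactors = FALSE)
    if (config@conventionalAccuracy)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "conventional_accuracy", structure = nm,
        value = pixelAccuracy(gt, det, conventional = TRUE),
        n = length(gt), stringsAsFactors = FALSE)
  }
  if (!is.null(gtStages) && !is.null(detStages)) {
    a <- gtStages[!is.na(gtStages$stage), c("id", "stage")]
    b <- detStages[!is.na(detStages$stage), c("id", "stage")]
    onlyA <- setdiff(a$id, b$id); onlyB <- setdiff(b$id, a$id)
    if (length(onlyA) || length(onlyB))
      .perioStop("perio_id_mismatch",
                 "stage id mismatch: only in gt {%s}, only in det {%s}",
                 paste(onlyA, collapse = ","), paste(onlyB, collapse = ","))
    mrg <- merge(a, b, by = "id", suffixes = c("_gt", "_det"))
    nst <- nrow(mrg)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("mad", "pearson", "icc"), structure = "stages",
      value = c(madStages(mrg$stage_gt, mrg$stage_det),
                tryCatch(pearsonStages(mrg$stage_gt, mrg$stage_det),
                         perio_constant_rater = function(e) NA_real_),
                tryCatch(as.numeric(iccStages(cbind(mrg$stage_gt, mrg$stage_det),
                                              model = config@iccModel)),
                         perioError = function(e) NA_real_)),
      n = nst, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "stage_diff", structure = paste0("case_", mrg$id),
      value = mrg$stage_det - mrg$stage_gt, n = 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
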