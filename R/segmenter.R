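## Pluggable segmenter contract. The staging pipeline starts from
## segmentation masks; where those masks come from is behind this
## interface, so a learned detector can be attached later. The package
## ships an oracle segmenter (perfect detection of phantom ground truth)
## and a noisy wrapper around it.

#' Oracle segmenter: perfect detection of a phantom scene
#'
#' Returns the scene's ground-truth masks cast to probability rasters in
#' \{0, 1\}. Stands in for a trained detector when exercising the
#' downstream pipeline.
#'
#' @param scene a [PhantomScene-class].
#' @return a [SegmenterOutput-class].
#' @export
oracleSegmenter <- function(scene) {
  stopifnot(is(scene, "PhantomScene"))
  ms <- scene@masks
  asProb <- function(m) matrix(as.numeric(m > 0), nrow(m), ncol(m))
  new("SegmenterOutput",
      oralCavity = asProb(ms@oralCavity),
      cejMaxilla = asProb(ms@cejMaxilla),
      cejMandible = asProb(ms@cejMandible),
      instances = ms@instances)
}

#' Noisy segmenter: oracle output degraded by boundary noise and dropout
#'
#' @param scene a [PhantomScene-class].
#' @param boundaryNoisePx boundary displacement amplitude in pixels.
#' @param dropoutRate per-instance dropout probability in [0, 1).
#' @param seed integer seed.
#' @return a [SegmenterOutput-class].
#' @export
noisySegmenter <- function(scene, boundaryNoisePx = 2, dropoutRate = 0,
                           seed = 1L) {
  oracleSegmenter(perturbMasks(scene, boundaryNoisePx, dropoutRate, seed))
}

#' Resolve a segmenter by configuration key
#'
#' `"oracle"` and `"noisy"` name the built-ins; any other key is taken as
#' a function name (optionally `"pkg::fun"`) resolving to a callable that
#' maps a scene/input to a [SegmenterOutput-class].
#'
#' @param key character key.
#' @return a function.
#' @export
resolveSegmenter <- function(key) {
  if (key == "oracle") return(oracleSegmenter)
  if (key == "noisy") return(noisySegmenter)
  if (grepl("::", key, fixed = TRUE)) {
    parts <- strsplit(key, "::", fixed = TRUE)[[1L]]
    return(getExportedValue(parts[1L], parts[2L]))
  }
  fn <- tryCatch(match.fun(key), error = function(e) NULL)
  if (is.null(fn))
    .perioStop("perio_bad_input", "cannot resolve segmenter '%s'", key)
  fn
}

#' Binarize segmenter output into a structure mask set
#'
#' After this step the staging pipeline consumes segmenter output and
#' directly-loaded mask sets interchangeably.
#'
#' @param segOutput a [SegmenterOutput-class].
#' @param threshold binarization threshold in (0, 1).
#' @return a [StructureMaskSet-class].
#' @export
asMaskSet <- function(segOutput, threshold = 0.5) {
  stopifnot(is(segOutput, "SegmenterOutput"))
  new("StructureMaskSet",
      oralCavity = binarize(segOutput@oralCavity, threshold),
      cejMaxilla = binarize(segOutput@cejMaxilla, threshold),
      cejMandible = binarize(segOutput@cejMandible, threshold),
      instances = segOutput@instances)
}
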