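## Raster and report I/O. PNG via the png package; label rasters are
## written 8-bit (instance ids <= 255) and read back from either 8- or
## 16-bit files using the file's declared bit depth.

.defaultNaming <- list(oral_cavity = "oral_cavity.png",
                       cej_maxilla = "cej_maxilla.png",
                       cej_mandible = "cej_mandible.png",
                       instances = "instances.png")

#' Read one raster, returning values on the original integer scale.
#' @noRd
.readRaster <- function(path, what = c("prob", "label")) {
  what <- match.arg(what)
  img <- png::readPNG(path, info = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]       # grayscale written as RGB
  if (what == "prob") return(matrix(as.numeric(img), nrow(img), ncol(img)))
  depth <- attr(img, "info")$bit.depth
  if (is.null(depth)) depth <- 8L
  matrix(as.integer(round(img * (2^depth - 1))), nrow(img), ncol(img))
}

#' @noRd
.writeRaster <- function(mask, path, what = c("prob", "label")) {
  what <- match.arg(what)
  if (what == "label") {
    if (max(mask) > 255L)
      .perioStop("perio_io", "cannot write label raster: ids exceed 255")
    img <- mask / 255
  } else img <- mask * 1.0
  png::writePNG(matrix(as.numeric(img), nrow(mask), ncol(mask)), path)
}

#' Read a structure mask set from a directory
#'
#' Expects the four rasters named per `naming` (defaults:
#' `oral_cavity.png`, `cej_maxilla.png`, `cej_mandible.png`,
#' `instances.png`). The three structure rasters may be binary or hold
#' probabilities in [0, 1]; they are passed through unthresholded for
#' later binarization. The instance raster is decoded as integer labels.
#'
#' @param dir directory containing the rasters.
#' @param naming named list overriding any of the default file names.
#' @return a validated [StructureMaskSet-class].
#' @export
readMaskSet <- function(dir, naming = list()) {
  naming <- modifyList(.defaultNaming, naming)
  paths <- lapply(naming, function(f) file.path(dir, f))
  for (nm in names(.defaultNaming))
    if (!file.exists(paths[[nm]]))
      .perioStop("perio_io", "missing mask file for structure '%s': %s",
                 nm, paths[[nm]])
  oc <- .readRaster(paths$oral_cavity, "prob")
  cx <- .readRaster(paths$cej_maxilla, "prob")
  cn <- .readRaster(paths$cej_mandible, "prob")
  inst <- .readRaster(paths$instances, "label")
  dims <- lapply(list(oral_cavity = oc, cej_maxilla = cx,
                      cej_mandible = cn, instances = inst), dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    .perioStop("perio_io", "mask dimension mismatch: %s",
               paste(sprintf("%s=%s", names(dims),
                             vapply(dims, paste, "", collapse = "x")),
                     collapse = ", "))
  new("StructureMaskSet", oralCavity = oc, cejMaxilla = cx,
      cejMandible = cn, instances = inst)
}

#' Write a structure mask set (or phantom scene) to a directory
#'
#' Writes the four rasters under the standard names; for a
#' [PhantomScene-class] additionally writes `truth.csv` and `spec.yaml` so
#' the scene round-trips. Binary rasters are 8-bit PNG; the label raster
#' is 8-bit PNG (ids must be <= 255).
#'
#' @param x a [StructureMaskSet-class] or [PhantomScene-class].
#' @param dir output directory, created if needed.
#' @param naming named list overriding default file names.
#' @return `dir`, invisibly.
#' @export
writeMaskSet <- function(x, dir, naming = list()) {
  naming <- modifyList(.defaultNaming, naming)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ms <- if (is(x, "PhantomScene")) x@masks else x
  .writeRaster(ms@oralCavity, file.path(dir, naming$oral_cavity), "prob")
  .writeRaster(ms@cejMaxilla, file.path(dir, naming$cej_maxilla), "prob")
  .writeRaster(ms@cejMandible, file.path(dir, naming$cej_mandible), "prob")
  .writeRaster(ms@instances, file.path(dir, naming$instances), "label")
  if (is(x, "PhantomScene")) {
    write.csv(x@truth, file.path(dir, "truth.csv"), row.names = FALSE)
    writePhantomSpec(x@spec, file.path(dir, "spec.yaml"))
  }
  invisible(dir)
}

#' Read a phantom scene written by [writeMaskSet()]
#'
#' @param dir directory holding the rasters, `truth.csv` and `spec.yaml`.
#' @return a [PhantomScene-class].
#' @export
readScene <- function(dir) {
  ms <- readMaskSet(dir)
  tpath <- file.path(dir, "truth.csv")
  spath <- file.path(dir, "spec.yaml")
  if (!file.exists(tpath) || !file.exists(spath))
    .perioStop("perio_io", "not a phantom scene directory (truth.csv/spec.yaml missing): %s", dir)
  ms@oralCavity <- matrix(as.integer(ms@oralCavity > 0.5),
                          nrow(ms@oralCavity), ncol(ms@oralCavity))
  ms@cejMaxilla <- matrix(as.integer(ms@cejMaxilla > 0.5),
                          nrow(ms@cejMaxilla), ncol(ms@cejMaxilla))
  ms@cejMandible <- matrix(as.integer(ms@cejMandible > 0.5),
                           nrow(ms@cejMandible), ncol(ms@cejMandible))
  new("PhantomScene", masks = ms,
      truth = read.csv(tpath, stringsAsFactors = FALSE),
      spec = readPhantomSpec(spath))
}

#' Serialize a phantom spec to YAML / read it back
#'
#' @param spec a [PhantomSpec-class].
#' @param path YAML file path.
#' @return `readPhantomSpec()` returns a [PhantomSpec-class];
#'   `writePhantomSpec()` returns `path` invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  yaml::write_yaml(list(
    image_height = spec@imageHeight, image_width = spec@imageWidth,
    teeth_per_jaw = spec@teethPerJaw, tooth_width = spec@toothWidth,
    root_length = spec@rootLength, crown_length = spec@crownLength,
    loss_fractions = list(maxilla = as.numeric(spec@lossFractions[, 1L]),
                          mandible = as.numeric(spec@lossFractions[, 2L])),
    tilt_degrees = list(maxilla = as.numeric(spec@tiltDegrees[, 1L]),
                        mandible = as.numeric(spec@tiltDegrees[, 2L])),
    implant_flags = list(maxilla = as.logical(spec@implantFlags[, 1L]),
                         mandible = as.logical(spec@implantFlags[, 2L])),
    curve_waviness = spec@curveWaviness, seed = spec@seed), path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  perJaw <- function(v) cbind(unlist(v$maxilla), unlist(v$mandible))
  phantomSpec(imageHeight = y$image_height, imageWidth = y$image_width,
              teethPerJaw = y$teeth_per_jaw, toothWidth = y$tooth_width,
              rootLength = y$root_length, crownLength = y$crown_length,
              lossFractions = perJaw(y$loss_fractions),
              tiltDegrees = perJaw(y$tilt_degrees),
              implantFlags = perJaw(y$implant_flags),
              curveWaviness = y$curve_waviness, seed = y$seed)
}

#' Read polygon annotations from JSON
#'
#' Package JSON dialect:
#' `{"structures": [{"name": ..., "points": [[x, y], ...]}, ...]}` with
#' 0-based pixel coordinates and an implicit closing edge.
#'
#' @param path JSON file.
#' @return named list of two-column vertex matrices.
#' @export
readPolygonAnnotations <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$structures))
    .perioStop("perio_io", "no 'structures' key in %s", path)
  sts <- j$structures
  out <- lapply(seq_len(nrow(sts)), function(i) {
    p <- sts$points[[i]]
    if (is.null(dim(p))) p <- matrix(p, ncol = 2L, byrow = TRUE)
    colnames(p) <- c("x", "y")
    p
  })
  names(out) <- sts$name
  out
}

.reportColumns <- c("id", "jaw", "kind", "d_cej_px", "d_pbl_px",
                    "rbl_percent", "stage", "flags")

#' Write a staging report as CSV and JSON
#'
#' Column order is fixed (`id, jaw, kind, d_cej_px, d_pbl_px, rbl_percent,
#' stage, flags`, then `error` for instances that failed). CSV rounds
#' floating values to 2 decimals; JSON keeps full precision.
#'
#' @param measurements `data.frame` as returned by [stageAll()] (an empty
#'   frame yields a header-only CSV).
#' @param path output path; `.csv` and `.json` siblings are written (a
#'   trailing `.csv` or `.json` in `path` is treated as the stem).
#' @return named character vector with the two file paths, invisibly.
#' @export
writeReport <- function(measurements, path) {
  stem <- sub("\\.(csv|json)$", "", path)
  cols <- c(.reportColumns,
            intersect("error", names(measurements)))
  df <- if (nrow(measurements))
    measurements[, cols, drop = FALSE]
  else
    stats::setNames(as.data.frame(rep(list(character(0)), length(cols))), cols)
  csv <- df
  for (nm in c("d_cej_px", "d_pbl_px", "rbl_percent"))
    if (nm %in% names(csv) && nrow(csv))
      csv[[nm]] <- sprintf("%.2f", as.numeric(csv[[nm]]))
  csvPath <- paste0(stem, ".csv"); jsonPath <- paste0(stem, ".json")
  ok <- tryCatch({
    write.csv(csv, csvPath, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(df, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .perioStop("perio_io", "cannot write report to %s: %s",
               stem, conditionMessage(ok))
  invisible(c(csv = csvPath, json = jsonPath))
}

#' Read back the JSON half of a staging report
#'
#' @param path the `.json` report file.
#' @return a `data.frame` with full-precision values.
#' @export
readReport <- function(path) {
  df <- jsonlite::fromJSON(path)
  as.data.frame(df, stringsAsFactors = FALSE)
}
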