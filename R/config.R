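## Pipeline configuration: construction, YAML round-trip, logging of the
## resolved values.

#' Construct a pipeline configuration
#'
#' All parameters have working defaults; see [PipelineConfig-class] for
#' their meaning and units.
#'
#' @param binarizeThreshold probability threshold in (0, 1).
#' @param lateralTrimFraction per-side column trim fraction in [0, 0.5).
#' @param smoothingWindow odd median window in columns (1 = off).
#' @param isotropyThreshold minimum elongation for a defined orientation.
#' @param gapInterpolationSpanPx largest bridged curve gap, columns.
#' @param rblConvention `"loss"` or `"remaining"`.
#' @param iccModel `"ICC1"`, `"ICC2"` or `"ICC3"`.
#' @param momentSource `"boundary"` or `"filled"`.
#' @param conventionalAccuracy also report (TP+TN)/total in evaluations.
#' @param seed integer seed for seeded helpers.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(binarizeThreshold = 0.5,
                           lateralTrimFraction = 0.05,
                           smoothingWindow = 1L,
                           isotropyThreshold = 1.2,
                           gapInterpolationSpanPx = 40,
                           rblConvention = "loss",
                           iccModel = "ICC2",
                           momentSource = "boundary",
                           conventionalAccuracy = FALSE,
                           seed = 1L) {
  new("PipelineConfig",
      binarizeThreshold = as.numeric(binarizeThreshold),
      lateralTrimFraction = as.numeric(lateralTrimFraction),
      smoothingWindow = as.integer(smoothingWindow),
      isotropyThreshold = as.numeric(isotropyThreshold),
      gapInterpolationSpanPx = as.numeric(gapInterpolationSpanPx),
      rblConvention = rblConvention, iccModel = iccModel,
      momentSource = momentSource,
      conventionalAccuracy = as.logical(conventionalAccuracy),
      seed = as.integer(seed))
}

.configYamlKeys <- c(
  binarizeThreshold = "binarize_threshold",
  lateralTrimFraction = "lateral_trim_fraction",
  smoothingWindow = "smoothing_window",
  isotropyThreshold = "isotropy_threshold",
  gapInterpolationSpanPx = "gap_interpolation_span_px",
  rblConvention = "rbl_convention",
  iccModel = "icc_model",
  momentSource = "moment_source",
  conventionalAccuracy = "conventional_accuracy",
  seed = "seed")

#' Read / write a pipeline configuration as YAML
#'
#' The file uses snake_case keys (`binarize_threshold`, ...); absent keys
#' take their defaults, so a partial file is a valid override. Writing
#' then reading reproduces the configuration verbatim.
#'
#' @param path YAML file path.
#' @param config a [PipelineConfig-class].
#' @return `readPipelineConfig()` returns a [PipelineConfig-class];
#'   `writePipelineConfig()` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  unknown <- setdiff(names(y), .configYamlKeys)
  if (length(unknown))
    .perioStop("perio_bad_input", "unknown config keys: %s",
               paste(unknown, collapse = ", "))
  args <- list()
  for (slot in names(.configYamlKeys)) {
    key <- .configYamlKeys[[slot]]
    if (!is.null(y[[key]])) args[[slot]] <- y[[key]]
  }
  do.call(pipelineConfig, args)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(is(config, "PipelineConfig"))
  vals <- lapply(names(.configYamlKeys), function(s) slot(config, s))
  names(vals) <- unname(.configYamlKeys)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Log the fully-resolved configuration (all defaults materialized) so a
#' run is reproducible from its log alone.
#' @noRd
.logConfig <- function(config) {
  for (s in names(.configYamlKeys))
    .log("INFO", "config %s = %s", .configYamlKeys[[s]],
         paste(format(slot(config, s)), collapse = " "))
}
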