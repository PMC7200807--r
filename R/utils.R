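## Internal helpers shared across modules.

#' Stop with a classed condition so callers can catch specific failures.
#' @noRd
.perioStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "perioError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Coordinates (0-based x = col, y = row) of non-zero pixels of a matrix.
#' @return two-column matrix with columns x, y.
#' @noRd
.maskPixels <- function(mask) {
  idx <- which(mask > 0)
  if (!length(idx)) return(matrix(numeric(0), 0L, 2L,
                                  dimnames = list(NULL, c("x", "y"))))
  h <- nrow(mask)
  cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

#' 4-connected component labels of a binary matrix (EBImage backend).
#' @noRd
.labelComponents <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)))
  matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
}

#' Run expr with the RNG seeded to `seed`, restoring the caller's RNG state.
#' Keeps all package randomness flowing from explicit seeds without
#' disturbing the global stream.
#' @noRd
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Fold a direction vector to a signed angle from vertical in (-90, 90] deg.
#'
#' The undirected long-axis angle: 0 means vertical, positive angles lean
#' the top of the line toward larger x. Both orientations of the same line
#' map to the same value.
#'
#' @param dir numeric length-2 vector `(dx, dy)` (y grows downward).
#' @return angle in degrees in (-90, 90].
#' @export
#' @examples
#' axisAngleFromVertical(c(0, 1))   # 0
#' axisAngleFromVertical(c(1, 1))   # 45
axisAngleFromVertical <- function(dir) {
  stopifnot(length(dir) == 2L, all(is.finite(dir)), any(dir != 0))
  a <- atan2(dir[[1L]], dir[[2L]]) * 180 / pi
  if (a > 90) a <- a - 180
  if (a <= -90) a <- a + 180
  a
}

#' Validate that a raster is a numeric matrix with values in [0, 1].
#' @noRd
.checkProbRaster <- function(r, name = deparse(substitute(r))) {
  if (!is.matrix(r) || !is.numeric(r))
    .perioStop("perio_bad_input", "%s must be a numeric matrix", name)
  if (any(!is.finite(r)) || any(r < 0 | r > 1))
    .perioStop("perio_bad_input", "%s must have finite values in [0, 1]", name)
  invisible(r)
}

## ---- logging ----------------------------------------------------------

.logLevels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Set or query the package log level
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return the current level, invisibly when setting.
#' @export
perioLogLevel <- function(level = NULL) {
  if (is.null(level)) return(getOption("perioStage.logLevel", "WARN"))
  level <- match.arg(toupper(level), names(.logLevels))
  options(perioStage.logLevel = level)
  invisible(level)
}

#' @noRd
.log <- function(level, fmt, ...) {
  cur <- .logLevels[[getOption("perioStage.logLevel", "WARN")]]
  if (.logLevels[[level]] >= cur)
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}
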