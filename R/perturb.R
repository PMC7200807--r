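## Seeded mask degradation: emulates imperfect detector output so the
## metric suite has something other than perfect masks to measure.

#' Smooth random field via bilinear upsampling of a coarse iid normal grid.
#' @noRd
.noiseField <- function(h, w, sigma, grid = 16L) {
  gh <- ceiling(h / grid) + 2L
  gw <- ceiling(w / grid) + 2L
  coarse <- matrix(rnorm(gh * gw, sd = sigma), gh, gw)
  ry <- (0:(h - 1L)) / grid + 1
  rx <- (0:(w - 1L)) / grid + 1
  iy <- pmin(floor(ry), gh - 1L); fy <- ry - iy
  ix <- pmin(floor(rx), gw - 1L); fx <- rx - ix
  a <- coarse[cbind(rep(iy, length(ix)), rep(ix, each = length(iy)))]
  b <- coarse[cbind(rep(iy, length(ix)), rep(ix + 1L, each = length(iy)))]
  c2 <- coarse[cbind(rep(iy + 1L, length(ix)), rep(ix, each = length(iy)))]
  d <- coarse[cbind(rep(iy + 1L, length(ix)), rep(ix + 1L, each = length(iy)))]
  fyv <- rep(fy, length(ix)); fxv <- rep(fx, each = length(iy))
  matrix((1 - fyv) * (1 - fxv) * a + (1 - fyv) * fxv * b +
           fyv * (1 - fxv) * c2 + fyv * fxv * d, h, w)
}

#' Signed Euclidean distance to the mask boundary: positive inside,
#' negative outside (EBImage distance transforms).
#' @noRd
.signedDistance <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  inside <- as.matrix(EBImage::distmap(m))
  outside <- as.matrix(EBImage::distmap(1 - m))
  inside - outside
}

#' Displace a binary mask boundary by a smooth noise field of the given
#' amplitude: threshold signed distance + field at zero.
#' @noRd
.perturbBinary <- function(mask, noisePx, grid = 16L) {
  if (noisePx <= 0) return(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
  sd <- .signedDistance(mask)
  field <- .noiseField(nrow(mask), ncol(mask), noisePx, grid)
  matrix(as.integer(sd + field > 0), nrow(mask), ncol(mask))
}

#' Degrade a phantom scene's masks
#'
#' Applies two independent corruptions to every raster of the scene while
#' leaving the ground truth untouched: (1) boundary noise — each mask
#' boundary is displaced by a smooth seeded random field whose amplitude is
#' `boundaryNoisePx` pixels (implemented by thresholding the signed
#' distance transform plus the field); (2) instance dropout — each instance
#' is removed entirely with probability `dropoutRate` (connected components
#' of the binary structure masks are likewise dropped). With zero noise and
#' zero dropout the masks are returned unchanged.
#'
#' @param scene a [PhantomScene-class].
#' @param boundaryNoisePx boundary displacement amplitude, pixels, >= 0.
#' @param dropoutRate probability in [0, 1) of dropping each instance.
#' @param seed integer seed; the perturbation is reproducible.
#' @return a new [PhantomScene-class] with degraded masks and the original
#'   truth and spec.
#' @export
perturbMasks <- function(scene, boundaryNoisePx, dropoutRate = 0, seed = 1L) {
  stopifnot(is(scene, "PhantomScene"),
            boundaryNoisePx >= 0, dropoutRate >= 0, dropoutRate < 1)
  ms <- scene@masks
  if (boundaryNoisePx == 0 && dropoutRate == 0) return(scene)
  .withLocalSeed(seed, {
    dropBin <- function(mask) {
      if (dropoutRate == 0) return(mask)
      lab <- .labelComponents(mask)
      ncomp <- max(lab)
      if (ncomp == 0L) return(mask)
      keep <- runif(ncomp) >= dropoutRate
      matrix(as.integer(lab > 0L & keep[pmax(lab, 1L)]), nrow(mask), ncol(mask))
    }
    ocav <- .perturbBinary(dropBin(ms@oralCavity), boundaryNoisePx)
    cejx <- .perturbBinary(dropBin(ms@cejMaxilla), boundaryNoisePx)
    cejn <- .perturbBinary(dropBin(ms@cejMandible), boundaryNoisePx)
    inst <- matrix(0L, nrow(ms@instances), ncol(ms@instances))
    for (id in instanceIds(ms)) {
      if (dropoutRate > 0 && runif(1L) < dropoutRate) next
      pm <- .perturbBinary(instanceMask(ms, id), boundaryNoisePx, grid = 8L)
      inst[pm > 0L] <- id
    }
    new("PhantomScene",
        masks = new("StructureMaskSet", oralCavity = ocav, cejMaxilla = cejx,
                    cejMandible = cejn, instances = inst),
        truth = scene@truth, spec = scene@spec)
  })
}
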