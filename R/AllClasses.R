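#' Binary nucleus mask with physical pixel size
#'
#' A segmented nucleus: a single connected binary foreground component on a
#' 2D raster, together with the physical pixel size in nanometres.  All radial
#' partitions (rings, ribbons, periphery/interior bands) are derived from this
#' object.  Holes are filled at construction; masks with more than one
#' connected component are rejected.
#'
#' @slot mask logical matrix, \code{TRUE} inside the nucleus.
#' @slot pixelSize numeric(1), nanometres per pixel edge.
#' @slot id character(1) nucleus identifier.
#' @export
setClass("NucleusMask",
  representation(mask = "matrix", pixelSize = "numeric", id = "character"))

setValidity("NucleusMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (is.logical(object@mask) && sum(object@mask) == 0L)
    msg <- c(msg, "mask has zero area")
  if (length(msg)) msg else TRUE
})

#' Labelled partition of a nucleus mask
#'
#' Integer label raster that partitions a \linkS4class{NucleusMask} exactly
#' into named regions: concentric rings (label 1 most central), fixed-width
#' boundary ribbons (label 1 most peripheral, matching the regional imaging
#' convention), or a periphery/interior two-band split.  Region pixel areas
#' and the construction parameters are carried along so downstream
#' normalizations (e.g. the 2k-1 ring-area weights) are reproducible.
#'
#' @slot labels integer matrix, 0 outside the nucleus, region index inside.
#' @slot regionNames character vector naming regions 1..K.
#' @slot areas integer vector of per-region pixel counts.
#' @slot type character(1): "rings", "ribbons" or "peripheryInterior".
#' @slot pixelSize numeric(1), nm per pixel (inherited from the mask).
#' @slot params list of construction parameters (K, weights, width_nm, ...).
#' @export
setClass("RegionPartition",
  representation(labels = "matrix", regionNames = "character",
                 areas = "integer", type = "character",
                 pixelSize = "numeric", params = "list"))

setValidity("RegionPartition", function(object) {
  msg <- character()
  k <- length(object@regionNames)
  if (length(object@areas) != k)
    msg <- c(msg, "areas and regionNames lengths differ")
  if (any(object@labels < 0L) || any(object@labels > k))
    msg <- c(msg, "labels outside 0..K")
  if (any(object@areas <= 0L))
    msg <- c(msg, "every region must contain at least one pixel")
  if (length(msg)) msg else TRUE
})

#' Sparse binned contact matrix
#'
#' Upper-triangular (cis) or rectangular (trans) binned contact counts at a
#' fixed resolution, stored as 1-based COO triplets.  Counts may be
#' non-integer because balancing (e.g. KR) happens upstream.
#'
#' @slot chromA,chromB character(1) chromosome names (equal for cis).
#' @slot resolution numeric(1) bin size in bp.
#' @slot nBinsA,nBinsB integer(1) matrix extent in bins.
#' @slot counts data.frame with columns \code{i}, \code{j}, \code{count}
#'   (1-based bin indices; \code{i <= j} for cis matrices).
#' @export
setClass("ContactMatrix",
  representation(chromA = "character", chromB = "character",
                 resolution = "numeric", nBinsA = "integer",
                 nBinsB = "integer", counts = "data.frame"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  cts <- object@counts
  if (!all(c("i", "j", "count") %in% names(cts)))
    msg <- c(msg, "counts needs columns i, j, count")
  else {
    if (any(cts$count < 0)) msg <- c(msg, "negative contact counts")
    if (any(cts$i < 1L) || any(cts$j < 1L) ||
        any(cts$i > object@nBinsA) || any(cts$j > object@nBinsB))
      msg <- c(msg, "bin indices outside matrix extent")
    if (object@chromA == object@chromB && any(cts$i > cts$j))
      msg <- c(msg, "cis matrices must be stored upper-triangular (i <= j)")
  }
  if (object@resolution <= 0) msg <- c(msg, "resolution must be positive")
  if (length(msg)) msg else TRUE
})

#' Image stack with a named third axis
#'
#' A 2D raster or a 3D cube whose third axis is wavelength (spectral
#' interference cube, nm grid), time (temporal interference cube, frame
#' interval in seconds) or z.  Pixel size is in nm.
#'
#' @slot data numeric array, 2D or 3D.
#' @slot pixelSize numeric(1) nm per pixel.
#' @slot axis character(1): "none", "wavelength", "time" or "z".
#' @slot axisValues numeric vector; wavelength grid (nm) or frame times (s).
#' @export
setClass("ImageStack",
  representation(data = "array", pixelSize = "numeric",
                 axis = "character", axisValues = "numeric"))

setValidity("ImageStack", function(object) {
  msg <- character()
  nd <- length(dim(object@data))
  if (!nd %in% c(2L, 3L)) msg <- c(msg, "data must be 2D or 3D")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
  if (!object@axis %in% c("none", "wavelength", "time", "z"))
    msg <- c(msg, "axis must be none/wavelength/time/z")
  if (nd == 3L && length(object@axisValues) != dim(object@data)[3])
    msg <- c(msg, "axisValues length must match third data dimension")
  if (length(msg)) msg else TRUE
})

#' Optical constants for the fractional-moving-mass normalization
#'
#' Physical constants entering the prefactor that converts temporal
#' interference variance into fractional moving mass:
#' nucleosome dry density \code{rho0} (g/cm^3), Fresnel intensity coefficient
#' \code{Gamma} at normal incidence (dimensionless; no default - it depends
#' on the substrate/medium pair and must be supplied, e.g. via
#' \code{\link{fresnelGamma}}), illumination scalar wavenumber \code{k}
#' (1/cm), immersion refractive index \code{n_i}, nuclear refractive index
#' \code{n_1}, nucleosome refractive index \code{n_m}, and the illumination
#' and collection numerical apertures \code{NA_i}, \code{NA_c}.
#'
#' @slot rho0,Gamma,k,n_i,n_1,n_m,NA_i,NA_c numeric(1) each; \code{Gamma}
#'   defaults to \code{NA} and must be set before use.
#' @export
setClass("OpticalConstants",
  representation(rho0 = "numeric", Gamma = "numeric", k = "numeric",
                 n_i = "numeric", n_1 = "numeric", n_m = "numeric",
                 NA_i = "numeric", NA_c = "numeric"))

setValidity("OpticalConstants", function(object) {
  msg <- character()
  pos <- c(rho0 = object@rho0, k = object@k, n_i = object@n_i,
           n_1 = object@n_1, n_m = object@n_m,
           NA_i = object@NA_i, NA_c = object@NA_c)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all constants except Gamma must be strictly positive")
  if (object@n_m <= object@n_1)
    msg <- c(msg, "n_m must exceed n_1 (nucleosome denser than nucleoplasm)")
  if (!is.na(object@Gamma) && object@Gamma <= 0)
    msg <- c(msg, "Gamma, when set, must be strictly positive")
  if (length(msg)) msg else TRUE
})
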