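#' Construct a NucleusMask
#'
#' Wraps a binary raster as a \linkS4class{NucleusMask}.  Interior holes are
#' filled (radial partitions are defined on the filled shape) and masks with
#' more than one connected foreground component are rejected.
#'
#' @param mask logical or 0/1 matrix, foreground = nucleus.
#' @param pixelSize nm per pixel (> 0).
#' @param id nucleus identifier.
#' @param fillHoles fill interior holes before validation (default TRUE).
#' @return a \linkS4class{NucleusMask}
#' @examples
#' m <- simNucleusMask(64, 64, 130, c(3000, 2000))
#' maskArea(m)
#' @export
NucleusMask <- function(mask, pixelSize, id = "nucleus", fillHoles = TRUE) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop("mask contains NA")
  if (sum(mask) == 0L) stop("mask has zero area")
  if (fillHoles)
    mask <- EBImage::fillHull(mask * 1L) > 0
  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) > 1L)
    stop("mask has ", max(lab), " connected components; expected exactly 1")
  new("NucleusMask", mask = mask, pixelSize = as.numeric(pixelSize),
      id = as.character(id))
}

#' Construct a ContactMatrix
#'
#' @param counts data.frame with 1-based columns \code{i}, \code{j},
#'   \code{count}.  For cis matrices entries are folded to the upper triangle
#'   and duplicate (i, j) records are summed.
#' @param resolution bin size in bp.
#' @param nBinsA,nBinsB matrix extent in bins (\code{nBinsB} defaults to
#'   \code{nBinsA} for cis matrices).
#' @param chromA,chromB chromosome names; equal names declare a cis matrix.
#' @return a \linkS4class{ContactMatrix}
#' @export
ContactMatrix <- function(counts, resolution, nBinsA,
                          nBinsB = nBinsA, chromA = "chr", chromB = chromA) {
  counts <- as.data.frame(counts)[c("i", "j", "count")]
  if (any(counts$count < 0)) stop("negative contact counts are not allowed")
  if (chromA == chromB) {
    ii <- pmin(counts$i, counts$j)
    jj <- pmax(counts$i, counts$j)
    counts$i <- ii; counts$j <- jj
  }
  key <- paste(counts$i, counts$j)
  if (anyDuplicated(key)) {
    agg <- rowsum(counts$count, key, reorder = FALSE)
    first <- !duplicated(key)
    counts <- counts[first, ]
    counts$count <- agg[match(paste(counts$i, counts$j), rownames(agg)), 1L]
  }
  counts <- counts[order(counts$i, counts$j), , drop = FALSE]
  rownames(counts) <- NULL
  new("ContactMatrix", chromA = chromA, chromB = chromB,
      resolution = as.numeric(resolution), nBinsA = as.integer(nBinsA),
      nBinsB = as.integer(nBinsB), counts = counts)
}

#' Construct an ImageStack
#'
#' @param data numeric matrix or 3D array.
#' @param pixelSize nm per pixel.
#' @param axis name of the third axis: "none", "wavelength", "time" or "z".
#' @param axisValues grid along the third axis (nm for wavelength, seconds
#'   for time).
#' @return an \linkS4class{ImageStack}
#' @export
ImageStack <- function(data, pixelSize, axis = "none",
                       axisValues = numeric()) {
  data <- as.array(data)
  new("ImageStack", data = data, pixelSize = as.numeric(pixelSize),
      axis = axis, axisValues = as.numeric(axisValues))
}

#' Optical constants with instrument defaults
#'
#' Returns the constant set used by the fractional-moving-mass normalization,
#' defaulting to nucleosome dry density 0.55 g/cm^3, illumination wavenumber
#' 1.57e5 cm^-1, immersion RI 1.518, nuclear RI 1.37, nucleosome RI 1.43,
#' illumination NA 0.52 and collection NA 1.49.  The Fresnel intensity
#' coefficient \code{Gamma} carries no default: it depends on the reference
#' interface and must be supplied explicitly (see \code{\link{fresnelGamma}}).
#'
#' @param Gamma Fresnel intensity coefficient at normal incidence.
#' @param rho0,k,n_i,n_1,n_m,NA_i,NA_c overrides for the defaults above.
#' @return an \linkS4class{OpticalConstants}
#' @examples
#' opticalConstants(Gamma = fresnelGamma(1.518, 1.37))
#' @export
opticalConstants <- function(Gamma = NA_real_, rho0 = 0.55, k = 1.57e5,
                             n_i = 1.518, n_1 = 1.37, n_m = 1.43,
                             NA_i = 0.52, NA_c = 1.49) {
  new("OpticalConstants", rho0 = rho0, Gamma = as.numeric(Gamma), k = k,
      n_i = n_i, n_1 = n_1, n_m = n_m, NA_i = NA_i, NA_c = NA_c)
}

#' Normal-incidence Fresnel intensity coefficient
#'
#' Helper for choosing \code{Gamma}: the intensity reflection coefficient of
#' a planar interface between refractive indices \code{n_a} and \code{n_b} at
#' normal incidence, \eqn{((n_a - n_b)/(n_a + n_b))^2}.
#'
#' @param n_a,n_b refractive indices of the two media.
#' @return numeric(1)
#' @export
fresnelGamma <- function(n_a, n_b) {
  stopifnot(n_a > 0, n_b > 0)
  ((n_a - n_b) / (n_a + n_b))^2
}
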