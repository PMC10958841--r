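# Spectroscopic chromatin statistics: spectral-variance Sigma maps, a
# pluggable Sigma -> D calibration, temporal interference variance, the
# fractional-moving-mass normalization, autocorrelation-decay diffusion, and
# ribbon-regional aggregation.

#' Per-pixel spectral interference standard deviation (Sigma)
#'
#' Divides each pixel's spectrum by a reference spectrum (the reflectance of
#' the bare substrate/medium interface), removes the per-pixel spectral mean,
#' and returns the population standard deviation over wavelength.  Sigma is
#' proportional to nanoscale refractive-index (hence chromatin density)
#' variations.
#'
#' @param cube \linkS4class{ImageStack} with axis "wavelength".
#' @param reference strictly positive numeric vector (per-wavelength) or
#'   scalar; default 1 for cubes that are already reference-normalized.
#' @return numeric matrix of Sigma values
#' @export
computeSigma <- function(cube, reference = 1) {
  stopifnot(is(cube, "ImageStack"))
  if (cube@axis != "wavelength")
    stop("computeSigma needs a wavelength-axis cube")
  d <- dim(cube@data)
  if (d[3] < 3) stop("need at least 3 wavelength samples")
  if (any(reference <= 0)) stop("reference must be strictly positive")
  if (length(reference) == 1L) reference <- rep(reference, d[3])
  if (length(reference) != d[3])
    stop("reference length must match the wavelength grid")
  x <- matrix(cube@data, d[1] * d[2], d[3])
  x <- sweep(x, 2L, reference, "/")
  mu <- rowMeans(x)
  sig <- sqrt(rowMeans((x - mu)^2))
  matrix(sig, d[1], d[2])
}

#' Map Sigma to chromatin packing scaling D through a calibration
#'
#' The functional relation between spectral variance and the packing
#' scaling D depends on the optical system and is supplied by the user:
#' identity (pass-through), affine (\code{a * Sigma + b}), or a monotone
#' tabulated curve interpolated linearly.
#'
#' @param sigmaMap numeric matrix from \code{\link{computeSigma}}.
#' @param calibration \code{"identity"}, numeric(2) \code{c(a, b)} for
#'   affine, or a data.frame/list with strictly monotone \code{sigma} and
#'   \code{d} vectors for tabulated interpolation.
#' @return numeric matrix of D values (calibration recorded in
#'   \code{attr(, "calibration")})
#' @export
sigmaToD <- function(sigmaMap, calibration = "identity") {
  if (identical(calibration, "identity")) {
    out <- sigmaMap
    attr(out, "calibration") <- "identity"
    return(out)
  }
  if (is.numeric(calibration) && length(calibration) == 2L) {
    out <- calibration[1] * sigmaMap + calibration[2]
    attr(out, "calibration") <- sprintf("affine a=%g b=%g",
                                        calibration[1], calibration[2])
    return(out)
  }
  tab <- as.list(calibration)
  if (!all(c("sigma", "d") %in% names(tab)))
    stop("tabulated calibration needs 'sigma' and 'd'")
  ds <- diff(tab$sigma)
  if (any(ds <= 0) || (!all(diff(tab$d) > 0) && !all(diff(tab$d) < 0)))
    stop("calibration table must be strictly monotone")
  out <- matrix(approx(tab$sigma, tab$d, xout = as.vector(sigmaMap),
                       rule = 2)$y, nrow(sigmaMap), ncol(sigmaMap))
  attr(out, "calibration") <- "tabulated"
  out
}

#' Per-pixel temporal interference variance (Sigma_t^2)
#'
#' Population variance over frames of the reference-normalized intensity at
#' each pixel of a temporal cube.
#'
#' @param cube \linkS4class{ImageStack} with axis "time" (>= 10 frames).
#' @param reference per-frame reference (scalar or vector), default 1.
#' @return numeric matrix of temporal variances
#' @export
temporalVariance <- function(cube, reference = 1) {
  stopifnot(is(cube, "ImageStack"))
  if (cube@axis != "time") stop("temporalVariance needs a time-axis cube")
  d <- dim(cube@data)
  if (d[3] < 10) stop("need at least 10 frames")
  if (any(reference <= 0)) stop("reference must be strictly positive")
  if (length(reference) == 1L) reference <- rep(reference, d[3])
  x <- matrix(cube@data, d[1] * d[2], d[3])
  x <- sweep(x, 2L, reference, "/")
  mu <- rowMeans(x)
  matrix(rowMeans((x - mu)^2), d[1], d[2])
}

#' Fractional moving mass from temporal variance
#'
#' Applies the physical normalization that converts temporal interference
#' variance into the fractional moving mass
#' \eqn{m_f = m_c \varphi} (mass of the typical moving macromolecular
#' cluster times the mobile volume fraction):
#' \deqn{m_f = \Sigma_t^2 \cdot \frac{\pi \rho_0}{2 \Gamma^2 k^3 n_i}
#'   \left(\frac{NA_i}{NA_c}\right)^2
#'   \left(\frac{n_1}{n_m - n_1}\right)^2}
#' With \code{k} in 1/cm and \code{rho0} in g/cm^3 the prefactor carries
#' units of grams.  \code{Gamma} has no default and must be present in the
#' constants (see \code{\link{fresnelGamma}}).
#'
#' @param sigmaT2Map numeric matrix from \code{\link{temporalVariance}}.
#' @param constants an \linkS4class{OpticalConstants} with \code{Gamma} set.
#' @return numeric matrix of m_f (g); the prefactor is recorded in
#'   \code{attr(, "prefactor")}
#' @export
fractionalMovingMass <- function(sigmaT2Map, constants) {
  stopifnot(is(constants, "OpticalConstants"))
  if (is.na(constants@Gamma))
    stop("Gamma is unset: supply the Fresnel intensity coefficient for ",
         "your reference interface (see fresnelGamma()) via ",
         "opticalConstants(Gamma = ...)")
  C <- movingMassPrefactor(constants)
  out <- C * sigmaT2Map
  attr(out, "prefactor") <- C
  out
}

#' Prefactor of the fractional-moving-mass normalization
#'
#' @param constants an \linkS4class{OpticalConstants} with \code{Gamma} set.
#' @return numeric(1), grams
#' @export
movingMassPrefactor <- function(constants) {
  with(list(o = constants),
       (pi * o@rho0 / (2 * o@Gamma^2 * o@k^3 * o@n_i)) *
       (o@NA_i / o@NA_c)^2 * (o@n_1 / (o@n_m - o@n_1))^2)
}

#' Autocorrelation-decay rate map of a temporal cube
#'
#' For every in-mask pixel, computes the normalized autocovariance of the
#' intensity series and fits a single exponential \eqn{\exp(-t/\tau)} by
#' ordinary least squares on the log-transformed positive autocorrelation
#' values over the first \code{fitLags} lags (lag 0 excluded).  The decay
#' rate \eqn{1/\tau} in 1/s is returned per pixel; an optional
#' multiplicative \code{diffusionConstant} converts rates to diffusion
#' units.  Pixels whose lag-1 autocorrelation is non-positive, or with fewer
#' than 3 positive early lags, are noise-dominated: they are flagged
#' \code{NA} and excluded from regional means.
#'
#' @param cube \linkS4class{ImageStack} with axis "time" (>= 50 frames).
#' @param mask logical matrix or \linkS4class{NucleusMask}; default all
#'   pixels.
#' @param fitLags number of lags in the fit window (>= 3, default 10).
#' @param diffusionConstant multiplicative conversion from decay rate to
#'   diffusion units (default 1: rates are returned).
#' @return numeric matrix of decay rates (1/s, scaled by
#'   \code{diffusionConstant}); NA marks flagged or out-of-mask pixels.
#'   \code{attr(, "nFlagged")} counts flagged in-mask pixels.
#' @export
diffusionMap <- function(cube, mask = NULL, fitLags = 10L,
                         diffusionConstant = 1) {
  stopifnot(is(cube, "ImageStack"))
  if (cube@axis != "time") stop("diffusionMap needs a time-axis cube")
  d <- dim(cube@data)
  frames <- d[3]
  if (frames < 50) stop("need at least 50 frames for ACF fitting")
  fitLags <- as.integer(fitLags)
  if (fitLags < 3L) stop("fitLags must be >= 3")
  dt <- if (length(cube@axisValues) >= 2)
    cube@axisValues[2] - cube@axisValues[1] else 1
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (is(mask, "NucleusMask")) mask <- maskRaster(mask)
  x <- matrix(cube@data, d[1] * d[2], frames)[which(mask), , drop = FALSE]
  xc <- x - rowMeans(x)
  v0 <- rowMeans(xc^2)
  # normalized autocovariance at lags 1..fitLags (population normalization)
  acfs <- vapply(seq_len(fitLags), function(l)
    rowMeans(xc[, 1:(frames - l), drop = FALSE] *
             xc[, (1 + l):frames, drop = FALSE]) * (frames - l) / frames,
    numeric(nrow(xc)))
  acfs <- matrix(acfs / v0, nrow = nrow(xc))
  lagT <- seq_len(fitLags) * dt
  rate <- apply(acfs, 1L, function(a) {
    if (is.na(a[1]) || a[1] <= 0) return(NA_real_)
    pos <- which(a > 0)
    # fit over the leading run of positive ACF values
    lead <- pos[pos == seq_along(pos)]
    if (length(lead) < 3L) return(NA_real_)
    fit <- lm(log(a[lead]) ~ lagT[lead])
    -unname(coef(fit)[2])
  })
  out <- matrix(NA_real_, d[1], d[2])
  out[which(mask)] <- rate * diffusionConstant
  attr(out, "nFlagged") <- sum(is.na(rate))
  out
}

#' Regional aggregation of a per-pixel map over ribbons
#'
#' Mean of valid (finite) pixels in each region of a partition; with a
#' paired map (same cells after treatment), the per-region percent change
#' \eqn{100 (treated - control)/control} is also reported.  Flagged
#' (\code{NA}) pixels are excluded and their counts reported; regions with
#' no valid pixel are returned as \code{NA} means.
#'
#' @param map numeric matrix (e.g. D, m_f or decay-rate map).
#' @param regions a \linkS4class{RegionPartition} (usually ribbons).
#' @param pairedMap optional second map of identical frame.
#' @return data.frame with \code{region}, \code{mean}, \code{nValid},
#'   \code{nFlagged} (plus \code{meanPaired}, \code{pctChange} when paired)
#' @export
regionalDynamics <- function(map, regions, pairedMap = NULL) {
  stopifnot(is(regions, "RegionPartition"))
  lab <- regionLabels(regions)
  if (!all(dim(map) == dim(lab)))
    stop("map and region partition frames differ")
  K <- nRegions(regions)
  one <- function(mp, k) {
    v <- mp[lab == k]
    ok <- is.finite(v)
    c(mean = if (any(ok)) mean(v[ok]) else NA_real_,
      nValid = sum(ok), nFlagged = sum(!ok))
  }
  a <- t(vapply(seq_len(K), function(k) one(map, k), numeric(3)))
  out <- data.frame(region = regions@regionNames, mean = a[, 1],
                    nValid = as.integer(a[, 2]),
                    nFlagged = as.integer(a[, 3]))
  if (!is.null(pairedMap)) {
    if (!all(dim(pairedMap) == dim(lab)))
      stop("pairedMap frame differs from the partition")
    b <- t(vapply(seq_len(K), function(k) one(pairedMap, k), numeric(3)))
    out$meanPaired <- b[, 1]
    out$pctChange <- 100 * (b[, 1] - a[, 1]) / a[, 1]
  }
  out
}
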