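# Seeded synthetic-data generators.  Each generator emulates one class of
# study input (segmented nuclei, radial fluorescence, SMLM events, contact
# maps, temporal/spectral interference cubes, expression tables, gene/LAD
# layouts) with analytically known structure, so every downstream statistic
# can be tested for recovery of planted truth.  All generators are
# deterministic given (seed, parameters) and leave the caller's RNG state
# untouched; expected-value ("noiseless") modes exist wherever sampling is
# involved.

#' Simulate an elliptical nucleus mask
#'
#' Rasterizes an ellipse with semi-axes given in nm at the stated pixel size.
#' Pixel-centre inclusion is used, so for large masks the pixel area matches
#' the continuous area \eqn{\pi a b / pixelSize^2} within a fraction of a
#' percent.
#'
#' @param widthPx,heightPx frame size in pixels (columns, rows).
#' @param pixelSizeNm nm per pixel.
#' @param semiAxesNm numeric(2): semi-axes (a, b) in nm.
#' @param center frame centre by default; numeric(2) pixel coordinates
#'   (x = column, y = row).
#' @param rotationDeg rotation of the a-axis, degrees counter-clockwise.
#' @param id nucleus identifier.
#' @return a \linkS4class{NucleusMask}
#' @examples
#' m <- simNucleusMask(128, 128, 130, c(6500, 6500))
#' maskArea(m) / (pi * 50^2)   # close to 1
#' @export
simNucleusMask <- function(widthPx, heightPx, pixelSizeNm, semiAxesNm,
                           center = c(widthPx, heightPx) / 2,
                           rotationDeg = 0, id = "sim") {
  a <- semiAxesNm[1] / pixelSizeNm
  b <- semiAxesNm[2] / pixelSizeNm
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  rmax <- max(a, b)
  if (center[1] - rmax < 0 || center[1] + rmax > widthPx ||
      center[2] - rmax < 0 || center[2] + rmax > heightPx)
    stop("ellipse does not fit inside the frame")
  g <- .pixelGrid(heightPx, widthPx)
  # pixel centres at (col - 0.5, row - 0.5)
  dx <- g$col - 0.5 - center[1]
  dy <- g$row - 0.5 - center[2]
  th <- rotationDeg * pi / 180
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  NucleusMask(u^2 + v^2 <= 1, pixelSizeNm, id = id, fillHoles = FALSE)
}

#' Simulate a radial intensity image over a nucleus
#'
#' Expected pixel intensity is proportional to \code{profile(rho)} where
#' \code{rho} is the normalized boundary-distance radial coordinate
#' (\code{\link{normalizedRadialCoordinate}}), scaled so the expected in-mask
#' total equals \code{totalIntensity}.  With \code{noiseModel = "none"} the
#' expected image is returned; with \code{"poisson"} each pixel is Poisson
#' sampled.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param profile non-negative function of rho in [0, 1].
#' @param totalIntensity expected total in-mask intensity.
#' @param noiseModel "none" or "poisson".
#' @param seed RNG seed for the Poisson mode.
#' @return numeric matrix in the mask frame
#' @export
simRadialImage <- function(mask, profile, totalIntensity = 1e6,
                           noiseModel = c("none", "poisson"), seed = NULL) {
  noiseModel <- match.arg(noiseModel)
  rho <- normalizedRadialCoordinate(mask)
  m <- maskRaster(mask)
  vals <- profile(rho[m])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("profile must be finite and non-negative on [0, 1]")
  if (sum(vals) == 0) stop("profile is identically zero over the mask")
  lambda <- vals / sum(vals) * totalIntensity
  img <- matrix(0, nrow(m), ncol(m))
  img[m] <- if (noiseModel == "none") lambda else
    withSeed(seed, rpois(length(lambda), lambda))
  img
}

#' Simulate foci with a prescribed radial distribution
#'
#' Draws \code{n} points inside the mask whose normalized radial coordinate
#' rho follows the supplied marginal density.  Geometric area weighting is
#' explicit in the contract: \code{radialDensity} is the marginal density of
#' rho itself, so a distribution uniform over the nuclear area corresponds to
#' \code{function(rho) 2 * rho} (the 2*pi*rho annulus weighting), not to a
#' constant.  Sampling inverts the CDF of the density on a fine grid, picks a
#' mask pixel from the matching rho stratum, and jitters uniformly within the
#' pixel.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param n number of foci (> 0).
#' @param radialDensity non-negative function on [0, 1]; marginal density of
#'   rho.  Default: uniform over area.
#' @param seed RNG seed.
#' @return data.frame with columns \code{x}, \code{y} (nm, frame
#'   coordinates) and \code{rho}
#' @export
simFoci <- function(mask, n, radialDensity = function(rho) 2 * rho,
                    seed = NULL) {
  if (n <= 0) stop("n must be positive")
  rho <- normalizedRadialCoordinate(mask)
  m <- maskRaster(mask)
  ps <- pixelSize(mask)
  rhoIn <- rho[m]
  idxIn <- which(m)
  nGrid <- 512L
  grid <- seq(0, 1, length.out = nGrid)
  dens <- radialDensity(grid)
  if (any(!is.finite(dens)) || any(dens < 0))
    stop("radialDensity must be finite and non-negative")
  if (sum(dens) == 0) stop("radialDensity is identically zero")
  cdf <- cumsum(dens) / sum(dens)
  # stratify mask pixels by rho so a sampled rho maps to a nearby pixel
  strata <- findInterval(rhoIn, grid, all.inside = TRUE)
  withSeed(seed, {
    u <- runif(n)
    gi <- findInterval(u, cdf) + 1L
    gi[gi > nGrid] <- nGrid
    pick <- integer(n)
    byStratum <- split(seq_along(rhoIn), strata)
    stratumKeys <- as.integer(names(byStratum))
    for (t in seq_len(n)) {
      k <- gi[t]
      # nearest non-empty rho stratum
      s <- stratumKeys[which.min(abs(stratumKeys - k))]
      cand <- byStratum[[as.character(s)]]
      pick[t] <- cand[sample.int(length(cand), 1L)]
    }
    lin <- idxIn[pick]
    rr <- ((lin - 1L) %% nrow(m)) + 1L
    cc <- ((lin - 1L) %/% nrow(m)) + 1L
    data.frame(x = (cc - 0.5 + runif(n, -0.5, 0.5)) * ps,
               y = (rr - 0.5 + runif(n, -0.5, 0.5)) * ps,
               rho = rhoIn[pick])
  })
}

#' Simulate SMLM localizations with planted peripheral enrichment
#'
#' Each of the \code{n} events lands in the periphery mask with probability
#' \code{peripheryFraction} (uniform over periphery pixels) and otherwise
#' uniformly over the remaining nuclear pixels.  Coordinates are emitted in
#' nm with sub-pixel jitter.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param n number of localizations.
#' @param peripheryFraction expected fraction of events in the periphery.
#' @param peripheryMask logical matrix, subset of the nucleus mask.
#' @param seed RNG seed.
#' @return data.frame with columns \code{x}, \code{y} (nm) and logical
#'   \code{periphery}
#' @export
simLocalizations <- function(mask, n, peripheryFraction, peripheryMask,
                             seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (peripheryFraction < 0 || peripheryFraction > 1)
    stop("peripheryFraction must lie in [0, 1]")
  m <- maskRaster(mask)
  if (any(peripheryMask & !m))
    stop("peripheryMask must be a subset of the nucleus mask")
  per <- which(peripheryMask)
  inn <- which(m & !peripheryMask)
  if (!length(per) && peripheryFraction > 0)
    stop("empty periphery mask with peripheryFraction > 0")
  if (!length(inn) && peripheryFraction < 1)
    stop("empty interior with peripheryFraction < 1")
  ps <- pixelSize(mask)
  withSeed(seed, {
    inPer <- runif(n) < peripheryFraction
    lin <- integer(n)
    if (any(inPer))
      lin[inPer] <- per[sample.int(length(per), sum(inPer), replace = TRUE)]
    if (any(!inPer))
      lin[!inPer] <- inn[sample.int(length(inn), sum(!inPer),
                                    replace = TRUE)]
    rr <- ((lin - 1L) %% nrow(m)) + 1L
    cc <- ((lin - 1L) %/% nrow(m)) + 1L
    data.frame(x = (cc - 0.5 + runif(n, -0.5, 0.5)) * ps,
               y = (rr - 0.5 + runif(n, -0.5, 0.5)) * ps,
               periphery = inPer)
  })
}

#' Simulate a cis contact map with segment-class power laws
#'
#' Expected count for bin pair (i, j), i != j, is
#' \eqn{scale \cdot d^{-s_c}} with \eqn{d = |i - j| \cdot resolution} bp and
#' \eqn{s_c} the exponent of the pair's segment class: both anchors in a LAD
#' ("lad"), both outside ("nonlad"), or one of each ("cross").  When
#' \code{totalContacts} is given, \code{scale} is set so the expected
#' upper-triangle total equals it.  In \code{mode = "poisson"} counts are
#' Poisson sampled and then rescaled by a single global constant so the grand
#' total matches \code{totalContacts} (a multiplicative constant, so fitted
#' exponents are unaffected); \code{mode = "expected"} returns the noiseless
#' expectations.  The diagonal is zero.
#'
#' @param nBins number of bins.
#' @param resolution bin size in bp.
#' @param ladLayout logical vector of length \code{nBins} (TRUE = LAD bin),
#'   or a list of integer bin ranges \code{c(from, to)} marking LADs.
#' @param exponents named list/vector with elements \code{lad},
#'   \code{nonlad}, \code{cross}; all >= 0.  Classes absent from the layout
#'   may be omitted.
#' @param totalContacts target expected total over the upper triangle
#'   (ignored when \code{scale} is given).
#' @param scale explicit prefactor; overrides \code{totalContacts}.
#' @param mode "poisson" or "expected".
#' @param seed RNG seed.
#' @param chrom chromosome name for the output matrix.
#' @return list with elements \code{matrix} (\linkS4class{ContactMatrix}) and
#'   \code{labels} (factor of "LAD"/"nonLAD" per bin)
#' @export
simCisContactMap <- function(nBins, resolution, ladLayout, exponents,
                             totalContacts = 5e6, scale = NULL,
                             mode = c("poisson", "expected"), seed = NULL,
                             chrom = "chrSim") {
  mode <- match.arg(mode)
  lad <- if (is.list(ladLayout)) {
    v <- logical(nBins)
    for (r in ladLayout) v[r[1]:r[2]] <- TRUE
    v
  } else as.logical(ladLayout)
  stopifnot(length(lad) == nBins)
  ex <- as.list(exponents)
  pairs <- which(upper.tri(matrix(0L, nBins, nBins)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  cls <- ifelse(lad[i] & lad[j], "lad",
                ifelse(!lad[i] & !lad[j], "nonlad", "cross"))
  needed <- unique(cls)
  miss <- setdiff(needed, names(ex))
  if (length(miss))
    stop("exponents missing for classes present in the layout: ",
         paste(miss, collapse = ", "))
  s <- unlist(ex[cls], use.names = FALSE)
  if (any(s < 0)) stop("exponents must be non-negative")
  d <- (j - i) * resolution
  lambda0 <- d^(-s)
  if (is.null(scale)) scale <- totalContacts / sum(lambda0)
  lambda <- scale * lambda0
  cnt <- if (mode == "expected") lambda else withSeed(seed, {
    x <- rpois(length(lambda), lambda)
    if (!is.null(totalContacts) && sum(x) > 0)
      x * (totalContacts / sum(x)) else x
  })
  keep <- cnt > 0
  cm <- ContactMatrix(data.frame(i = i[keep], j = j[keep],
                                 count = cnt[keep]),
                      resolution, nBinsA = nBins, chromA = chrom)
  list(matrix = cm,
       labels = factor(ifelse(lad, "LAD", "nonLAD"),
                       levels = c("LAD", "nonLAD")))
}

#' Simulate a paired control/treated trans contact block
#'
#' Control entries are Poisson(\code{baseline}); treated entries are
#' Poisson(\code{baseline * foldChange}), giving an expected percent change
#' of \code{100 * (foldChange - 1)} in mean trans contact frequency.
#'
#' @param nBinsA,nBinsB block extent in bins.
#' @param baseline expected control count per entry (> 0).
#' @param foldChange treated/control expectation ratio (> 0).
#' @param resolution bin size in bp (metadata only).
#' @param seed RNG seed.
#' @param chromA,chromB chromosome names.
#' @return list with \linkS4class{ContactMatrix} elements \code{control} and
#'   \code{treated}
#' @export
simTransContacts <- function(nBinsA, nBinsB, baseline, foldChange,
                             resolution = 1e6, seed = NULL,
                             chromA = "chrA", chromB = "chrB") {
  if (baseline <= 0) stop("baseline must be positive")
  if (foldChange <= 0) stop("foldChange must be positive")
  ij <- expand.grid(i = seq_len(nBinsA), j = seq_len(nBinsB))
  withSeed(seed, {
    ctrl <- rpois(nrow(ij), baseline)
    trt <- rpois(nrow(ij), baseline * foldChange)
    mk <- function(cnt)
      ContactMatrix(data.frame(i = ij$i, j = ij$j, count = cnt)[cnt > 0, ],
                    resolution, nBinsA = nBinsA, nBinsB = nBinsB,
                    chromA = chromA, chromB = chromB)
    list(control = mk(ctrl), treated = mk(trt))
  })
}

#' Simulate a temporal interference cube
#'
#' Every in-mask pixel is an independent stationary AR(1) series (the exact
#' discretization of an Ornstein-Uhlenbeck process) around a mean level of 1
#' (reference-normalized intensity), with stationary variance
#' \code{variance} and autocorrelation \eqn{\exp(-t/\tau)}.  Out-of-mask
#' pixels are constant 1.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param frames number of frames (>= 10).
#' @param dtS frame interval in seconds (> 0).
#' @param variance stationary variance of the normalized intensity.
#' @param tauS correlation time in seconds (> 0).
#' @param seed RNG seed.
#' @return an \linkS4class{ImageStack} with axis "time"
#' @export
simTemporalCube <- function(mask, frames, dtS, variance, tauS, seed = NULL) {
  if (dtS <= 0) stop("dtS must be positive")
  if (tauS <= 0) stop("tauS must be positive")
  if (frames < 10) stop("need at least 10 frames")
  m <- maskRaster(mask)
  npx <- sum(m)
  phi <- exp(-dtS / tauS)
  cube <- array(1, c(nrow(m), ncol(m), frames))
  if (variance > 0) {
    x <- withSeed(seed, {
      out <- matrix(0, npx, frames)
      out[, 1] <- rnorm(npx, 0, sqrt(variance))
      innovSd <- sqrt(variance * (1 - phi^2))
      for (t in 2:frames)
        out[, t] <- phi * out[, t - 1] + rnorm(npx, 0, innovSd)
      out
    })
    idx <- which(m)
    for (t in seq_len(frames)) {
      plane <- cube[, , t]
      plane[idx] <- 1 + x[, t]
      cube[, , t] <- plane
    }
  }
  ImageStack(cube, pixelSize(mask), axis = "time",
             axisValues = (seq_len(frames) - 1) * dtS)
}

#' Simulate a spectral interference cube
#'
#' Per-pixel reference-normalized spectra with mean 1 and a prescribed
#' standard deviation over wavelength.  \code{mode = "sinusoid"} produces a
#' deterministic modulation of amplitude \code{sqrt(2) * sigma} over an
#' integer number of cycles, so the population spectral standard deviation
#' equals \code{sigma} exactly; \code{mode = "random"} adds i.i.d. Gaussian
#' fluctuations of standard deviation \code{sigma}.
#'
#' @param mask a \linkS4class{NucleusMask}.
#' @param sigmaMap numeric matrix (or scalar) of target spectral sd.
#' @param wavelengths wavelength grid in nm (length >= 3); default
#'   500-700 nm at 2 nm.
#' @param mode "random" or "sinusoid".
#' @param cycles integer sinusoid cycles across the grid.
#' @param seed RNG seed (random mode).
#' @return an \linkS4class{ImageStack} with axis "wavelength"
#' @export
simSpectralCube <- function(mask, sigmaMap,
                            wavelengths = seq(500, 700, by = 2),
                            mode = c("random", "sinusoid"), cycles = 4L,
                            seed = NULL) {
  mode <- match.arg(mode)
  if (length(wavelengths) < 3) stop("wavelength grid shorter than 3")
  m <- maskRaster(mask)
  if (length(sigmaMap) == 1L)
    sigmaMap <- matrix(sigmaMap, nrow(m), ncol(m))
  if (any(sigmaMap[m] < 0)) stop("sigmaMap must be non-negative")
  nl <- length(wavelengths)
  cube <- array(1, c(nrow(m), ncol(m), nl))
  idx <- which(m)
  sig <- sigmaMap[idx]
  if (mode == "sinusoid") {
    wave <- sin(2 * pi * cycles * (seq_len(nl) - 1) / nl)
    for (l in seq_len(nl)) {
      plane <- cube[, , l]
      plane[idx] <- 1 + sqrt(2) * sig * wave[l]
      cube[, , l] <- plane
    }
  } else {
    z <- withSeed(seed, matrix(rnorm(length(idx) * nl), length(idx), nl))
    for (l in seq_len(nl)) {
      plane <- cube[, , l]
      plane[idx] <- 1 + sig * z[, l]
      cube[, , l] <- plane
    }
  }
  ImageStack(cube, pixelSize(mask), axis = "wavelength",
             axisValues = wavelengths)
}

#' Simulate a lognormal expression table
#'
#' Values are i.i.d. lognormal(0, sigma^2).  The population Gini coefficient
#' of this distribution is \eqn{\mathrm{erf}(\sigma/2)} =
#' \code{2 * pnorm(sigma / sqrt(2)) - 1}, which \code{\link{gini}} recovers
#' on large samples.
#'
#' @param nGenes number of genes.
#' @param lognormalSigma sigma of log expression (>= 0).
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene} and \code{expression}
#' @export
simExpression <- function(nGenes, lognormalSigma, seed = NULL) {
  if (lognormalSigma < 0) stop("lognormalSigma must be non-negative")
  vals <- withSeed(seed, rlnorm(nGenes, 0, lognormalSigma))
  data.frame(gene = sprintf("g%05d", seq_len(nGenes)), expression = vals)
}

#' Theoretical Gini coefficient of a lognormal distribution
#'
#' @param sigma lognormal shape parameter.
#' @return \eqn{\mathrm{erf}(\sigma/2)}
#' @export
lognormalGini <- function(sigma) 2 * pnorm(sigma / sqrt(2)) - 1

#' Simulate a gene/LAD layout with a planted within-LAD fraction
#'
#' Places \code{nLads} non-overlapping LADs of length \code{ladLenBp} evenly
#' along a linear genome, then places exactly
#' \code{round(fracWithin * nGenes)} genes strictly inside LADs and the rest
#' strictly outside, with a safety margin from every LAD boundary so
#' any-overlap classification recovers the planted labels exactly.
#'
#' @param genomeBp genome (chromosome) length in bp.
#' @param nLads number of LADs.
#' @param ladLenBp LAD length in bp.
#' @param nGenes number of genes.
#' @param fracWithin planted fraction of genes overlapping a LAD.
#' @param geneLenBp gene length in bp (default 2000).
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @return list with \code{genes} (GRanges with logical metadata column
#'   \code{withinLad}, the truth labels) and \code{lads} (GRanges)
#' @export
simGenesAndLads <- function(genomeBp, nLads, ladLenBp, nGenes, fracWithin,
                            geneLenBp = 2000, seed = NULL, chrom = "chrS") {
  margin <- geneLenBp + 10L
  gapTotal <- genomeBp - nLads * ladLenBp
  if (gapTotal < (nLads + 1) * (2 * margin + geneLenBp))
    stop("genome too small for the requested LAD layout")
  if (ladLenBp < 2 * margin + geneLenBp)
    stop("LADs too short to contain genes with a safety margin")
  gap <- floor(gapTotal / (nLads + 1))
  ladStart <- gap + (seq_len(nLads) - 1) * (ladLenBp + gap) + 1
  lads <- GRanges(chrom, IRanges(ladStart, ladStart + ladLenBp - 1))
  nIn <- round(fracWithin * nGenes)
  nOut <- nGenes - nIn
  withSeed(seed, {
    placeIn <- function(k) {
      lad <- sample.int(nLads, k, replace = TRUE)
      lo <- ladStart[lad] + margin
      hi <- ladStart[lad] + ladLenBp - 1 - margin - geneLenBp
      floor(lo + runif(k) * (hi - lo))
    }
    placeOut <- function(k) {
      g <- sample.int(nLads + 1, k, replace = TRUE)
      gapStart <- c(1, ladStart + ladLenBp)
      lo <- gapStart[g] + margin
      hi <- gapStart[g] + gap - 1 - margin - geneLenBp
      floor(lo + runif(k) * (hi - lo))
    }
    starts <- c(if (nIn) placeIn(nIn), if (nOut) placeOut(nOut))
    genes <- GRanges(chrom, IRanges(starts, starts + geneLenBp - 1))
    mcols(genes)$gene <- sprintf("g%05d", seq_len(nGenes))
    mcols(genes)$withinLad <- rep(c(TRUE, FALSE), c(nIn, nOut))
    ord <- order(start(genes))
    list(genes = genes[ord], lads = lads)
  })
}
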