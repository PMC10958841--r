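# Signal statistics over geometric partitions: ring occupancy with 2k-1
# normalization, normalized regional intensity (NSI), coefficient of
# variation, localization-image reconstruction, and foci distance metrics.

#' Radial ring occupancy of a fluorescence signal
#'
#' For a ring partition of K concentric rings, computes the raw fraction of
#' total in-mask intensity in each ring, \eqn{f_k}, and the area-normalized
#' value \eqn{g_k = f_k / (2k - 1)}: under the circular idealization ring k
#' has area proportional to \eqn{2k - 1}, so a uniformly distributed signal
#' gives equal \eqn{g_k} across rings.  A renormalized profile
#' (\eqn{g_k / \sum g_k}) is also reported for plotting comparability, and
#' measured ring pixel areas allow an empirical-area normalization instead.
#'
#' @param image numeric matrix of non-negative intensities, same frame as
#'   the rings.
#' @param rings a \linkS4class{RegionPartition} of type "rings"
#'   (\code{\link{makeRings}}).
#' @return data.frame with columns \code{ring}, \code{fraction} (f_k),
#'   \code{weight} (2k-1), \code{normalized} (g_k), \code{normalizedRenorm},
#'   \code{areaPx}
#' @export
ringOccupancy <- function(image, rings) {
  stopifnot(is(rings, "RegionPartition"), rings@type == "rings")
  if (!all(dim(image) == dim(regionLabels(rings))))
    stop("image and ring partition frames differ")
  lab <- regionLabels(rings)
  K <- nRegions(rings)
  inMask <- lab > 0L
  tot <- sum(image[inMask])
  if (tot <= 0) stop("zero total intensity inside the mask")
  sums <- vapply(seq_len(K), function(k) sum(image[lab == k]), 0)
  f <- sums / tot
  w <- rings@params$weights
  g <- f / w
  data.frame(ring = seq_len(K), fraction = f, weight = w, normalized = g,
             normalizedRenorm = g / sum(g), areaPx = rings@areas)
}

#' Summarize ring occupancy across nuclei
#'
#' Per-ring mean and standard error of the raw fractions across a list of
#' per-nucleus profiles, plus per-ring differences of means when two
#' conditions are supplied.
#'
#' @param profiles list of data.frames from \code{\link{ringOccupancy}}.
#' @param profilesB optional second condition.
#' @param column which profile column to aggregate (default "fraction").
#' @return data.frame with per-ring \code{mean}, \code{sem}, \code{n} (and
#'   \code{meanB}, \code{semB}, \code{diff} when two conditions are given)
#' @export
ringOccupancySummary <- function(profiles, profilesB = NULL,
                                 column = "fraction") {
  agg <- function(ps) {
    m <- vapply(ps, function(p) p[[column]], numeric(nrow(ps[[1]])))
    m <- matrix(m, nrow = nrow(ps[[1]]))
    list(mean = rowMeans(m),
         sem = apply(m, 1, sd) / sqrt(ncol(m)), n = ncol(m))
  }
  a <- agg(profiles)
  out <- data.frame(ring = profiles[[1]]$ring, mean = a$mean, sem = a$sem,
                    n = a$n)
  if (!is.null(profilesB)) {
    b <- agg(profilesB)
    out$meanB <- b$mean; out$semB <- b$sem; out$nB <- b$n
    out$diff <- b$mean - a$mean
  }
  out
}

#' Normalized regional intensity (NSI)
#'
#' The mean pixel intensity inside a regional mask divided by the mean pixel
#' intensity over the whole nucleus:
#' \deqn{NSI = \frac{\sum_i s_i / A_{mask}}{\sum_j s_j / A_{nuc}}}
#' NSI = 1 means the region carries signal in proportion to its area; NSI of
#' a half-area region containing all signal is 2.  For any disjoint
#' partition of the nucleus, the area-weighted NSI values sum to exactly 1.
#'
#' @param image numeric matrix (e.g. a reconstructed localization image).
#' @param regionMask logical matrix, subset of \code{nucleusMask}.
#' @param nucleusMask logical matrix or \linkS4class{NucleusMask}.
#' @return list with \code{nsi}, \code{aMask}, \code{aNuc}, \code{sMask},
#'   \code{sNuc}
#' @export
computeNsi <- function(image, regionMask, nucleusMask) {
  if (is(nucleusMask, "NucleusMask")) nucleusMask <- maskRaster(nucleusMask)
  if (any(regionMask & !nucleusMask))
    stop("regionMask must be a subset of the nucleus mask")
  aMask <- sum(regionMask); aNuc <- sum(nucleusMask)
  if (aMask == 0L) stop("empty region mask")
  sMask <- sum(image[regionMask]); sNuc <- sum(image[nucleusMask])
  if (sNuc <= 0) stop("zero total nuclear intensity")
  list(nsi = (sMask / aMask) / (sNuc / aNuc), aMask = aMask, aNuc = aNuc,
       sMask = sMask, sNuc = sNuc)
}

#' Coefficient of variation of in-mask intensity
#'
#' \eqn{CoV = \sigma / \mu} over the in-mask pixel intensities, a proxy for
#' chromatin compaction heterogeneity.  Population standard deviation by
#' default (denominator n), switchable to the sample estimator.
#'
#' @param image numeric matrix.
#' @param mask logical matrix or \linkS4class{NucleusMask}.
#' @param variant "population" (default) or "sample".
#' @return list with \code{cov}, \code{sigma}, \code{mu}, \code{n}
#' @export
computeCov <- function(image, mask, variant = c("population", "sample")) {
  variant <- match.arg(variant)
  if (is(mask, "NucleusMask")) mask <- maskRaster(mask)
  x <- image[mask]
  mu <- mean(x)
  if (mu == 0) stop("mean intensity is zero; CoV undefined")
  sigma <- if (variant == "population") popSd(x) else sd(x)
  list(cov = sigma / mu, sigma = sigma, mu = mu, n = length(x))
}

#' Reconstruct an intensity image from localization events
#'
#' Default mode is a plain 2D count histogram at \code{binNm} per pixel, so
#' pixel intensity is the count of localized events in that bin.  The
#' average-shifted-histogram (ASH) mode averages \code{m^2} histograms whose
#' origins are shifted on an m x m subgrid of the bin, trading a small blur
#' for reduced binning artefacts.  Both modes conserve the total:
#' the image sums to the number of localizations.
#'
#' @param locs data.frame with \code{x}, \code{y} in nm
#'   (\code{\link{readLocalizations}} output).
#' @param binNm bin size in nm (default 26).
#' @param frame integer(2): image size (rows, cols); default is the smallest
#'   frame containing all events.
#' @param mode "histogram" or "ash".
#' @param m ASH shift count per axis (default 2).
#' @return numeric matrix
#' @export
reconstructImage <- function(locs, binNm = 26, frame = NULL,
                             mode = c("histogram", "ash"), m = 2L) {
  mode <- match.arg(mode)
  if (binNm <= 0) stop("binNm must be positive")
  if (is.null(frame)) {
    if (!nrow(locs)) stop("empty localization table and no frame given")
    frame <- c(floor(max(locs$y) / binNm) + 1L,
               floor(max(locs$x) / binNm) + 1L)
  }
  nr <- frame[1]; nc <- frame[2]
  binOnce <- function(offX, offY) {
    r <- floor((locs$y - offY) / binNm) + 1L
    c <- floor((locs$x - offX) / binNm) + 1L
    r <- pmin(pmax(r, 1L), nr)
    c <- pmin(pmax(c, 1L), nc)
    matrix(as.numeric(tabulate(r + (c - 1L) * nr, nbins = nr * nc)),
           nr, nc)
  }
  if (!nrow(locs)) return(matrix(0, nr, nc))
  if (mode == "histogram") return(binOnce(0, 0))
  m <- as.integer(m)
  acc <- matrix(0, nr, nc)
  shifts <- (seq_len(m) - 1) / m * binNm
  for (sx in shifts) for (sy in shifts)
    acc <- acc + binOnce(sx, sy)
  acc / m^2
}

#' Focus-to-centroid normalized distances
#'
#' Distance from each focus to the nucleus centroid divided by the
#' circular-equivalent radius (\code{\link{centroidRadius}}).  An
#' area-normalized variant \eqn{d / \sqrt{area}} is reported alongside
#' (dimensionally consistent reading of normalizing by the nuclear area; the
#' literal \eqn{d / area}, in 1/nm, is included as \code{dOverArea} for
#' completeness).
#'
#' @param foci data.frame with \code{x}, \code{y} in nm.
#' @param cr output of \code{\link{centroidRadius}}.
#' @return list with \code{perFocus} data.frame (\code{dNm}, \code{dOverR},
#'   \code{dOverSqrtArea}, \code{dOverArea}) and scalars \code{meanDOverR},
#'   \code{n}
#' @export
fociDistances <- function(foci, cr) {
  if (cr$radiusNm <= 0) stop("non-positive nucleus radius")
  if (!nrow(foci))
    return(list(perFocus = data.frame(dNm = numeric(), dOverR = numeric(),
                                      dOverSqrtArea = numeric(),
                                      dOverArea = numeric()),
                meanDOverR = NA_real_, n = 0L))
  d <- sqrt((foci$x - cr$centroidNm["x"])^2 +
            (foci$y - cr$centroidNm["y"])^2)
  per <- data.frame(dNm = d, dOverR = d / cr$radiusNm,
                    dOverSqrtArea = d / sqrt(cr$areaNm2),
                    dOverArea = d / cr$areaNm2)
  list(perFocus = per, meanDOverR = mean(per$dOverR), n = nrow(per))
}

#' Pairwise distances between two foci label sets in one nucleus
#'
#' Matches foci of label set A to foci of label set B by greedy nearest-pair
#' assignment (repeatedly take the globally closest unmatched pair), then
#' normalizes matched Euclidean distances by the circular-equivalent nuclear
#' radius.  An exhaustive optimal assignment (minimum total distance over
#' all permutations) is available for small sets via
#' \code{method = "optimal"}.
#'
#' @param fociA,fociB data.frames with \code{x}, \code{y} in nm.
#' @param cr output of \code{\link{centroidRadius}}.
#' @param method "greedy" (default) or "optimal" (exhaustive; needs
#'   \code{min(nA, nB) <= 8}).
#' @return list with \code{pairs} data.frame (\code{a}, \code{b},
#'   \code{dNm}, \code{dOverR}), \code{meanDOverR}, \code{n}, and
#'   \code{empty} flag
#' @export
pairwiseFociDistances <- function(fociA, fociB, cr,
                                  method = c("greedy", "optimal")) {
  method <- match.arg(method)
  if (!nrow(fociA) || !nrow(fociB))
    return(list(pairs = data.frame(a = integer(), b = integer(),
                                   dNm = numeric(), dOverR = numeric()),
                meanDOverR = NA_real_, n = 0L, empty = TRUE))
  D <- outer(seq_len(nrow(fociA)), seq_len(nrow(fociB)),
             function(ia, ib) sqrt((fociA$x[ia] - fociB$x[ib])^2 +
                                   (fociA$y[ia] - fociB$y[ib])^2))
  nPairs <- min(nrow(D), ncol(D))
  if (method == "optimal") {
    small <- which.min(dim(D))
    if (max(dim(D)) > 7L) stop("optimal assignment limited to 7 foci per set")
    Dm <- if (small == 1L) D else t(D)
    perms <- .permutations(ncol(Dm))
    best <- NULL; bestCost <- Inf
    for (p in seq_len(nrow(perms))) {
      sel <- perms[p, seq_len(nrow(Dm))]
      cost <- sum(Dm[cbind(seq_len(nrow(Dm)), sel)])
      if (cost < bestCost) { bestCost <- cost; best <- sel }
    }
    ia <- if (small == 1L) seq_len(nrow(Dm)) else best
    ib <- if (small == 1L) best else seq_len(nrow(Dm))
  } else {
    ia <- integer(nPairs); ib <- integer(nPairs)
    W <- D
    for (t in seq_len(nPairs)) {
      k <- arrayInd(which.min(W), dim(W))
      ia[t] <- k[1]; ib[t] <- k[2]
      W[k[1], ] <- Inf; W[, k[2]] <- Inf
    }
  }
  d <- D[cbind(ia, ib)]
  pairs <- data.frame(a = ia, b = ib, dNm = d, dOverR = d / cr$radiusNm)
  list(pairs = pairs, meanDOverR = mean(pairs$dOverR), n = nPairs,
       empty = FALSE)
}

# all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
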