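# LAD-aware contact-matrix analytics: bin labelling, segment-classified
# contact-probability curves, power-law exponent fits, coverage-exponential
# fits, interchromosomal change matrices, compartment eigenvectors, and
# TAD/LAD overlap summaries.

#' Label matrix bins as LAD / non-LAD
#'
#' A bin is labelled LAD iff its basepair overlap with the merged LAD
#' intervals is at least \code{minOverlap * resolution} (>= comparison, so a
#' bin exactly half covered at the default threshold is a LAD bin).
#'
#' @param lads \code{GRanges} of LAD intervals (any overlap structure;
#'   merged internally).
#' @param chrom chromosome to label.
#' @param nBins number of bins.
#' @param resolution bin size in bp.
#' @param minOverlap minimum covered fraction of a bin (default 0.5).
#' @return factor of length \code{nBins} with levels "LAD", "nonLAD"
#' @export
labelBins <- function(lads, chrom, nBins, resolution, minOverlap = 0.5) {
  lads <- reduce(lads[seqnames(lads) == chrom])
  if (length(lads) && max(end(lads)) > nBins * resolution)
    stop("LAD interval extends beyond the chromosome extent (",
         nBins * resolution, " bp)")
  bins <- GRanges(chrom, IRanges(start = (seq_len(nBins) - 1) * resolution
                                 + 1, width = resolution))
  cov <- numeric(nBins)
  if (length(lads)) {
    hits <- findOverlaps(bins, lads)
    if (length(hits)) {
      ov <- width(pintersect(bins[queryHits(hits)], lads[subjectHits(hits)]))
      cov <- cov + as.numeric(tapply(ov, factor(queryHits(hits),
                                                levels = seq_len(nBins)),
                                     sum, default = 0))
      cov[is.na(cov)] <- 0
    }
  }
  factor(ifelse(cov >= minOverlap * resolution, "LAD", "nonLAD"),
         levels = c("LAD", "nonLAD"))
}

#' Segment-classified contact-probability scaling curve
#'
#' Mean contact frequency P as a function of genomic separation N, over
#' log-spaced distance bins, restricted to bin pairs of a segment class:
#' both anchors in LAD bins ("LAD"), both in non-LAD bins ("nonLAD"), one of
#' each ("cross") or any pair ("all").  P for a distance bin is the total
#' count over qualifying pairs divided by the number of qualifying pairs
#' (zero-count pairs included in the denominator); the diagonal is excluded.
#' Distance bins with no qualifying pair are reported with \code{pairs = 0}
#' and \code{P = NA}.
#'
#' The representative separation of a log-spaced bin is the pair-weighted
#' geometric mean of its constituent distances (not the raw bin centre),
#' which removes the leading curvature bias that coarse binning would
#' otherwise impose on downstream exponent fits.
#'
#' @param cm cis \linkS4class{ContactMatrix}.
#' @param labels factor from \code{\link{labelBins}} (or the generator);
#'   may be NULL for class "all".
#' @param segmentClass "all", "LAD", "nonLAD" or "cross".
#' @param distanceBins numeric: log-spaced bins per decade (default 8), or
#'   \code{"integer"} for one bin per distinct bin-level separation.
#' @return data.frame with columns \code{distance} (bp, representative
#'   separation), \code{P}, \code{pairs}, \code{totalCount}, \code{class}
#' @export
scalingCurve <- function(cm, labels = NULL,
                         segmentClass = c("all", "LAD", "nonLAD", "cross"),
                         distanceBins = 8) {
  segmentClass <- match.arg(segmentClass)
  if (!isCis(cm)) stop("scaling curves are defined for cis matrices")
  n <- cm@nBinsA
  res <- binResolution(cm)
  if (segmentClass != "all") {
    if (is.null(labels)) stop("labels required for segment classes")
    stopifnot(length(labels) == n)
    lad <- labels == "LAD"
  }
  # qualifying pair count at each bin distance d = 1 .. n-1
  pairsAt <- numeric(n - 1)
  for (d in seq_len(n - 1)) {
    a <- seq_len(n - d)
    b <- a + d
    pairsAt[d] <- switch(segmentClass,
      all = n - d,
      LAD = sum(lad[a] & lad[b]),
      nonLAD = sum(!lad[a] & !lad[b]),
      cross = sum(xor(lad[a], lad[b])))
  }
  cts <- contactCounts(cm)
  off <- cts$j > cts$i
  di <- cts$j[off] - cts$i[off]
  cnt <- cts$count[off]
  qual <- switch(segmentClass,
    all = rep(TRUE, length(di)),
    LAD = lad[cts$i[off]] & lad[cts$j[off]],
    nonLAD = !lad[cts$i[off]] & !lad[cts$j[off]],
    cross = xor(lad[cts$i[off]], lad[cts$j[off]]))
  sumAt <- numeric(n - 1)
  if (any(qual)) {
    agg <- rowsum(cnt[qual], di[qual])
    sumAt[as.integer(rownames(agg))] <- agg[, 1]
  }
  dBp <- seq_len(n - 1) * res
  if (identical(distanceBins, "integer")) {
    keep <- pairsAt > 0
    return(data.frame(distance = dBp[keep],
                      P = sumAt[keep] / pairsAt[keep],
                      pairs = pairsAt[keep], totalCount = sumAt[keep],
                      class = segmentClass))
  }
  # log-spaced distance bins over [res, n*res]
  lo <- log10(res); hi <- log10(n * res)
  edges <- 10^seq(lo, hi + 1e-9, by = 1 / distanceBins)
  bin <- findInterval(dBp, edges, rightmost.closed = TRUE)
  f <- factor(bin, levels = seq_len(length(edges) - 1))
  totPairs <- as.numeric(tapply(pairsAt, f, sum, default = 0))
  totPairs[is.na(totPairs)] <- 0
  totCount <- as.numeric(tapply(sumAt, f, sum, default = 0))
  totCount[is.na(totCount)] <- 0
  # pair-weighted geometric-mean separation per bin
  wlog <- as.numeric(tapply(pairsAt * log(dBp), f, sum, default = 0))
  wlog[is.na(wlog)] <- 0
  centre <- sqrt(edges[-length(edges)] * edges[-1])
  rep <- ifelse(totPairs > 0, exp(wlog / totPairs), centre)
  keep <- totPairs > 0 | totCount > 0
  data.frame(distance = rep[keep],
             P = ifelse(totPairs[keep] > 0,
                        totCount[keep] / totPairs[keep], NA_real_),
             pairs = totPairs[keep], totalCount = totCount[keep],
             class = segmentClass)
}

#' Fit the contact-probability power-law exponent |s|
#'
#' Ordinary least squares of log P on log N over distance bins inside
#' \code{[nMin, nMax]} (default 1e5 - 1e6 bp) with positive pair count and
#' positive P.  Returns the exponent magnitude \code{|s| = -slope}, the
#' intercept and R^2.  Invariant to rescaling the matrix by a positive
#' constant.
#'
#' @param curve data.frame from \code{\link{scalingCurve}}.
#' @param nMin,nMax fit window in bp.
#' @return list with \code{s} (|s|), \code{slope}, \code{intercept},
#'   \code{r2}, \code{nBins}, \code{window}
#' @export
fitExponent <- function(curve, nMin = 1e5, nMax = 1e6) {
  ok <- curve$distance >= nMin & curve$distance <= nMax &
    curve$pairs > 0 & !is.na(curve$P) & curve$P > 0
  if (sum(ok) < 3)
    stop("fewer than 3 populated distance bins in [", nMin, ", ", nMax, "]")
  fit <- lm(log(P) ~ log(distance), data = curve[ok, ])
  sl <- unname(coef(fit)[2])
  y <- log(curve$P[ok])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else 1
  list(s = abs(sl), slope = sl, intercept = unname(coef(fit)[1]),
       r2 = r2, nBins = sum(ok), window = c(nMin, nMax))
}

#' Per-chromosome LAD coverage fraction
#'
#' Merged LAD basepairs divided by chromosome length, for each chromosome in
#' \code{chromSizes}.
#'
#' @param lads \code{GRanges} of LAD intervals.
#' @param chromSizes named vector from \code{\link{readChromSizes}}.
#' @return named numeric vector of coverage fractions in [0, 1]
#' @export
ladCoverage <- function(lads, chromSizes) {
  extra <- setdiff(unique(as.character(seqnames(lads))), names(chromSizes))
  if (length(extra))
    stop("LADs on chromosomes absent from chrom sizes: ",
         paste(extra, collapse = ", "))
  merged <- reduce(lads)
  vapply(names(chromSizes), function(cc) {
    sum(width(merged[seqnames(merged) == cc])) / chromSizes[[cc]]
  }, 0)
}

#' Exponential fit of |s| against LAD coverage
#'
#' Least-squares fit of \eqn{y = a e^{-b x}}: initialized by
#' log-linearization (OLS of log y on x) and refined by nonlinear least
#' squares.  Used for the inverse relationship between within-LAD |s| and
#' the chromosome's lamin B1 coverage fraction.
#'
#' @param x coverage fractions.
#' @param y exponent magnitudes (> 0).
#' @return list with \code{a}, \code{b}, \code{residuals},
#'   \code{residualNorm}, \code{fitted}
#' @export
fitCoverageExponential <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 (coverage, exponent) points")
  if (any(y <= 0)) stop("exponents must be positive for the log-linear fit")
  lin <- lm(log(y) ~ x)
  a0 <- exp(unname(coef(lin)[1])); b0 <- -unname(coef(lin)[2])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x), start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    a <- a0; b <- b0; fv <- a * exp(-b * x)
  } else {
    cf <- coef(fit); a <- unname(cf["a"]); b <- unname(cf["b"])
    fv <- fitted(fit)
  }
  res <- y - fv
  list(a = a, b = b, residuals = res, residualNorm = sqrt(sum(res^2)),
       fitted = fv)
}

#' Interchromosomal contact change between two conditions
#'
#' For every chromosome pair present in both condition lists, the percent
#' change in mean trans contact frequency,
#' \eqn{100 (\bar c_{treated} - \bar c_{control}) / \bar c_{control}},
#' where the mean is over all entries of the block (zeros included).  With
#' \code{normalize = TRUE} each condition's counts are first divided by that
#' condition's grand total across all pairs (library-depth guard).  Pairs
#' with zero control mean are masked (\code{NA}).
#'
#' @param control,treated named lists of trans
#'   \linkS4class{ContactMatrix} objects; names identify chromosome pairs
#'   and must match across conditions.
#' @param normalize apply total-sum scaling per condition (default FALSE).
#' @return data.frame with \code{pair}, \code{meanControl},
#'   \code{meanTreated}, \code{pctChange}; the \code{pctChange} column is
#'   the histogram input
#' @export
transChange <- function(control, treated, normalize = FALSE) {
  if (!setequal(names(control), names(treated)))
    stop("conditions must cover the same chromosome pairs")
  pairs <- names(control)
  meanOf <- function(cm)
    totalContacts(cm) / (as.numeric(cm@nBinsA) * cm@nBinsB)
  mc <- vapply(control[pairs], meanOf, 0)
  mt <- vapply(treated[pairs], meanOf, 0)
  if (normalize) {
    mc <- mc / sum(vapply(control[pairs], totalContacts, 0))
    mt <- mt / sum(vapply(treated[pairs], totalContacts, 0))
  }
  pct <- ifelse(mc > 0, 100 * (mt - mc) / mc, NA_real_)
  data.frame(pair = pairs, meanControl = mc, meanTreated = mt,
             pctChange = pct, row.names = NULL)
}

#' First eigenvector of the contact correlation matrix (compartment track)
#'
#' Observed/expected transform (expected = per-distance mean over populated
#' entries), Pearson correlation matrix of the O/E columns, and the leading
#' eigenvector (largest eigenvalue magnitude), unit-normalized.  The sign is
#' oriented to correlate positively with \code{referenceTrack} when given
#' (e.g. gene density); otherwise the first nonzero entry is made positive
#' (deterministic).  Bins with no contacts are returned as \code{NA}.
#'
#' @param cm cis \linkS4class{ContactMatrix} with >= 10 populated bins.
#' @param referenceTrack optional numeric vector of length \code{nBins}.
#' @return list with \code{eigenvector} (length nBins, unit norm over
#'   non-NA entries), \code{eigenvalue}, \code{signConvention}
#' @export
compartmentEigenvector <- function(cm, referenceTrack = NULL) {
  if (!isCis(cm)) stop("compartment eigenvector needs a cis matrix")
  n <- cm@nBinsA
  M <- matrix(0, n, n)
  cts <- contactCounts(cm)
  M[cbind(cts$i, cts$j)] <- cts$count
  M[cbind(cts$j, cts$i)] <- cts$count
  populated <- rowSums(M) > 0
  if (sum(populated) < 10) stop("need at least 10 populated bins")
  idx <- which(populated)
  Ms <- M[idx, idx, drop = FALSE]
  ns <- length(idx)
  # expected value per |i - j| over populated entries only
  dmat <- abs(outer(idx, idx, "-"))
  oe <- Ms
  for (d in unique(as.vector(dmat))) {
    sel <- dmat == d
    vals <- Ms[sel]
    pop <- vals > 0
    e <- if (any(pop)) mean(vals[pop]) else 0
    oe[sel] <- if (e > 0) Ms[sel] / e else 0
  }
  if (all(abs(oe - mean(oe)) < 1e-12))
    stop("degenerate (constant) matrix: correlation undefined")
  cc <- suppressWarnings(cor(oe))
  if (anyNA(cc)) {
    keep <- apply(cc, 1, function(r) !anyNA(r))
    if (sum(keep) < 10) stop("too few non-degenerate bins")
    idx <- idx[keep]
    cc <- cc[keep, keep, drop = FALSE]
  }
  eg <- eigen(cc, symmetric = TRUE)
  lead <- which.max(abs(eg$values))
  v <- eg$vectors[, lead]
  v <- v / sqrt(sum(v^2))
  conv <- "first-nonzero-positive"
  if (!is.null(referenceTrack)) {
    r <- suppressWarnings(cor(v, referenceTrack[idx]))
    if (!is.na(r) && r < 0) v <- -v
    conv <- "reference-track"
  } else {
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) v <- -v
  }
  out <- rep(NA_real_, n)
  out[idx] <- v
  list(eigenvector = out, eigenvalue = eg$values[lead],
       signConvention = conv)
}

#' TAD size summary inside and outside LADs
#'
#' Classes each externally supplied domain as LAD if at least
#' \code{minOverlap} of its length overlaps the merged LAD intervals, then
#' reports counts and mean/median sizes per class.
#'
#' @param domains \code{GRanges} of domain calls.
#' @param lads \code{GRanges} of LAD intervals.
#' @param minOverlap minimum overlapping fraction of the domain length
#'   (default 0.5).
#' @return list with \code{perDomain} (data.frame: width, overlap fraction,
#'   class) and \code{summary} (data.frame per class: n, meanKb, medianKb)
#' @export
domainLadSummary <- function(domains, lads, minOverlap = 0.5) {
  lads <- reduce(lads)
  ovFrac <- numeric(length(domains))
  hits <- findOverlaps(domains, lads)
  if (length(hits)) {
    ov <- width(pintersect(domains[queryHits(hits)],
                           lads[subjectHits(hits)]))
    agg <- tapply(ov, factor(queryHits(hits),
                             levels = seq_along(domains)), sum, default = 0)
    ovFrac <- as.numeric(agg) / width(domains)
    ovFrac[is.na(ovFrac)] <- 0
  }
  cls <- factor(ifelse(ovFrac >= minOverlap, "LAD", "nonLAD"),
                levels = c("LAD", "nonLAD"))
  per <- data.frame(widthBp = width(domains), overlapFraction = ovFrac,
                    class = cls)
  summ <- do.call(rbind, lapply(levels(cls), function(cl) {
    w <- per$widthBp[per$class == cl]
    data.frame(class = cl, n = length(w),
               meanKb = if (length(w)) mean(w) / 1000 else NA_real_,
               medianKb = if (length(w)) median(w) / 1000 else NA_real_)
  }))
  list(perDomain = per, summary = summ)
}
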