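# Gene-level post-processing: DEG threshold filtering, gene-vs-LAD
# classification (coverage / closest / relative-distance semantics),
# class tallies, and the Gini coefficient of transcriptional divergence.

#' Filter differentially expressed genes
#'
#' Keeps records with adjusted P strictly below \code{padjMax} and absolute
#' log2 fold change strictly above \code{absLfcMin} (defaults 0.01 and 1,
#' both strict, so boundary records are dropped), and assigns an up/down
#' direction from the fold-change sign.
#'
#' @param degs \code{GRanges} from \code{\link{readDegTable}} (metadata
#'   columns \code{gene}, \code{log2FoldChange}, \code{padj}) or a
#'   data.frame with those columns.
#' @param padjMax adjusted-P cutoff (exclusive).
#' @param absLfcMin absolute log fold-change cutoff (exclusive).
#' @return input subset with an added \code{direction} column
#'   (factor up/down)
#' @export
filterDegs <- function(degs, padjMax = 0.01, absLfcMin = 1.0) {
  md <- if (is(degs, "GRanges")) mcols(degs) else degs
  need <- c("log2FoldChange", "padj")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- !is.na(md$padj) & md$padj < padjMax &
    abs(md$log2FoldChange) > absLfcMin
  gr <- is(degs, "GRanges")
  out <- if (gr) degs[keep] else degs[keep, , drop = FALSE]
  lfc <- (if (gr) mcols(out) else out)$log2FoldChange
  dir <- factor(ifelse(lfc > 0, "up", "down"), levels = c("up", "down"))
  if (gr) mcols(out)$direction <- dir else out$direction <- dir
  out
}

#' Classify genes as within or outside LADs
#'
#' A gene is within-LAD iff its interval overlaps the merged LADs by at
#' least \code{minOverlapBp} basepairs (default 1: any overlap, the
#' standard interval-tool convention; genes spanning a LAD boundary are
#' within).  The distance to the nearest LAD on the same chromosome is 0
#' for overlapping genes and the basepair gap otherwise; genes on
#' chromosomes with no LADs get \code{Inf} with the \code{noLadChrom} flag.
#'
#' @param genes \code{GRanges} with a \code{gene} metadata column.
#' @param lads \code{GRanges} of LAD intervals.
#' @param minOverlapBp minimum overlap in bp to call within-LAD.
#' @return data.frame with \code{gene}, \code{class} (within/outside),
#'   \code{overlapBp}, \code{distanceBp}, \code{noLadChrom}
#' @export
classifyGenesVsLads <- function(genes, lads, minOverlapBp = 1) {
  lads <- reduce(lads)
  n <- length(genes)
  ov <- numeric(n)
  hits <- findOverlaps(genes, lads)
  if (length(hits)) {
    w <- width(pintersect(genes[queryHits(hits)], lads[subjectHits(hits)]))
    agg <- tapply(w, factor(queryHits(hits), levels = seq_len(n)), sum,
                  default = 0)
    ov <- as.numeric(agg); ov[is.na(ov)] <- 0
  }
  dist <- rep(Inf, n)
  dn <- distanceToNearest(genes, lads)
  dist[queryHits(dn)] <- mcols(dn)$distance
  noLad <- !as.character(seqnames(genes)) %in%
    unique(as.character(seqnames(lads)))
  dist[noLad] <- Inf
  gene <- if ("gene" %in% names(mcols(genes))) mcols(genes)$gene else
    as.character(seq_len(n))
  data.frame(gene = gene,
             class = factor(ifelse(ov >= minOverlapBp, "within", "outside"),
                            levels = c("within", "outside")),
             overlapBp = ov, distanceBp = dist, noLadChrom = noLad)
}

#' Relative distance of genes to flanking LAD midpoints
#'
#' For each gene midpoint lying between two consecutive LAD midpoints on the
#' same chromosome, the statistic
#' \eqn{\min(d_{left}, d_{right}) / (d_{left} + d_{right}) \in [0, 0.5]}
#' (the interval-tool "reldist" convention): 0 when the gene midpoint sits
#' on a LAD midpoint, 0.5 exactly between two.  Features distributed
#' independently of the LADs give a flat histogram with mean 0.25.  Genes
#' outside the flanked span (or on chromosomes with < 2 LADs) are excluded
#' with a flag.
#'
#' @param genes,lads \code{GRanges}.
#' @param breaks histogram break count over [0, 0.5] (default 10).
#' @return list with \code{perGene} data.frame (\code{gene}, \code{reldist},
#'   \code{flagged}), \code{histogram} data.frame and \code{meanRelDist}
#' @export
relativeDistance <- function(genes, lads, breaks = 10) {
  lads <- reduce(lads)
  n <- length(genes)
  gmid <- (start(genes) + end(genes)) / 2
  gchr <- as.character(seqnames(genes))
  stat <- rep(NA_real_, n)
  for (cc in unique(gchr)) {
    lmid <- sort((start(lads) + end(lads))[as.character(seqnames(lads)) ==
                                             cc] / 2)
    sel <- which(gchr == cc)
    if (length(lmid) < 2L) next
    pos <- gmid[sel]
    k <- findInterval(pos, lmid)
    ok <- k >= 1L & k < length(lmid)
    dl <- pos[ok] - lmid[k[ok]]
    dr <- lmid[k[ok] + 1L] - pos[ok]
    stat[sel[ok]] <- pmin(dl, dr) / (dl + dr)
  }
  gene <- if ("gene" %in% names(mcols(genes))) mcols(genes)$gene else
    as.character(seq_len(n))
  per <- data.frame(gene = gene, reldist = stat, flagged = is.na(stat))
  h <- hist(stat[!is.na(stat)], breaks = seq(0, 0.5, length.out = breaks + 1),
            plot = FALSE, include.lowest = TRUE)
  list(perGene = per,
       histogram = data.frame(mid = h$mids, count = h$counts),
       meanRelDist = mean(stat, na.rm = TRUE))
}

#' Tally DEGs by LAD class
#'
#' Counts of differentially expressed genes by within/outside-LAD class and
#' direction (optionally also by chromosome), with percentages of the total.
#'
#' @param degs filtered \code{GRanges} from \code{\link{filterDegs}} (needs
#'   \code{gene} and \code{direction}).
#' @param classes data.frame from \code{\link{classifyGenesVsLads}}.
#' @param byChrom also stratify by chromosome (default FALSE).
#' @return data.frame of counts with a \code{percent} column
#' @export
tallyDegsByLad <- function(degs, classes, byChrom = FALSE) {
  md <- if (is(degs, "GRanges")) mcols(degs) else degs
  idx <- match(md$gene, classes$gene)
  if (anyNA(idx))
    stop("DEGs without a class record: ",
         paste(head(md$gene[is.na(idx)], 5), collapse = ", "))
  df <- data.frame(class = classes$class[idx], direction = md$direction)
  if (byChrom) df$chrom <- as.character(seqnames(degs))
  tab <- as.data.frame(table(df), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  tab$percent <- if (sum(tab$count) > 0)
    100 * tab$count / sum(tab$count) else 0
  tab
}

#' Gini coefficient of a non-negative vector
#'
#' Population variant
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}, computed through
#' the equivalent sorted-rank O(n log n) form
#' \eqn{G = \sum_i (2i - n - 1) x_{(i)} / (n^2 \bar x)}; the sample variant
#' multiplies by \eqn{n/(n-1)}.  0 for any constant positive vector,
#' invariant under positive scaling, and \eqn{(n-1)/n} when a single entry
#' holds all the mass.
#'
#' @param values non-negative numeric vector with at least one positive
#'   entry.
#' @param variant "population" (default) or "sample".
#' @return list with \code{gini}, \code{n}, \code{variant}
#' @export
gini <- function(values, variant = c("population", "sample")) {
  variant <- match.arg(variant)
  x <- values[!is.na(values)]
  if (any(x < 0)) stop("values must be non-negative")
  n <- length(x)
  if (n < 1L || sum(x) == 0) stop("need at least one positive value")
  xs <- sort(x)
  g <- sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * mean(xs))
  if (variant == "sample") g <- g * n / (n - 1)
  list(gini = g, n = n, variant = variant)
}
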