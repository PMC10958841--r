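# ---- BED ------------------------------------------------------------------

#' Read a BED3+ interval file
#'
#' Parses tab-separated BED records into a \code{GRanges}.  BED coordinates
#' are 0-based half-open on disk; the returned \code{GRanges} uses the usual
#' 1-based closed convention (\code{start = bed_start + 1}), so
#' \code{writeBed()} round-trips the file exactly.  \code{track},
#' \code{browser} and \code{#} comment lines are skipped; record order is
#' preserved.  Optional columns 4-6 become \code{name}, \code{score} and
#' strand (strand is parsed but ignored by every downstream operation).
#'
#' @param path file path.
#' @param oneBased set TRUE for tables that are already 1-based closed
#'   (e.g. gene tables exported from R); coordinates are then taken as-is.
#' @return \code{GRanges}
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100\tladA", f)
#' readBed(f)
#' @export
readBed <- function(path, oneBased = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("BED parse error at line ", lineNo[bad[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop("BED parse error at line ", lineNo[bad[1]],
         ": non-integer coordinates")
  if (!oneBased) s <- s + 1           # to 1-based closed
  bad <- which(e < s | s < 1 | !nzchar(chrom))
  if (length(bad))
    stop("BED parse error at line ", lineNo[bad[1]],
         ": end <= start (or empty chrom)")
  gr <- GRanges(chrom, IRanges(s, e))
  if (any(nf >= 4L))
    mcols(gr)$name <- vapply(fields, function(x)
      if (length(x) >= 4L) x[4L] else NA_character_, "")
  if (any(nf >= 5L))
    mcols(gr)$score <- suppressWarnings(vapply(fields, function(x)
      if (length(x) >= 5L) as.numeric(x[5L]) else NA_real_, 0))
  if (any(nf >= 6L)) {
    st <- vapply(fields, function(x)
      if (length(x) >= 6L) x[6L] else "*", "")
    st[!st %in% c("+", "-", "*")] <- "*"
    strand(gr) <- st
  }
  gr
}

#' Write a GRanges as BED
#'
#' Inverse of \code{\link{readBed}}: emits 0-based half-open coordinates.
#'
#' @param gr a \code{GRanges}.
#' @param path output file.
#' @return invisibly, the path
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  md <- mcols(gr)
  hasName <- "name" %in% names(md)
  hasScore <- "score" %in% names(md)
  hasStrand <- any(as.character(strand(gr)) != "*")
  if (hasName || hasScore || hasStrand)
    df$name <- if (hasName) md$name else "."
  if (hasScore || hasStrand)
    df$score <- if (hasScore) md$score else 0
  if (hasStrand)
    df$strand <- as.character(strand(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- chrom sizes ----------------------------------------------------------

#' Read a two-column chrom-sizes file
#'
#' @param path file with \code{chrom<TAB>length} records.
#' @return named numeric vector of chromosome lengths (bp)
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("chrom-sizes file needs two columns")
  setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}

# ---- contact matrices -----------------------------------------------------

#' Read a text contact matrix
#'
#' Two dialects are accepted.  (1) COO text with records
#' \code{chromA binA chromB binB count} (whitespace- or tab-separated;
#' \code{binA}/\code{binB} are 0-based bin indices), the dialect used for all
#' real inputs.  (2) A dense square numeric table, auto-detected by column
#' count, for toy inputs.  Cis entries are folded to the upper triangle.  In
#' the default \code{"upper"} dialect duplicate records are summed
#' (unmirrored input); in the \code{"mirrored"} dialect the two mirror halves
#' of each off-diagonal entry are collapsed to a single record (values must
#' agree).
#'
#' @param path file path.
#' @param resolution bin size in bp.
#' @param dialect \code{"upper"} (default) or \code{"mirrored"}.
#' @param chromSizes optional named vector from \code{\link{readChromSizes}};
#'   when given, bin indices are validated against the chromosome extent.
#' @return a \linkS4class{ContactMatrix}
#' @export
readContactMatrix <- function(path, resolution,
                              dialect = c("upper", "mirrored"),
                              chromSizes = NULL) {
  dialect <- match.arg(dialect)
  first <- readLines(path, n = 1L)
  nf <- length(strsplit(trimws(first), "[\t ,]+")[[1]])
  if (nf == 5L) {
    df <- read.table(path, header = FALSE,
                     col.names = c("chromA", "binA", "chromB", "binB",
                                   "count"),
                     colClasses = c("character", "numeric", "character",
                                    "numeric", "numeric"))
  } else {
    dense <- as.matrix(read.table(path, header = FALSE))
    if (nrow(dense) != ncol(dense))
      stop("dense contact table must be square (got ",
           nrow(dense), "x", ncol(dense), ")")
    idx <- which(dense != 0, arr.ind = TRUE)
    df <- data.frame(chromA = "chr", binA = idx[, 1] - 1, chromB = "chr",
                     binB = idx[, 2] - 1, count = dense[idx])
  }
  if (any(df$count < 0)) stop("negative contact count in ", path)
  if (length(unique(df$chromA)) > 1L || length(unique(df$chromB)) > 1L)
    stop("readContactMatrix reads one chromosome pair per file")
  chromA <- df$chromA[1]; chromB <- df$chromB[1]
  cis <- chromA == chromB
  i <- df$binA + 1L; j <- df$binB + 1L
  if (cis) { ii <- pmin(i, j); j <- pmax(i, j); i <- ii }
  cnt <- df$count
  if (cis && dialect == "mirrored") {
    # both halves present once each: collapse, checking agreement
    key <- paste(i, j)
    dup <- duplicated(key)
    if (any(dup)) {
      firstVal <- cnt[match(key[dup], key)]
      if (any(abs(firstVal - cnt[dup]) > 1e-9 * pmax(1, abs(firstVal))))
        stop("mirrored dialect: mirror halves disagree")
      i <- i[!dup]; j <- j[!dup]; cnt <- cnt[!dup]
    }
  }
  nA <- max(i); nB <- max(j)
  if (!is.null(chromSizes)) {
    for (cc in unique(c(chromA, chromB)))
      if (!cc %in% names(chromSizes))
        stop("chromosome ", cc, " absent from chrom sizes")
    nA <- as.integer(ceiling(chromSizes[[chromA]] / resolution))
    nB <- as.integer(ceiling(chromSizes[[chromB]] / resolution))
    if (max(i) > nA || max(j) > nB)
      stop("bin index exceeds chromosome extent")
    if (cis) nB <- nA <- max(nA, nB)
  }
  ContactMatrix(data.frame(i = i, j = j, count = cnt), resolution,
                nBinsA = nA, nBinsB = nB, chromA = chromA, chromB = chromB)
}

#' Write a ContactMatrix as COO text
#'
#' Emits \code{chromA binA chromB binB count} records with 0-based bins
#' (upper-triangular for cis matrices), readable by
#' \code{\link{readContactMatrix}}.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param path output file.
#' @return invisibly, the path
#' @export
writeContactMatrix <- function(cm, path) {
  cts <- contactCounts(cm)
  df <- data.frame(cm@chromA, cts$i - 1L, cm@chromB, cts$j - 1L, cts$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- localization tables --------------------------------------------------

#' Read a single-molecule localization table
#'
#' Reads a delimited table with headered x/y coordinate columns in nm.
#' Accepted header spellings per axis: \code{"x [nm]"}, \code{"x_nm"},
#' \code{"x(nm)"} or plain \code{"x"} (case-insensitive; likewise for y).
#' Optional \code{frame} and \code{intensity} columns are carried through.
#'
#' @param path CSV (or tab-delimited) file.
#' @return data.frame with columns \code{x}, \code{y} (nm) and any optional
#'   columns present
#' @export
readLocalizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) == 1L)
    df <- utils::read.delim(path, check.names = FALSE)
  norm <- tolower(gsub("[][()\\s_]+", "", names(df), perl = TRUE))
  findCol <- function(ax) which(norm %in% c(ax, paste0(ax, "nm")))[1]
  xi <- findCol("x"); yi <- findCol("y")
  if (is.na(xi) || is.na(yi))
    stop("localization table needs x and y columns in nm; accepted headers: ",
         "'x [nm]', 'x_nm', 'x(nm)', 'x' (and the y equivalents); found: ",
         paste(names(df), collapse = ", "))
  out <- data.frame(x = as.numeric(df[[xi]]), y = as.numeric(df[[yi]]))
  if (nrow(out) && (anyNA(out$x) || anyNA(out$y) ||
      any(out$x < 0) || any(out$y < 0) || any(!is.finite(c(out$x, out$y)))))
    stop("localization coordinates must be finite and non-negative")
  fi <- which(norm == "frame")[1]; ii <- which(norm == "intensity")[1]
  if (!is.na(fi)) out$frame <- df[[fi]]
  if (!is.na(ii)) out$intensity <- as.numeric(df[[ii]])
  out
}

# ---- DEG tables -----------------------------------------------------------

#' Read a differential-expression table with gene coordinates
#'
#' Expects a CSV with columns \code{gene}, \code{chrom}, \code{start},
#' \code{end}, \code{log2FoldChange} and \code{padj} (extra columns kept as
#' metadata).  Gene coordinates are 1-based closed unless
#' \code{oneBased = FALSE}.
#'
#' @param path CSV file.
#' @param oneBased whether start/end are 1-based closed (default TRUE).
#' @return \code{GRanges} with metadata columns \code{gene},
#'   \code{log2FoldChange}, \code{padj}
#' @export
readDegTable <- function(path, oneBased = TRUE) {
  df <- utils::read.csv(path)
  need <- c("gene", "chrom", "start", "end", "log2FoldChange", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DEG table missing columns: ", paste(miss, collapse = ", "))
  s <- df$start + if (oneBased) 0L else 1L
  gr <- GRanges(df$chrom, IRanges(s, df$end))
  mcols(gr) <- df[setdiff(names(df), c("chrom", "start", "end"))]
  gr
}
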