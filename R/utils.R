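# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards, so generator calls are reproducible and do
# not perturb surrounding streams.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Derive a per-generator substream seed from a scene seed
#'
#' Counter-based expansion of one global seed into independent substream
#' seeds, so adding a generator call to a scene does not perturb the streams
#' of earlier calls.  The mixing uses a Weyl-style multiplicative hash and
#' stays below 2^31.
#'
#' @param seed integer scene seed.
#' @param index non-negative integer stream counter.
#' @return integer(1) substream seed in [0, 2^31)
#' @export
substream <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L, index >= 0)
  # 64-bit-safe mixing in doubles: exact below 2^53
  x <- (as.numeric(seed) %% 2^31) + as.numeric(index) * 2654435761
  x <- (x * 2246822519) %% 2^31
  as.integer(x)
}

# population standard deviation / variance (denominator n)
popVar <- function(x) mean((x - mean(x))^2)
popSd <- function(x) sqrt(popVar(x))

# distance-to-background map (px units, EBImage convention: boundary
# foreground pixels have value 1)
.distmap <- function(mask) {
  dm <- EBImage::distmap(mask * 1L)
  matrix(as.numeric(dm), nrow(mask), ncol(mask))
}

# pixel-centre coordinate grids (px units, centre of pixel (r, c) at (r, c))
.pixelGrid <- function(nr, nc) {
  list(row = matrix(seq_len(nr), nr, nc),
       col = matrix(rep(seq_len(nc), each = nr), nr, nc))
}

.assertSameFrame <- function(image, mask) {
  if (!all(dim(image)[1:2] == dim(maskRaster(mask))))
    stop("image and nucleus mask frames differ: ",
         paste(dim(image)[1:2], collapse = "x"), " vs ",
         paste(dim(maskRaster(mask)), collapse = "x"))
  invisible(TRUE)
}
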