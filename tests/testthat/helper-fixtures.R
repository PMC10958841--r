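# Shared fixtures: all built in code, no files on disk.

# disk nucleus centred on a pixel centre so the continuum radius maps cleanly
# onto the raster
makeDisk <- function(radiusPx, pixelSize = 100, pad = 6L) {
  n <- 2L * (as.integer(ceiling(radiusPx)) + pad)
  laminscape::simNucleusMask(n, n, pixelSize,
                             c(radiusPx, radiusPx) * pixelSize,
                             center = c(n / 2 + 0.5, n / 2 + 0.5))
}

# true continuum radius of each pixel centre of a disk fixture
diskRadii <- function(mask) {
  m <- maskRaster(mask)
  n <- nrow(m)
  ctr <- n / 2 + 0.5
  row <- matrix(seq_len(n), n, n)
  col <- matrix(rep(seq_len(n), each = n), n, n)
  sqrt((col - 0.5 - ctr)^2 + (row - 0.5 - ctr)^2)
}

expect_partition <- function(part, mask) {
  lab <- regionLabels(part)
  m <- maskRaster(mask)
  expect_true(all((lab > 0L) == m))
  expect_identical(sum(regionAreas(part)), sum(m))
}
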