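test_that("elliptical masks match continuum area and rotation symmetry", {
  # circle r = 6.5 um at 130 nm/px in a 128x128 frame: ~ pi * 50^2 px
  m <- simNucleusMask(128, 128, 130, c(6500, 6500))
  expect_lt(abs(maskArea(m) / (pi * 50^2) - 1), 0.02)

  # ellipse area
  e <- simNucleusMask(160, 160, 100, c(6000, 3000))
  expect_lt(abs(maskArea(e) / (pi * 60 * 30) - 1), 0.02)

  # a circle is rotation invariant
  a <- simNucleusMask(64, 64, 100, c(2000, 2000), rotationDeg = 0)
  b <- simNucleusMask(64, 64, 100, c(2000, 2000), rotationDeg = 37)
  expect_identical(maskRaster(a), maskRaster(b))

  expect_error(simNucleusMask(64, 64, 100, c(4000, 2000)), "fit")
})

test_that("radial images honour the profile and conserve intensity", {
  m <- makeDisk(40)
  img <- simRadialImage(m, function(r) rep(1, length(r)), 1e6)
  vals <- img[maskRaster(m)]
  expect_true(all(abs(vals - vals[1]) < 1e-9))
  expect_equal(sum(img), 1e6)

  # signal confined to the outermost shell
  out <- simRadialImage(m, function(r) as.numeric(r > 0.9), 1e4)
  rho <- normalizedRadialCoordinate(m)
  expect_true(all(out[maskRaster(m) & rho <= 0.9] == 0))

  expect_error(simRadialImage(m, function(r) r - 0.5, 1), "non-negative")

  # Poisson mode: per-ring means vs pixel-summation oracle within 3 sigma
  rings <- makeRings(m)
  expected <- simRadialImage(m, function(r) r^2, 5e5)
  noisy <- simRadialImage(m, function(r) r^2, 5e5, "poisson", seed = 42)
  for (k in c(3, 6, 10)) {
    sel <- regionMask(rings, k)
    mu <- sum(expected[sel])
    expect_lt(abs(sum(noisy[sel]) - mu), 3 * sqrt(mu) + 1e-9)
  }
})

test_that("foci sampling follows the radial density", {
  m <- makeDisk(50)
  expect_error(simFoci(m, 0), "positive")

  # point mass at the centre -> deepest pixels only
  ctr <- simFoci(m, 20, function(r) as.numeric(r < 0.002), seed = 1)
  expect_true(all(ctr$rho < 0.05))

  # mass at the boundary -> outermost ring
  rings <- makeRings(m)
  edge <- simFoci(m, 50, function(r) as.numeric(r > 0.998), seed = 2)
  expect_true(all(edge$rho >= 0.9))

  # uniform over area: mean normalized distance 2/3 within 2%
  f <- simFoci(m, 1e4, seed = 3)
  fd <- fociDistances(f, centroidRadius(m))
  expect_lt(abs(fd$meanDOverR - 2 / 3), 0.02 * 2 / 3)
})

test_that("localization generator plants the periphery fraction", {
  m <- makeDisk(60, pixelSize = 26)
  pin <- makePeripheryInterior(m)
  per <- regionMask(pin, 1)

  expect_identical(nrow(simLocalizations(m, 1, 0.5, per, seed = 1)), 1L)
  allIn <- simLocalizations(m, 500, 1, per, seed = 2)
  expect_true(all(allIn$periphery))
  expect_error(simLocalizations(m, 10, 0.5,
                                matrix(FALSE, 132, 132)), "empty periphery")

  half <- simLocalizations(m, 1e5, 0.5, per, seed = 3)
  expect_lt(abs(mean(half$periphery) - 0.5), 0.01)
})

test_that("cis contact maps realize the per-class power laws", {
  # flat exponents: equal expected counts everywhere off-diagonal
  flat <- simCisContactMap(30, 1e4, rep(TRUE, 30), list(lad = 0),
                           mode = "expected", scale = 7)
  expect_true(all(abs(contactCounts(flat$matrix)$count - 7) < 1e-9))

  # noiseless s = 1: counts exactly proportional to 1/d
  nl <- simCisContactMap(50, 1e4, rep(FALSE, 50), list(nonlad = 1),
                         mode = "expected", scale = 1000)
  cc <- contactCounts(nl$matrix)
  d <- (cc$j - cc$i) * 1e4
  expect_equal(cc$count, 1000 / d, tolerance = 1e-12)

  # Poisson mode: segment-stratified means match analytic moments (3 sigma)
  lad <- rep(c(TRUE, FALSE), each = 60)
  sim <- simCisContactMap(120, 1e4, lad, list(lad = 0.9, nonlad = 1.2,
                                              cross = 1.05),
                          scale = 2000, totalContacts = NULL, seed = 5)
  cc <- contactCounts(sim$matrix)
  dense <- matrix(0, 120, 120)
  dense[cbind(cc$i, cc$j)] <- cc$count
  for (d in c(3, 11, 40)) {
    i <- seq_len(120 - d); j <- i + d
    for (cls in c("lad", "nonlad", "cross")) {
      sel <- switch(cls, lad = lad[i] & lad[j],
                    nonlad = !lad[i] & !lad[j], cross = xor(lad[i], lad[j]))
      if (!any(sel)) next
      s <- c(lad = 0.9, nonlad = 1.2, cross = 1.05)[[cls]]
      lambda <- 2000 * (d * 1e4)^(-s)
      tot <- sum(dense[cbind(i[sel], j[sel])])
      expect_lt(abs(tot - sum(sel) * lambda),
                3 * sqrt(sum(sel) * lambda) + 1e-9)
    }
  }

  expect_error(simCisContactMap(20, 1e4, rep(TRUE, 20), list(nonlad = 1)),
               "exponents missing")
})

test_that("trans contact pairs realize the fold change", {
  expect_error(simTransContacts(10, 10, 0, 2), "baseline")
  tc <- simTransContacts(60, 60, 8, 1, seed = 1)
  res <- transChange(list(p = tc$control), list(p = tc$treated))
  expect_lt(abs(res$pctChange), 3)   # fold 1 -> ~0% (sampling error)
})

test_that("temporal cubes are stationary AR(1) with the stated moments", {
  m <- makeDisk(3)
  expect_error(simTemporalCube(m, 100, -1, 0.1, 1), "dtS")
  expect_error(simTemporalCube(m, 5, 0.1, 0.1, 1), "10 frames")

  still <- simTemporalCube(m, 20, 0.1, 0, 1)
  expect_true(all(still@data == 1))

  cube <- simTemporalCube(m, 1e4, 0.1, variance = 0.04, tauS = 1, seed = 9)
  x <- cube@data[which(maskRaster(m))[1] +
                 (seq_len(1e4) - 1) * prod(dim(maskRaster(m)))]
  expect_lt(abs(mean((x - mean(x))^2) - 0.04), 0.05 * 0.04 * 2.5)
  # lag-1 autocorrelation ~ exp(-0.1) within 3 sigma (~3/sqrt(n))
  r1 <- cor(x[-1], x[-1e4])
  expect_lt(abs(r1 - exp(-0.1)), 3 / sqrt(1e4))
})

test_that("spectral cubes hit the target spectral deviation", {
  m <- makeDisk(8)
  expect_error(simSpectralCube(m, 0.05, wavelengths = c(500, 502)),
               "shorter than 3")
  flat <- simSpectralCube(m, 0, mode = "sinusoid")
  expect_true(all(flat@data == 1))

  sig <- computeSigma(simSpectralCube(m, 0.05, mode = "sinusoid"))
  expect_true(all(abs(sig[maskRaster(m)] - 0.05) < 1e-12))

  rnd <- computeSigma(simSpectralCube(m, 0.05, seed = 11))
  rel <- abs(rnd[maskRaster(m)] / 0.05 - 1)
  # chi-distributed sample sd over 101 wavelengths: sd ~ 7% of target
  expect_lt(median(rel), 0.06)
  expect_gt(mean(rel < 0.15), 0.9)
})

test_that("expression generator matches the lognormal Gini closed form", {
  ones <- simExpression(100, 0, seed = 1)
  expect_true(all(ones$expression == 1))
  expect_error(gini(rep(0, 5)), "positive")

  e <- simExpression(1e5, 1, seed = 6)
  g <- gini(e$expression)$gini
  expect_lt(abs(g - lognormalGini(1)), 0.01 * lognormalGini(1))
  # scale invariance of the downstream statistic
  expect_equal(gini(10 * e$expression)$gini, g, tolerance = 1e-12)
})

test_that("gene/LAD layouts plant the within fraction exactly", {
  gl0 <- simGenesAndLads(5e7, 8, 1e6, 200, 0, seed = 1)
  gl1 <- simGenesAndLads(5e7, 8, 1e6, 200, 1, seed = 1)
  ov0 <- GenomicRanges::countOverlaps(gl0$genes, gl0$lads)
  ov1 <- GenomicRanges::countOverlaps(gl1$genes, gl1$lads)
  expect_true(all(ov0 == 0))
  expect_true(all(ov1 > 0))
  expect_error(simGenesAndLads(1e5, 10, 9e3, 50, 0.5), "too small")
})

test_that("generators are deterministic and do not disturb the caller RNG", {
  m <- makeDisk(20)
  a <- simFoci(m, 100, seed = 7)
  b <- simFoci(m, 100, seed = 7)
  expect_identical(a, b)

  c1 <- simCisContactMap(40, 1e4, rep(TRUE, 40), list(lad = 1),
                         totalContacts = 1e4, seed = 3)
  c2 <- simCisContactMap(40, 1e4, rep(TRUE, 40), list(lad = 1),
                         totalContacts = 1e4, seed = 3)
  expect_identical(contactCounts(c1$matrix), contactCounts(c2$matrix))

  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simFoci(m, 10, seed = 99)); x2 <- runif(1)
  expect_identical(x1, x2)

  # substream expansion stays in 32-bit range and separates indices
  s <- vapply(0:10, function(k) substream(1L, k), 0L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(anyDuplicated(s) > 0)
})
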