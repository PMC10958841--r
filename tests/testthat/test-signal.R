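test_that("ring occupancy normalizes uniform signal flat and sums to 1", {
  m <- makeDisk(60)
  rings <- makeRings(m)
  img <- simRadialImage(m, function(r) rep(1, length(r)), 1e6)
  ro <- ringOccupancy(img, rings)
  expect_equal(sum(ro$fraction), 1, tolerance = 1e-9)
  # uniform signal: 2k-1 normalized occupancy flat within 5%
  expect_lt(max(abs(ro$normalizedRenorm / mean(ro$normalizedRenorm) - 1)),
            0.05)

  # everything in ring 10
  edge <- matrix(0, nrow(img), ncol(img))
  edge[regionMask(rings, 10)] <- 3
  roE <- ringOccupancy(edge, rings)
  expect_equal(roE$fraction, c(rep(0, 9), 1))

  # gradient image: fractions equal the direct pixel-summation oracle
  grad <- simRadialImage(m, function(r) 1 + 3 * r, 1e6)
  roG <- ringOccupancy(grad, rings)
  oracle <- vapply(1:10, function(k) sum(grad[regionMask(rings, k)]), 0) /
    sum(grad[maskRaster(m)])
  expect_equal(roG$fraction, oracle, tolerance = 1e-12)

  expect_error(ringOccupancy(0 * img, rings), "zero total")
})

test_that("peripheral profile concentrates in the outermost ring", {
  m <- makeDisk(60)
  rings <- makeRings(m)
  img <- simRadialImage(m, function(r) as.numeric(r > 0.9), 1e5,
                        "poisson", seed = 21)
  ro <- ringOccupancy(img, rings)
  expect_gt(ro$fraction[10], 0.95)
})

test_that("ring occupancy summaries aggregate across nuclei", {
  m <- makeDisk(40)
  rings <- makeRings(m)
  prof <- lapply(1:4, function(s)
    ringOccupancy(simRadialImage(m, function(r) 1 + r, 1e5, "poisson",
                                 seed = s), rings))
  summ <- ringOccupancySummary(prof[1:2], prof[3:4])
  expect_identical(nrow(summ), 10L)
  expect_true(all(c("mean", "sem", "diff") %in% names(summ)))
  expect_equal(summ$diff, summ$meanB - summ$mean)
})

test_that("NSI follows its defining formula and partition identity", {
  # uniform image: NSI 1 for any region
  m <- makeDisk(30)
  img <- matrix(1, nrow(maskRaster(m)), ncol(maskRaster(m)))
  rings <- makeRings(m)
  expect_equal(computeNsi(img, regionMask(rings, 4), m)$nsi, 1)

  # half-area region holding all signal: NSI exactly 2
  sq <- matrix(FALSE, 12, 12); sq[2:11, 2:11] <- TRUE
  nuc <- NucleusMask(sq, 100)
  half <- matrix(FALSE, 12, 12); half[2:11, 2:6] <- TRUE
  sig <- matrix(0, 12, 12); sig[half] <- 5
  expect_equal(computeNsi(sig, half, nuc)$nsi, 2)

  # random image against an independent formula evaluation
  set.seed(77)
  rimg <- matrix(runif(prod(dim(maskRaster(m)))), nrow(maskRaster(m)))
  reg <- regionMask(rings, 7)
  got <- computeNsi(rimg, reg, m)
  oracle <- (sum(rimg[reg]) / sum(reg)) /
    (sum(rimg[maskRaster(m)]) / maskArea(m))
  expect_equal(got$nsi, oracle, tolerance = 1e-12)

  # area-weighted NSI over any partition sums to exactly 1
  tot <- sum(vapply(1:10, function(k) {
    r <- computeNsi(rimg, regionMask(rings, k), m)
    r$aMask / r$aNuc * r$nsi
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-12)

  # scale invariance
  expect_equal(computeNsi(3.7 * rimg, reg, m)$nsi, got$nsi,
               tolerance = 1e-12)
  expect_error(computeNsi(rimg, matrix(FALSE, nrow(rimg), ncol(rimg)), m),
               "empty region")
})

test_that("coefficient of variation is sigma over mu, scale invariant", {
  m <- NucleusMask(matrix(TRUE, 10, 10), 100)
  expect_equal(computeCov(matrix(5, 10, 10), m)$cov, 0)
  half <- matrix(rep(c(0, 2), 50), 10, 10)
  r <- computeCov(half, m)
  expect_equal(r$mu, 1); expect_equal(r$sigma, 1); expect_equal(r$cov, 1)
  expect_equal(computeCov(half * 13, m)$cov, 1, tolerance = 1e-12)
  # sample variant uses n-1
  expect_equal(computeCov(half, m, "sample")$sigma, sd(half))
  expect_error(computeCov(matrix(0, 10, 10), m), "undefined")
})

test_that("reconstruction bins events exactly and conserves counts", {
  one <- reconstructImage(data.frame(x = 40, y = 66), binNm = 26,
                          frame = c(4, 4))
  expect_equal(sum(one), 1)
  expect_equal(one[3, 2], 1)   # row = floor(66/26)+1 = 3, col = 2

  set.seed(5)
  locs <- data.frame(x = runif(1000, 0, 26 * 12), y = runif(1000, 0, 26 * 12))
  img <- reconstructImage(locs, binNm = 26, frame = c(12, 12))
  # independent brute-force binning oracle
  oracle <- matrix(0, 12, 12)
  for (t in seq_len(1000)) {
    r <- min(floor(locs$y[t] / 26) + 1, 12)
    c <- min(floor(locs$x[t] / 26) + 1, 12)
    oracle[r, c] <- oracle[r, c] + 1
  }
  expect_identical(img, oracle)
  expect_equal(sum(img), 1000)

  ash <- reconstructImage(locs, binNm = 26, frame = c(12, 12), mode = "ash")
  expect_equal(sum(ash), 1000, tolerance = 1e-9)
  expect_error(reconstructImage(locs, binNm = 0), "positive")
})

test_that("focus-to-centroid distances normalize by equivalent radius", {
  m <- makeDisk(50, pixelSize = 100)
  cr <- centroidRadius(m)
  at0 <- fociDistances(data.frame(x = cr$centroidNm["x"],
                                  y = cr$centroidNm["y"]), cr)
  expect_equal(at0$perFocus$dOverR, 0)

  onB <- fociDistances(data.frame(x = cr$centroidNm["x"] + cr$radiusNm,
                                  y = cr$centroidNm["y"]), cr)
  expect_lt(abs(onB$perFocus$dOverR - 1), 0.02)

  # 2:1 ellipse, focus at the semi-major tip: d / sqrt(ab) = sqrt(2)
  e <- simNucleusMask(180, 180, 100, c(6000, 3000), center = c(90.5, 90.5))
  cre <- centroidRadius(e)
  tip <- fociDistances(data.frame(x = cre$centroidNm["x"] + 6000,
                                  y = cre$centroidNm["y"]), cre)
  expect_lt(abs(tip$perFocus$dOverR - sqrt(2)), 0.03)
  # area-normalized variant: d / sqrt(area) = d / (r sqrt(pi))
  expect_equal(tip$perFocus$dOverSqrtArea,
               tip$perFocus$dOverR / sqrt(pi), tolerance = 1e-12)

  expect_identical(fociDistances(data.frame(x = numeric(), y = numeric()),
                                 cr)$n, 0L)
})

test_that("pairwise foci matching is greedy with an optimal cross-check", {
  m <- makeDisk(50, pixelSize = 100)
  cr <- centroidRadius(m)
  A <- data.frame(x = c(1000, 2000, 3000), y = c(1000, 500, 4000))
  same <- pairwiseFociDistances(A, A, cr)
  expect_true(all(same$pairs$dNm == 0))

  two <- pairwiseFociDistances(data.frame(x = 0, y = 0),
                               data.frame(x = cr$radiusNm, y = 0), cr)
  expect_equal(two$pairs$dOverR, 1)

  empty <- pairwiseFociDistances(A[0, ], A, cr)
  expect_true(empty$empty)

  # exhaustive assignment equals an independent permutation oracle;
  # greedy total cost is bounded below by it
  set.seed(42)
  for (rep in 1:5) {
    fa <- data.frame(x = runif(5, 0, 5000), y = runif(5, 0, 5000))
    fb <- data.frame(x = runif(6, 0, 5000), y = runif(6, 0, 5000))
    D <- outer(seq_len(5), seq_len(6), function(i, j)
      sqrt((fa$x[i] - fb$x[j])^2 + (fa$y[i] - fb$y[j])^2))
    perms <- laminscape:::.permutations(6)
    costs <- apply(perms, 1, function(p) sum(D[cbind(1:5, p[1:5])]))
    best <- min(costs)
    opt <- pairwiseFociDistances(fa, fb, cr, method = "optimal")
    grd <- pairwiseFociDistances(fa, fb, cr, method = "greedy")
    expect_equal(sum(opt$pairs$dNm), best, tolerance = 1e-9)
    expect_gte(sum(grd$pairs$dNm), best - 1e-9)
  }
})
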