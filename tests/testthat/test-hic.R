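library(GenomicRanges)

test_that("bin labelling matches a brute-force basepair-overlap oracle", {
  lads <- GRanges("chr1", IRanges(c(1, 25001), c(10000, 30000)))
  lb <- labelBins(lads, "chr1", 10, 1e4)
  expect_identical(as.character(lb),
                   c("LAD", rep("nonLAD", 1), "LAD", rep("nonLAD", 7)))

  # exactly half a bin at threshold 0.5 is a LAD bin (>= rule)
  half <- GRanges("chr1", IRanges(5001, 10000))
  expect_identical(as.character(labelBins(half, "chr1", 2, 1e4))[1], "LAD")

  # random layouts vs enumeration
  set.seed(11)
  for (rep in 1:5) {
    n <- 40; res <- 5e3
    st <- sort(sample.int(n * res - 2e4, 6))
    lads <- reduce(GRanges("chrZ", IRanges(st, st + sample(2e3:1.5e4, 6))))
    got <- labelBins(lads, "chrZ", n, res)
    oracle <- vapply(seq_len(n), function(b) {
      lo <- (b - 1) * res + 1; hi <- b * res
      ov <- sum(pmax(0, pmin(end(lads), hi) - pmax(start(lads), lo) + 1))
      ov >= 0.5 * res
    }, TRUE)
    expect_identical(got == "LAD", oracle)
  }

  beyond <- GRanges("chr1", IRanges(1, 2e5))
  expect_error(labelBins(beyond, "chr1", 10, 1e4), "beyond")
})

test_that("scaling curves equal stratified brute-force averaging", {
  # all-LAD labels: LAD curve identical to the all curve
  sim <- simCisContactMap(80, 1e4, rep(TRUE, 80), list(lad = 1),
                          totalContacts = 2e5, seed = 4)
  cl <- scalingCurve(sim$matrix, sim$labels, "LAD")
  ca <- scalingCurve(sim$matrix, sim$labels, "all")
  expect_equal(cl[c("distance", "P", "pairs")], ca[c("distance", "P",
                                                     "pairs")])

  # noiseless s = 1: P exactly proportional to 1/N at every populated bin
  nl <- simCisContactMap(120, 1e4, rep(FALSE, 120), list(nonlad = 1),
                         mode = "expected", scale = 500)
  cv <- scalingCurve(nl$matrix, nl$labels, "nonLAD",
                     distanceBins = "integer")
  expect_equal(cv$P * cv$distance, rep(500, nrow(cv)), tolerance = 1e-9)

  # mixed layout Poisson map: per-class P matches direct enumeration
  lad <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 40, 20, 30))
  sim2 <- simCisContactMap(120, 1e4, lad,
                           list(lad = 0.9, nonlad = 1.2, cross = 1.0),
                           totalContacts = 3e5, seed = 9)
  cc <- contactCounts(sim2$matrix)
  dense <- matrix(0, 120, 120)
  dense[cbind(cc$i, cc$j)] <- cc$count
  for (cls in c("LAD", "nonLAD", "cross")) {
    got <- scalingCurve(sim2$matrix, sim2$labels, cls,
                        distanceBins = "integer")
    for (d in c(2, 7, 30)) {
      i <- seq_len(120 - d); j <- i + d
      sel <- switch(cls, LAD = lad[i] & lad[j],
                    nonLAD = !lad[i] & !lad[j], cross = xor(lad[i], lad[j]))
      if (!any(sel)) next
      oracle <- sum(dense[cbind(i[sel], j[sel])]) / sum(sel)
      expect_equal(got$P[got$distance == d * 1e4], oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("class curves combine into the all curve (partition identity)", {
  set.seed(30)
  for (rep in 1:5) {
    lad <- runif(100) < runif(1, 0.2, 0.8)
    sim <- simCisContactMap(100, 1e4, lad,
                            list(lad = 0.8, nonlad = 1.2, cross = 1.0),
                            totalContacts = 2e5, seed = rep)
    curves <- lapply(c("LAD", "nonLAD", "cross"), function(cl)
      scalingCurve(sim$matrix, sim$labels, cl, distanceBins = "integer"))
    all <- scalingCurve(sim$matrix, sim$labels, "all",
                        distanceBins = "integer")
    for (d in all$distance) {
      pairsSum <- 0; countSum <- 0
      for (cv in curves) {
        row <- cv[cv$distance == d, ]
        if (nrow(row)) {
          pairsSum <- pairsSum + row$pairs
          countSum <- countSum + row$totalCount
        }
      }
      expect_equal(pairsSum, all$pairs[all$distance == d])
      expect_equal(countSum / pairsSum, all$P[all$distance == d],
                   tolerance = 1e-12)
    }
  }
})

test_that("exponent fitting is exact on power laws and scale invariant", {
  nl <- simCisContactMap(150, 1e4, rep(FALSE, 150), list(nonlad = 1),
                         mode = "expected", scale = 1e4)
  cv <- scalingCurve(nl$matrix, nl$labels, "nonLAD",
                     distanceBins = "integer")
  fit <- fitExponent(cv)
  expect_equal(fit$s, 1, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)

  flat <- cv; flat$P <- 3.3
  expect_equal(fitExponent(flat)$s, 0, tolerance = 1e-9)

  # rescaling the matrix leaves the exponent unchanged
  sc <- cv; sc$P <- cv$P * 17
  expect_equal(fitExponent(sc)$s, fit$s, tolerance = 1e-12)

  expect_error(fitExponent(cv[cv$distance < 3e4, ]), "fewer than 3")
})

test_that("LAD coverage merges intervals before summing", {
  cs <- c(chr1 = 1e6, chr2 = 2e6)
  expect_equal(unname(ladCoverage(GRanges(), cs)), c(0, 0))
  tiling <- GRanges("chr1", IRanges(1, 1e6))
  expect_equal(ladCoverage(tiling, cs)[["chr1"]], 1)

  overlapping <- GRanges("chr1", IRanges(c(1, 5e4), c(1e5, 2e5)))
  cov <- ladCoverage(overlapping, cs)[["chr1"]]
  naive <- sum(width(overlapping)) / 1e6
  expect_equal(cov, 0.2)
  expect_lt(cov, naive)
  expect_error(ladCoverage(GRanges("chr9", IRanges(1, 10)), cs), "absent")
})

test_that("coverage-exponential fit recovers parameters", {
  x <- seq(0.05, 0.6, length.out = 12)
  y <- 1.2 * exp(-2 * x)
  f <- fitCoverageExponential(x, y)
  expect_equal(f$a, 1.2, tolerance = 1e-6)
  expect_equal(f$b, 2, tolerance = 1e-6)

  const <- fitCoverageExponential(x, rep(0.9, 12))
  expect_equal(const$a, 0.9, tolerance = 1e-6)
  expect_lt(abs(const$b), 1e-6)

  # noisy data: objective within 1% of a dense grid-search optimum
  set.seed(2)
  yn <- y * exp(rnorm(12, 0, 0.05))
  fn <- fitCoverageExponential(x, yn)
  grid <- expand.grid(a = seq(0.8, 1.6, length.out = 120),
                      b = seq(0.5, 3.5, length.out = 120))
  obj <- vapply(seq_len(nrow(grid)), function(k)
    sum((yn - grid$a[k] * exp(-grid$b[k] * x))^2), 0)
  expect_lte(sum(fn$residuals^2), min(obj) * 1.01)
  expect_error(fitCoverageExponential(x, -y), "positive")
})

test_that("trans change measures fold changes with antisymmetry", {
  tc <- simTransContacts(50, 50, 6, 2, seed = 12)
  same <- transChange(list(p = tc$control), list(p = tc$control))
  expect_equal(same$pctChange, 0)

  doubled <- ContactMatrix(within(contactCounts(tc$control),
                                  count <- count * 2),
                           1e6, 50, 50, "chrA", "chrB")
  expect_equal(transChange(list(p = tc$control),
                           list(p = doubled))$pctChange, 100)

  got <- transChange(list(p = tc$control), list(p = tc$treated))$pctChange
  expect_lt(abs(got - 100), 6)     # fold 2 -> +100% +/- sampling error

  # antisymmetry: pct(a,b) = -100 * pct(b,a) / (100 + pct(b,a))
  fwd <- transChange(list(p = tc$control), list(p = tc$treated))$pctChange
  rev <- transChange(list(p = tc$treated), list(p = tc$control))$pctChange
  expect_equal(fwd, -100 * rev / (100 + rev), tolerance = 1e-9)

  expect_error(transChange(list(a = tc$control), list(b = tc$treated)),
               "same chromosome pairs")
})

test_that("compartment eigenvector separates blocks and is deterministic", {
  n <- 12
  blocks <- rep(c(TRUE, FALSE), each = 6)
  M <- outer(1:n, 1:n, function(i, j)
    1 / (abs(i - j) + 1) * ifelse(blocks[i] == blocks[j], 2, 1))
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  cm <- ContactMatrix(data.frame(i = idx[, 1], j = idx[, 2],
                                 count = M[idx]), 1e5, n)
  ev <- compartmentEigenvector(cm)
  expect_equal(sum(ev$eigenvector^2), 1, tolerance = 1e-9)
  expect_true(all(sign(ev$eigenvector[blocks]) !=
                  sign(ev$eigenvector[!blocks])))

  # dense eigen-decomposition oracle built independently from the matrix
  E <- vapply(0:(n - 1), function(d) {
    v <- M[col(M) - row(M) == d]
    mean(v[v > 0])
  }, 0)
  oe <- M / E[abs(outer(1:n, 1:n, "-")) + 1]
  co <- cor(oe)
  eo <- eigen(co, symmetric = TRUE)
  vo <- eo$vectors[, which.max(abs(eo$values))]
  expect_equal(abs(cor(ev$eigenvector, vo)), 1, tolerance = 1e-9)

  # reference-track sign convention
  ref <- as.numeric(!blocks)
  ev2 <- compartmentEigenvector(cm, referenceTrack = ref)
  expect_gt(cor(ev2$eigenvector, ref), 0)

  # degenerate constant matrix
  flatM <- ContactMatrix(data.frame(i = idx[, 1], j = idx[, 2], count = 1),
                         1e5, n)
  expect_error(compartmentEigenvector(flatM), "degenerate")
})

test_that("domain/LAD summaries class by overlap fraction", {
  lads <- GRanges("chr1", IRanges(c(1e5, 5e5), c(2e5, 8e5)))
  doms <- GRanges("chr1", IRanges(c(1.2e5, 3e5, 4.8e5),
                                  c(1.8e5, 4e5, 6e5)))
  res <- domainLadSummary(doms, lads)
  expect_identical(as.character(res$perDomain$class),
                   c("LAD", "nonLAD", "LAD"))
  expect_identical(res$summary$n, c(2L, 1L))

  # random layouts vs brute-force overlap oracle
  set.seed(21)
  for (rep in 1:5) {
    ds <- sort(sample.int(9e5, 8))
    doms <- GRanges("chrR", IRanges(ds, ds + sample(2e4:1e5, 8)))
    ls <- sort(sample.int(9e5, 5))
    lads <- reduce(GRanges("chrR", IRanges(ls, ls + sample(3e4:2e5, 5))))
    got <- domainLadSummary(doms, lads)
    oracle <- vapply(seq_along(doms), function(k) {
      ov <- sum(pmax(0, pmin(end(lads), end(doms)[k]) -
                        pmax(start(lads), start(doms)[k]) + 1))
      ov >= 0.5 * width(doms)[k]
    }, TRUE)
    expect_identical(got$perDomain$class == "LAD", oracle)
    expect_equal(got$summary$meanKb[1],
                 mean(width(doms)[oracle]) / 1000)
  }
})
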