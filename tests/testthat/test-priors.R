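test_that("MRSI purity rule labels tumour ROIs as the paper prescribes", {
  geom <- mrsiGeometry(originVox = c(1, 1, 1), blockSize = c(2, 2, 1),
                       gridDim = c(3, 3))
  shape <- c(6, 6, 1)
  fr <- expand.grid(i = 1:3, j = 1:3)
  fr$fraction_normal <- 0.05
  fr$fraction_GII <- 0.92
  fr$fraction_GIV <- 0.03
  roi <- deriveTumourROIs(fr, geom, grade = "GII", shape = shape)
  expect_true(all(roi@labels == tissueIndex("GII")))

  fr2 <- fr
  fr2$fraction_normal <- 0.2; fr2$fraction_GII <- 0; fr2$fraction_GIV <- 0.8
  roi2 <- deriveTumourROIs(fr2, geom, grade = "GIV", shape = shape)
  expect_true(all(roi2@labels == 0))  # 0.8 fails the strict >0.9 rule

  # enumeration oracle on 9 MRSI voxels with mixed known fractions
  set.seed(31)
  fr3 <- expand.grid(i = 1:3, j = 1:3)
  fr3$fraction_GIV <- round(runif(9), 3)
  fr3$fraction_GII <- round(runif(9) * (1 - fr3$fraction_GIV), 3)
  fr3$fraction_normal <- 1 - fr3$fraction_GIV - fr3$fraction_GII
  roi3 <- deriveTumourROIs(fr3, geom, grade = "GIV", shape = shape)
  handCount <- sum(fr3$fraction_GIV > 0.9) * 4  # 2x2x1 voxels per block
  expect_identical(sum(roi3@labels == tissueIndex("GIV")), as.integer(handCount))

  # fractions must sum to one; blocks must stay inside the image
  frBad <- fr; frBad$fraction_normal <- 0.5
  expect_error(deriveTumourROIs(frBad, geom, grade = "GII", shape = shape),
               "sum to 1")
  expect_error(deriveTumourROIs(fr, geom, grade = "GII", shape = c(4, 4, 1)),
               "outside")
})

test_that("necrosis split relabels GIV voxels above the p threshold", {
  giv <- tissueIndex("GIV"); ne <- tissueIndex("Ne")
  lab <- array(0L, c(10, 10, 1))
  lab[1:100] <- giv
  p <- array(1e-3, c(10, 10, 1))
  p[1] <- 5e-3    # above 4e-3 -> necrosis
  p[2] <- 1e-3    # below -> stays GIV
  out <- splitNecrosis(labelVolume(lab), p)
  expect_identical(out@labels[1], ne)
  expect_identical(out@labels[2], giv)

  # counting oracle: 30 of 100 voxels above threshold
  set.seed(32)
  p2 <- array(1e-3, c(10, 10, 1))
  hot <- sample(100, 30)
  p2[hot] <- 4e-3 + runif(30, 1e-4, 2e-3)
  out2 <- splitNecrosis(labelVolume(lab), p2)
  expect_identical(sum(out2@labels == ne), 30L)
  expect_identical(sum(out2@labels == giv), 70L)

  lab2 <- lab; lab2[50] <- tissueIndex("GM")
  expect_error(splitNecrosis(labelVolume(lab2), p), "only GIV")
})

test_that("shared bin grid spans the pooled 0.5-99.5 percentile range", {
  set.seed(33)
  n <- 20000
  u <- matrix(runif(4 * n), ncol = 4)
  grid <- fitBinGrid(list(A = u), bins = 50)
  for (c in 1:4) {
    expect_lt(abs(grid@edges[[c]][1] - 0.005), 0.003)
    expect_lt(abs(grid@edges[[c]][51] - 0.995), 0.003)
    w <- diff(grid@edges[[c]])
    expect_lt(max(abs(w - mean(w))), 1e-12)   # uniform spacing
  }

  # pooling invariance: single- vs multi-class with the same union
  half <- n / 2
  g1 <- fitBinGrid(list(A = u), bins = 20)
  g2 <- fitBinGrid(list(A = u[1:half, ], B = u[(half + 1):n, ]), bins = 20)
  expect_equal(g1@edges, g2@edges, tolerance = 1e-12)

  # bins = 2 on {0..10}: three edges, middle at the percentile-range midpoint
  s <- matrix(rep(0:10, 4), ncol = 4)
  g3 <- fitBinGrid(list(A = s), bins = 2)
  e <- g3@edges$p
  expect_length(e, 3)
  expect_equal(e[2], (e[1] + e[3]) / 2, tolerance = 1e-12)

  expect_error(fitBinGrid(list(), bins = 10), "empty")
  expect_error(fitBinGrid(list(A = u[1:5, ]), bins = 50), "below bins")
})

test_that("4D histograms are unit-integral densities with exact counts", {
  set.seed(34)
  grid <- fitBinGrid(list(A = matrix(runif(4 * 1000), ncol = 4)), bins = 10)
  binvol <- prod(vapply(grid@edges, function(e) diff(e)[1], 1))

  # one sample -> one bin at density 1/binvolume
  one <- matrix(rep(0.5, 4), ncol = 4)
  pdd1 <- buildPDD(one, grid, "GM")
  expect_identical(sum(pdd1@density > 0), 1L)
  expect_equal(max(pdd1@density), 1 / binvol, tolerance = 1e-9)

  # unit integral for random samples
  pddR <- buildPDD(matrix(runif(4 * 500), ncol = 4), grid, "WM")
  expect_equal(sum(pddR@density) * binvol, 1, tolerance = 1e-9)

  # 6 hand-placed samples in 3 bins with counts 3:2:1
  centre <- function(i) vapply(grid@edges, function(e)
    (e[i] + e[i + 1]) / 2, 1)
  six <- rbind(matrix(centre(2), 3, 4, byrow = TRUE),
               matrix(centre(5), 2, 4, byrow = TRUE),
               matrix(centre(8), 1, 4, byrow = TRUE))
  pdd6 <- buildPDD(six, grid, "GII")
  d <- sort(pdd6@density[pdd6@density > 0])
  expect_equal(d / d[1], c(1, 2, 3), tolerance = 1e-9)

  expect_error(buildPDD(matrix(numeric(0), ncol = 4), grid, "Ne"), "no samples")
})

test_that("density lookup equals independent bin indexing", {
  set.seed(35)
  grid <- fitBinGrid(list(A = matrix(rnorm(4 * 2000), ncol = 4)), bins = 12)
  pdd <- buildPDD(matrix(rnorm(4 * 800), ncol = 4), grid, "GM")

  # the single-sample bin and an empty bin
  binvol <- prod(vapply(grid@edges, function(e) diff(e)[1], 1))
  one <- matrix(rep(0, 4), ncol = 4)
  pdd1 <- buildPDD(one, grid, "WM")
  expect_equal(lookupDensity(pdd1, c(0, 0, 0, 0)), 1 / binvol,
               tolerance = 1e-9)
  far <- vapply(grid@edges, function(e) e[1] + 1e-9, 1)
  expect_identical(lookupDensity(pdd1, far) == 0, TRUE)

  # brute-force oracle at 1000 random points (including out-of-grid)
  xs <- matrix(rnorm(4 * 1000, sd = 2), ncol = 4)
  got <- lookupDensity(pdd, xs)
  want <- vapply(seq_len(1000), function(i) lookupOracle(pdd, xs[i, ]), 1)
  expect_equal(got, want, tolerance = 0)
})

test_that("clipping: out-of-grid samples behave as edge-bin samples", {
  set.seed(36)
  grid <- fitBinGrid(list(A = matrix(runif(4 * 500), ncol = 4)), bins = 8)
  inside <- matrix(runif(4 * 20, 0.2, 0.8), ncol = 4)
  outlier <- matrix(c(10, 0.5, 0.5, 0.5), ncol = 4)      # beyond the p range
  edgeCentre <- outlier
  e <- grid@edges$p
  edgeCentre[1] <- (e[8] + e[9]) / 2                     # last-bin centre
  pddA <- buildPDD(rbind(inside, outlier), grid, "GM")
  pddB <- buildPDD(rbind(inside, edgeCentre), grid, "GM")
  expect_equal(pddA@density, pddB@density, tolerance = 0)
})

test_that("histograms converge to an analytic Gaussian density", {
  edges <- lapply(1:4, function(i) seq(-4, 4, length.out = 11))
  names(edges) <- c("p", "q", "T2n", "PDn")
  grid <- new("BinGrid4D", edges = edges, bins = 10L)
  # analytic bin-average density of a standard 4D normal
  p1 <- diff(pnorm(edges$p))
  prob <- outer(outer(outer(p1, p1), p1), p1)
  w <- diff(edges$p)[1]
  analytic <- prob / w^4
  e3 <- local({
    set.seed(37)
    pdd <- buildPDD(matrix(rnorm(4 * 1e3), ncol = 4), grid, "GM")
    mean(abs(pdd@density - analytic))
  })
  e5 <- local({
    set.seed(38)
    pdd <- buildPDD(matrix(rnorm(4 * 1e5), ncol = 4), grid, "GM")
    mean(abs(pdd@density - analytic))
  })
  expect_lt(e5, e3)
  expect_lt(e5, 5e-4)
})

test_that("optional bin-space smoothing preserves the unit integral", {
  set.seed(39)
  grid <- fitBinGrid(list(A = matrix(rnorm(4 * 1000), ncol = 4)), bins = 10)
  pdd <- buildPDD(matrix(rnorm(4 * 200), ncol = 4), grid, "GM",
                  smoothSigma = 1)
  expect_equal(sum(pdd@density * gliotype:::.binHypervolume(grid)), 1,
               tolerance = 1e-9)
  expect_gt(sum(pdd@density > 0), 200)  # mass spread beyond occupied bins
})

test_that("PDD set archives round-trip through the text format", {
  set.seed(40)
  grid <- fitBinGrid(list(A = matrix(rnorm(4 * 500), ncol = 4)), bins = 8)
  pdds <- list(GM = buildPDD(matrix(rnorm(4 * 100), ncol = 4), grid, "GM"),
               GII = buildPDD(matrix(rnorm(4 * 150), ncol = 4), grid, "GII"))
  dir <- withr::local_tempdir()
  writePDDSet(pdds, dir)
  back <- readPDDSet(dir)
  expect_setequal(names(back), names(pdds))
  for (nm in names(pdds)) {
    expect_equal(back[[nm]]@density, pdds[[nm]]@density, tolerance = 1e-12)
    expect_identical(back[[nm]]@nSamples, pdds[[nm]]@nSamples)
  }
})
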