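# helper: a PosteriorMap around a given (x, y, z, 7) probability array
makePosterior <- function(probs, vox = c(1, 1, 1)) {
  new("PosteriorMap", probs = probs,
      outOfSupport = array(FALSE, dim(probs)[1:3]),
      classOrder = tissueClasses(), voxelSize = vox)
}

test_that("a uniform slice yields a near-regular superpixel grid", {
  sh <- c(256, 256, 1)
  vol <- multimodalVolume(list(PDn = array(1, sh), FLAIR = array(1, sh),
                               p = array(1e-3, sh)), c(0.9375, 0.9375, 5))
  labels <- computeSuperpixels(vol, gridSize = 30, upsampleFactor = 4)
  count <- length(unique(labels[labels > 0]))
  expected <- (1024 / 30)^2
  expect_lt(abs(count - expected) / expected, 0.15)
  # ids partition the mask
  expect_true(all(labels > 0))
})

test_that("superpixels adhere to a high-contrast disc boundary", {
  sh <- c(128, 128, 1)
  ctr <- c(64.5, 64.5); R <- 40
  r <- sqrt(outer((1:128 - ctr[1])^2, (1:128 - ctr[2])^2, "+"))
  disc <- array(as.numeric(r <= R), sh)
  vol <- multimodalVolume(list(PDn = disc, FLAIR = disc,
                               p = disc * 1e-3), c(1, 1, 5))
  labels <- computeSuperpixels(vol, gridSize = 30, upsampleFactor = 2)
  step <- 30 / 2  # SLIC spatial step in native pixels
  ids <- unique(labels[labels > 0])
  expect_gt(length(ids), 9)
  # leakage: how far the minority side of any boundary-straddling
  # superpixel reaches past the disc edge
  worst <- 0
  for (id in ids) {
    vox <- which(labels[, , 1] == id)
    rs <- r[vox]
    nin <- sum(rs <= R); nout <- sum(rs > R)
    if (nin == 0 || nout == 0) next
    minority <- if (nin < nout) rs[rs <= R] else rs[rs > R]
    worst <- max(worst, max(abs(minority - R)))
  }
  expect_lte(worst, step)
})

test_that("identical slices segment identically (deterministic)", {
  set.seed(61)
  slice <- matrix(runif(96 * 96), 96)
  mk <- function(m) array(rep(m, 2), c(96, 96, 2))
  vol <- multimodalVolume(list(PDn = mk(slice), FLAIR = mk(slice * 0.5),
                               p = mk(slice * 1e-3)), c(2, 2, 5))
  labels <- computeSuperpixels(vol, gridSize = 20, upsampleFactor = 2)
  l1 <- labels[, , 1]
  l2 <- labels[, , 2]
  offset <- max(l1)
  expect_true(all(l2[l2 > 0] - offset == l1[l1 > 0]))
  expect_identical(l2 > 0, l1 > 0)
})

test_that("probability averaging matches brute force and conserves mass", {
  set.seed(62)
  sh <- c(12, 10, 2)
  probs <- array(runif(prod(sh) * 7), c(sh, 7))
  s <- apply(probs, 1:3, sum)
  for (k in 1:7) probs[, , , k] <- probs[, , , k] / s
  post <- makePosterior(probs)

  # constant field: every superpixel reproduces the constant
  cprobs <- array(rep(c(0.4, 0.3, 0.1, 0.1, 0.05, 0.03, 0.02),
                      each = prod(sh)), c(sh, 7))
  labels <- array(rep(1:4, each = prod(sh) / 4), sh)
  spmC <- averageProbabilities(makePosterior(cprobs), labels)
  for (i in 1:4)
    expect_equal(as.numeric(superpixelProbs(spmC)[i, ]),
                 c(0.4, 0.3, 0.1, 0.1, 0.05, 0.03, 0.02), tolerance = 1e-12)

  # two voxels with one-hot posteriors average to (0.5, 0.5, 0, ...)
  sh2 <- c(2, 1, 1)
  p2 <- array(0, c(sh2, 7)); p2[1, 1, 1, 1] <- 1; p2[2, 1, 1, 2] <- 1
  spm2 <- averageProbabilities(makePosterior(p2), array(1L, sh2))
  expect_equal(as.numeric(superpixelProbs(spm2)[1, ]),
               c(0.5, 0.5, 0, 0, 0, 0, 0), tolerance = 1e-12)

  # random field against an independent per-id mean
  set.seed(63)
  labels <- array(sample(1:17, prod(sh), replace = TRUE), sh)
  spm <- averageProbabilities(post, labels)
  for (id in sort(unique(as.integer(labels)))) {
    sel <- labels == id
    want <- vapply(1:7, function(k) mean(probs[, , , k][sel]), 1)
    want <- want / sum(want)
    expect_equal(as.numeric(superpixelProbs(spm)[as.character(id), ]), want,
                 tolerance = 1e-9)
  }

  # mass conservation: sum over superpixels of size * mean equals the
  # per-class posterior mass over all member voxels
  lhs <- colSums(superpixelProbs(spm) * as.numeric(superpixelSizes(spm)))
  rhs <- vapply(1:7, function(k) sum(probs[, , , k]), 1)
  expect_equal(as.numeric(lhs), rhs, tolerance = 1e-6)
})

# helper: a SuperpixelMap over a superpixel grid of 2x2-voxel blocks with
# prescribed abnormality
makeBlockSpMap <- function(spRows, spCols, abnormalIds) {
  sh <- c(2 * spRows, 2 * spCols, 1)
  spGrid <- matrix(seq_len(spRows * spCols), spRows, spCols)
  labels <- array(spGrid[rep(seq_len(spRows), each = 2),
                         rep(seq_len(spCols), each = 2)], sh)
  n <- spRows * spCols
  probs <- matrix(0, n, 7, dimnames = list(as.character(1:n), NULL))
  probs[, tissueIndex("GM")] <- 1
  probs[abnormalIds, ] <- 0
  probs[abnormalIds, tissueIndex("VO")] <- 0.8
  probs[abnormalIds, tissueIndex("GM")] <- 0.2
  size <- structure(rep(4L, n), names = as.character(1:n))
  new("SuperpixelMap", labels = labels, spProbs = probs, spSize = size,
      classOrder = tissueClasses())
}

test_that("lesion extraction keeps the largest connected component", {
  # all-normal map: empty lesion, zero volume
  spmN <- makeBlockSpMap(6, 6, integer(0))
  lesN <- extractLesion(spmN, c(1, 1, 1))
  expect_equal(lesionVolumeMl(lesN), 0)
  expect_false(any(lesionMask(lesN)))

  # 90-superpixel blob and a disconnected 10-superpixel blob
  spGrid <- matrix(seq_len(12 * 10), 12, 10)
  blobA <- as.integer(spGrid[1:9, ])              # 90 superpixels
  blobB <- as.integer(spGrid[11:12, 1:5])         # 10, separated by row 10
  spm <- makeBlockSpMap(12, 10, c(blobA, blobB))
  les <- extractLesion(spm, c(1, 1, 1))
  expect_identical(les@componentCountConsidered, 2L)
  kept <- unique(spm@labels[lesionMask(les)])
  expect_setequal(kept, blobA)
  expect_equal(lesionVolumeMl(les), 90 * 4 / 1000, tolerance = 1e-12)

  # lesion mask is invariant under a relabelling of superpixel ids
  perm <- sample(120)
  labs2 <- array(perm[spm@labels], dim(spm@labels))
  probs2 <- spm@spProbs[order(perm), , drop = FALSE]
  rownames(probs2) <- as.character(1:120)
  size2 <- structure(spm@spSize[order(perm)], names = as.character(1:120))
  spm2 <- new("SuperpixelMap", labels = labs2, spProbs = probs2,
              spSize = size2, classOrder = tissueClasses())
  les2 <- extractLesion(spm2, c(1, 1, 1))
  expect_identical(lesionMask(les2), lesionMask(les))
})

test_that("colour map follows the RGB rule with intensity modulation", {
  mk <- function(giv, gii, ne, vo = 0) {
    gm <- 1 - giv - gii - ne - vo
    probs <- matrix(c(gm, 0, 0, vo, gii, giv, ne), 1, 7,
                    dimnames = list("1", NULL))
    sz <- structure(4L, names = "1")
    spm <- new("SuperpixelMap", labels = array(1L, c(2, 2, 1)),
               spProbs = probs, spSize = sz, classOrder = tissueClasses())
    les <- extractLesion(spm, c(1, 1, 1))
    list(spm = spm, les = les,
         rgb = colourArray(renderColourMap(spm, les))[1, 1, 1, ])
  }
  # pure high-grade: saturated red
  expect_equal(mk(giv = 1, gii = 0, ne = 0)$rgb, c(1, 0, 0),
               tolerance = 1e-12)
  # pure vasogenic oedema: black
  expect_equal(mk(giv = 0, gii = 0, ne = 0, vo = 1)$rgb, c(0, 0, 0),
               tolerance = 1e-12)
  # equal low/high-grade mixture: yellow at 1/sqrt(2)
  expect_equal(mk(giv = 0.5, gii = 0.5, ne = 0)$rgb,
               c(1 / sqrt(2), 1 / sqrt(2), 0), tolerance = 1e-12)
  # outside the lesion everything is black
  spmN <- makeBlockSpMap(4, 4, integer(0))
  lesN <- extractLesion(spmN, c(1, 1, 1))
  expect_true(all(colourArray(renderColourMap(spmN, lesN)) == 0))
})

test_that("colour norm never exceeds the tumour-tissue probability", {
  fx <- e2eFixture()
  cmap <- renderColourMap(fx$spm, fx$lesion)
  rgb <- colourArray(cmap)
  norm <- sqrt(rgb[, , , 1]^2 + rgb[, , , 2]^2 + rgb[, , , 3]^2)
  P <- posteriorArray(fx$post)
  ids <- superpixelLabels(fx$spm)
  pr <- superpixelProbs(fx$spm)
  inLes <- lesionMask(fx$lesion) & ids > 0
  tumourP <- array(0, dim(ids))
  tumourP[inLes] <- rowSums(pr[, tissueIndex(c("GII", "GIV", "Ne"))])[
    match(ids[inLes], as.integer(rownames(pr)))]
  expect_true(all(norm[inLes] <= tumourP[inLes] + 1e-6))
})

test_that("high-grade volume totals lesion superpixels above threshold", {
  # a single 1 ml superpixel at p(GIV) = 0.6 contributes exactly 1 ml
  probs <- matrix(c(0, 0, 0, 0, 0.4, 0.6, 0), 1, 7,
                  dimnames = list("1", NULL))
  spm <- new("SuperpixelMap", labels = array(1L, c(10, 10, 10)),
             spProbs = probs, spSize = structure(1000L, names = "1"),
             classOrder = tissueClasses())
  les <- extractLesion(spm, c(1, 1, 1))
  expect_equal(highGradeVolume(spm, les, c(1, 1, 1)), 1, tolerance = 1e-12)
  # no superpixel above threshold: zero
  expect_equal(highGradeVolume(spm, les, c(1, 1, 1), threshold = 0.7), 0)
})
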