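# Shared fixtures. The full-resolution end-to-end run is expensive, so it
# is computed once per session and cached; smaller phantoms serve the
# cheaper module tests.

.fixtures <- new.env(parent = emptyenv())

# Full-size high-grade phantom plus the trained classifier and superpixel
# pipeline outputs (fixed seed).
e2eFixture <- function() {
  if (!is.null(.fixtures$e2e)) return(.fixtures$e2e)
  spec <- phantomSpec(seed = 42)
  ph <- generatePhantom(spec)
  train <- sampleTrainingSet(spec, 10000)
  grid <- fitBinGrid(train, bins = 50)
  pdds <- lapply(names(train), function(cl) buildPDD(train[[cl]], grid, cl))
  names(pdds) <- names(train)
  post <- classifyVolume(ph$volume, pdds, ph$brainMask)
  labels <- computeSuperpixels(ph$volume, ph$brainMask)
  spm <- averageProbabilities(post, labels)
  lesion <- extractLesion(spm, voxelSize(ph$volume))
  .fixtures$e2e <- list(spec = spec, ph = ph, train = train, grid = grid,
                        pdds = pdds, post = post, spm = spm,
                        lesion = lesion)
  .fixtures$e2e
}

# Coarse phantom for cheap smoke/property tests: same field of view on a
# 96 x 96 x 8 grid of 2.5 x 2.5 x 5 mm voxels, tumour flattened to fit
# the thinner slab.
smallPhantomSpec <- function(seed = 7, ...) {
  phantomSpec(shape = c(96, 96, 8), voxelSize = c(2.5, 2.5, 5),
              geometry = list(brainSemiAxes = c(105, 105, 18),
                              ventricleSemiAxes = c(10, 28, 6),
                              voRadii = c(32, 32, 12),
                              giiRadii = c(24, 24, 9),
                              givRadii = c(15, 15, 6),
                              neRadii = c(8, 8, 3)),
              seed = seed, ...)
}

# Independent O(n^2) loop implementation of sample distance correlation,
# kept deliberately naive (explicit loops, no shared code with the
# package implementation).
dcorLoopOracle <- function(xs, ys) {
  xs <- as.matrix(xs); ys <- as.matrix(ys)
  n <- nrow(xs)
  dmat <- function(m) {
    d <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    d
  }
  centre <- function(d) {
    A <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      A[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + mean(d)
    A
  }
  A <- centre(dmat(xs)); B <- centre(dmat(ys))
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  sqrt(dcov2 / sqrt(dvx * dvy))
}

# Independent bin lookup: recompute the bin index of one 4-vector by
# explicit comparison against the edge vectors.
lookupOracle <- function(pdd, x) {
  idx <- integer(4)
  for (c in 1:4) {
    e <- pdd@grid@edges[[c]]
    k <- sum(x[c] >= e)          # number of edges at or below x
    if (k < 1) k <- 1
    if (k > pdd@grid@bins) k <- pdd@grid@bins
    idx[c] <- k
  }
  pdd@density[idx[1], idx[2], idx[3], idx[4]]
}
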