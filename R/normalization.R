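#' Build a reference intensity histogram from a masked volume
#'
#' The reference spans the 0.1-99.9 percentile range of the masked
#' intensities with uniformly spaced bins (default 256, the 8-bit
#' acquisition-matrix convention); out-of-range intensities are clipped
#' into the end bins when histogramming.
#'
#' @param volume 3D numeric array (or vector of intensities).
#' @param mask Logical array of the same shape (default: all voxels).
#' @param bins Number of bins (default 256).
#' @param sourceId Free-text provenance tag.
#' @return A [ReferenceHistogram-class].
#' @export
buildReferenceHistogram <- function(volume, mask = NULL, bins = 256,
                                    sourceId = "reference") {
  v <- if (is.null(mask)) as.numeric(volume) else as.numeric(volume[mask])
  if (length(v) == 0) stop("empty mask")
  rng <- quantile(v, c(0.001, 0.999), names = FALSE)
  if (rng[2] <= rng[1]) stop("degenerate (constant) intensities")
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- .histCounts(v, edges)
  new("ReferenceHistogram", binEdges = edges, counts = counts,
      sourceId = sourceId)
}

# Clipped histogram counts on fixed edges.
.histCounts <- function(v, edges) {
  idx <- .binIndex1(v, edges)
  tabulate(idx, nbins = length(edges) - 1L)
}

# Unit-sum histogram of a*I + b on the reference edges, and its L2
# distance to the unit-sum reference. This is the normalisation objective.
.histL2 <- function(v, a, b, ref) {
  h <- .histCounts(a * v + b, ref@binEdges)
  h <- h / sum(h)
  r <- ref@counts / sum(ref@counts)
  sqrt(sum((h - r)^2))
}

#' Fit the affine intensity map that matches a volume to a reference
#'
#' Finds scale a > 0 and shift b such that the unit-sum histogram of
#' a*I + b on the reference bin edges minimises the L2 norm of its
#' difference to the unit-sum reference histogram. Because binning makes
#' the objective piecewise-constant in (a, b), the optimiser is a
#' moment-matched coarse grid search followed by Nelder-Mead refinement.
#'
#' @param volume 3D numeric array (or intensity vector).
#' @param ref A [ReferenceHistogram-class].
#' @param mask Logical array restricting the fit (default: all voxels).
#' @param gridN Points per axis in the coarse grid (default 21).
#' @return List with elements `scale`, `shift`, `residualL2`.
#' @export
#' @examples
#' set.seed(1)
#' v <- rnorm(5000, 100, 15)
#' ref <- buildReferenceHistogram(v, bins = 64)
#' fitAffineIntensityMap(v + 30, ref)  # shift approximately -30
fitAffineIntensityMap <- function(volume, ref, mask = NULL, gridN = 21) {
  v <- if (is.null(mask)) as.numeric(volume) else as.numeric(volume[mask])
  if (length(v) == 0) stop("empty mask")
  if (sd(v) == 0) stop("degenerate (constant) intensities")

  # moment-matched starting point from the reference histogram
  mids <- (head(ref@binEdges, -1) + ref@binEdges[-1]) / 2
  w <- ref@counts / sum(ref@counts)
  refMean <- sum(w * mids)
  refSd <- sqrt(sum(w * (mids - refMean)^2))
  a0 <- refSd / sd(v)
  b0 <- refMean - a0 * mean(v)
  span <- diff(range(ref@binEdges))

  # coarse grid around the moment estimate
  aGrid <- a0 * exp(seq(log(0.4), log(2.5), length.out = gridN))
  bGrid <- b0 + seq(-0.5, 0.5, length.out = gridN) * span
  obj <- outer(aGrid, bGrid,
               Vectorize(function(a, b) .histL2(v, a, b, ref)))
  best <- arrayInd(which.min(obj), dim(obj))
  a <- aGrid[best[1]]; b <- bGrid[best[2]]

  # derivative-free local refinement (scale kept positive via log)
  opt <- optim(c(log(a), b),
               function(p) .histL2(v, exp(p[1]), p[2], ref),
               method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  if (opt$value <= obj[best]) {
    a <- exp(opt$par[1]); b <- opt$par[2]; res <- opt$value
  } else {
    res <- obj[best]
  }
  list(scale = a, shift = b, residualL2 = res)
}

#' Apply an affine intensity map
#'
#' @param volume Numeric array.
#' @param scale,shift Affine coefficients from [fitAffineIntensityMap()].
#' @return `scale * volume + shift`, elementwise.
#' @export
applyIntensityMap <- function(volume, scale, shift) {
  scale * volume + shift
}

#' Normalisation objective for a given affine map
#'
#' Exposes the L2 histogram-distance objective so callers can compare
#' candidate maps (used in tests and diagnostics).
#'
#' @inheritParams fitAffineIntensityMap
#' @param scale,shift Affine coefficients.
#' @return The L2 distance between unit-sum histograms.
#' @export
intensityMapObjective <- function(volume, ref, scale = 1, shift = 0,
                                  mask = NULL) {
  v <- if (is.null(mask)) as.numeric(volume) else as.numeric(volume[mask])
  .histL2(v, scale, shift, ref)
}

#' Write a reference histogram to a two-column text file
#'
#' Format: tab-separated `edge<TAB>count`; the last row carries the final
#' edge with an empty count.
#'
#' @param ref A [ReferenceHistogram-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeReferenceHistogram <- function(ref, path) {
  df <- data.frame(edge = ref@binEdges,
                   count = c(ref@counts, NA))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference histogram written by [writeReferenceHistogram()]
#'
#' @param path Input path.
#' @param sourceId Provenance tag (default: the file name).
#' @return A [ReferenceHistogram-class].
#' @export
readReferenceHistogram <- function(path, sourceId = basename(path)) {
  df <- read.table(path, header = TRUE, sep = "\t")
  new("ReferenceHistogram", binEdges = df$edge,
      counts = df$count[!is.na(df$count)], sourceId = sourceId)
}
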