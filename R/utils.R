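# Internal helpers shared across modules.

# Per-bin 4D hypervolume array for a BinGrid4D (outer product of the four
# per-axis bin widths). For uniform edges this is constant, but the code
# supports non-uniform edges throughout.
.binHypervolume <- function(grid) {
  w <- lapply(grid@edges, diff)
  outer(outer(outer(w[[1]], w[[2]]), w[[3]]), w[[4]])
}

# Bin index along one axis with clipping: values below the grid fall into
# the first bin, values at or above the top edge into the last. Interior
# values on an edge belong to the right-hand bin (findInterval semantics),
# identically in histogram construction and lookup.
.binIndex1 <- function(x, edges) {
  pmin(pmax(findInterval(x, edges), 1L), length(edges) - 1L)
}

# Column-major linear index into a bins^4 array from an n x 4 matrix of
# per-axis bin indices.
.linearIndex4 <- function(idx, bins) {
  ((idx[, 4] - 1L) * bins + (idx[, 3] - 1L)) * bins * bins +
    (idx[, 2] - 1L) * bins + idx[, 1]
}

# n x 4 bin-index matrix for samples (n x 4 matrix, columns p/q/T2n/PDn).
.binIndex4 <- function(x, grid) {
  idx <- vapply(seq_len(4), function(c) .binIndex1(x[, c], grid@edges[[c]]),
                integer(nrow(x)))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)  # single sample
  idx
}

# Robust [0,1] rescale by the lo-hi percentile range (values clipped).
.percentileRescale <- function(x, lo = 0.01, hi = 0.99) {
  qs <- quantile(x, c(lo, hi), names = FALSE, na.rm = TRUE)
  if (qs[2] <= qs[1]) return(array(0, dim(x)))
  y <- (x - qs[1]) / (qs[2] - qs[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  y
}

# Upsample a 2D matrix by integer factor f with nearest-neighbour
# replication (label-safe; used before per-slice SLIC).
.upsample2d <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
    drop = FALSE]
}
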