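#' ROI derivation rule set
#'
#' Thresholds governing training-ROI derivation: MRSI voxels whose spectrum
#' decomposes to more than `mrsiPurityThreshold` of one glioma grade define
#' tumour ROIs; GIV ROI voxels with isotropic diffusivity p above
#' `necrosisPThreshold` (mm^2/s) are relabelled necrosis; normal-tissue
#' masks are expected to come from a probabilistic segmentation thresholded
#' at `normalProbThreshold` (an input contract — this package consumes such
#' masks, it does not segment controls).
#'
#' @param mrsiPurityThreshold Purity fraction, default 0.90 (strict >).
#' @param necrosisPThreshold Diffusivity in mm^2/s, default 4e-3 (strict >).
#' @param normalProbThreshold Probability, default 0.95.
#' @return A list of class `roiRules`.
#' @export
roiRules <- function(mrsiPurityThreshold = 0.90,
                     necrosisPThreshold = 4e-3,
                     normalProbThreshold = 0.95) {
  stopifnot(mrsiPurityThreshold > 0, mrsiPurityThreshold <= 1,
            necrosisPThreshold > 0,
            normalProbThreshold > 0, normalProbThreshold <= 1)
  structure(list(mrsiPurityThreshold = mrsiPurityThreshold,
                 necrosisPThreshold = necrosisPThreshold,
                 normalProbThreshold = normalProbThreshold),
            class = "roiRules")
}

# Image-voxel index ranges covered by MRSI voxel (gi, gj); errors if the
# block leaves the image.
.mrsiBlock <- function(geometry, gi, gj, shape) {
  o <- geometry@originVox; b <- geometry@blockSize
  xs <- o[1] + (gi - 1L) * b[1] + seq_len(b[1]) - 1L
  ys <- o[2] + (gj - 1L) * b[2] + seq_len(b[2]) - 1L
  zs <- o[3] + seq_len(b[3]) - 1L
  if (min(xs) < 1 || max(xs) > shape[1] ||
      min(ys) < 1 || max(ys) > shape[2] ||
      min(zs) < 1 || max(zs) > shape[3])
    stop(sprintf("MRSI voxel (%d, %d) maps outside the image", gi, gj))
  list(xs = xs, ys = ys, zs = zs)
}

#' Derive tumour training ROIs from MRSI tissue fractions
#'
#' Applies the purity rule: image voxels inside MRSI voxels whose spectral
#' decomposition exceeds the purity threshold for the patient's grade are
#' labelled GII (for grade II patients) or GIV (for grade IV patients);
#' every other voxel stays unlabelled.
#'
#' @param fractions Data frame with columns `i`, `j` (MRSI grid indices)
#'   and `fraction_normal`, `fraction_GII`, `fraction_GIV` summing to 1
#'   per row (tolerance 1e-6).
#' @param geometry An [MRSIGeometry-class] mapping grid voxels to image
#'   blocks.
#' @param rules A [roiRules()] list.
#' @param grade Patient grade, "GII" or "GIV".
#' @param shape Image grid shape (3 integers).
#' @return A [LabelVolume-class] labelling only the derived tumour ROI.
#' @export
deriveTumourROIs <- function(fractions, geometry, rules = roiRules(),
                             grade = c("GII", "GIV"), shape) {
  grade <- match.arg(grade)
  need <- c("i", "j", "fraction_normal", "fraction_GII", "fraction_GIV")
  if (!all(need %in% names(fractions)))
    stop("fractions must have columns ", paste(need, collapse = ", "))
  s <- rowSums(fractions[, need[3:5]])
  if (any(abs(s - 1) > 1e-6))
    stop("tissue fractions must sum to 1 per MRSI voxel")
  labels <- array(0L, shape)
  col <- paste0("fraction_", grade)
  hit <- fractions[[col]] > rules$mrsiPurityThreshold
  for (r in which(hit)) {
    blk <- .mrsiBlock(geometry, fractions$i[r], fractions$j[r], shape)
    labels[blk$xs, blk$ys, blk$zs] <- tissueIndex(grade)
  }
  labelVolume(labels)
}

#' Split necrosis out of a GIV ROI by isotropic diffusivity
#'
#' GIV-labelled voxels whose p diffusivity exceeds the necrosis threshold
#' (default 4e-3 mm^2/s, strict >) are relabelled Ne; all other voxels are
#' unchanged.
#'
#' @param givRoi A [LabelVolume-class] containing only GIV (and 0) labels.
#' @param pChannel 3D array of isotropic diffusivity p, same shape.
#' @param rules A [roiRules()] list.
#' @return A [LabelVolume-class] with GIV and Ne labels.
#' @export
splitNecrosis <- function(givRoi, pChannel, rules = roiRules()) {
  labels <- givRoi@labels
  if (!identical(dim(labels), dim(pChannel)))
    stop("p channel shape mismatch")
  present <- unique(labels[labels != 0])
  if (length(setdiff(present, tissueIndex("GIV"))))
    stop("givRoi must contain only GIV labels")
  ne <- labels == tissueIndex("GIV") & pChannel > rules$necrosisPThreshold
  labels[ne] <- tissueIndex("Ne")
  labelVolume(labels)
}

#' Fit the shared 4D bin grid from pooled training samples
#'
#' Pools the samples of all classes per channel and spans the pooled
#' 0.5-99.5 percentile range with uniformly spaced edges. One grid is
#' shared by every class histogram so cross-class likelihood ratios
#' compare densities at the same feature vector; out-of-range samples are
#' clipped into the end bins.
#'
#' @param samplesByClass Named list (tissue class -> n x 4 matrix with
#'   columns p, q, T2n, PDn).
#' @param bins Bins per axis (default 50).
#' @return A [BinGrid4D-class].
#' @export
fitBinGrid <- function(samplesByClass, bins = 50) {
  pooled <- do.call(rbind, samplesByClass)
  if (is.null(pooled) || nrow(pooled) == 0) stop("empty sample pool")
  if (nrow(pooled) < bins)
    stop("pooled sample count (", nrow(pooled), ") below bins (", bins, ")")
  edges <- lapply(seq_len(4), function(c) {
    qs <- quantile(pooled[, c], c(0.005, 0.995), names = FALSE)
    if (qs[2] <= qs[1]) stop("degenerate channel ", c)
    seq(qs[1], qs[2], length.out = bins + 1)
  })
  names(edges) <- c("p", "q", "T2n", "PDn")
  new("BinGrid4D", edges = edges, bins = as.integer(bins))
}

#' Build a per-class 4D probability density histogram
#'
#' Counts samples per 4D bin (values outside the grid clipped into edge
#' bins) and converts counts to densities, count / (n * bin hypervolume),
#' so the density integrates to 1 over the grid ("unit volume").
#'
#' @param samples n x 4 matrix (columns p, q, T2n, PDn), n >= 1.
#' @param grid The shared [BinGrid4D-class].
#' @param tissue Tissue class name.
#' @param smoothSigma Optional Gaussian smoothing width in bins applied in
#'   bin space (separable, renormalised); 0 (default) disables smoothing.
#' @return A [PDD4D-class].
#' @export
buildPDD <- function(samples, grid, tissue, smoothSigma = 0) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0) stop("no samples for class ", tissue)
  b <- grid@bins
  lin <- .linearIndex4(.binIndex4(samples, grid), b)
  counts <- tabulate(lin, nbins = b^4)
  dens <- array(counts / nrow(samples), rep(b, 4L)) / .binHypervolume(grid)
  if (smoothSigma > 0) {
    dens <- .smoothPDD(dens, smoothSigma)
    dens <- dens / sum(dens * .binHypervolume(grid))
  }
  new("PDD4D", tissue = tissue, grid = grid, density = dens,
      nSamples = nrow(samples))
}

# Separable Gaussian smoothing in bin space with renormalising (mass-
# preserving) truncated kernels at the array boundary.
.smoothPDD <- function(dens, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  b <- dim(dens)[1]
  conv1 <- function(m) {
    # m: b x M matrix, convolve columns-wise along rows with kernel k,
    # renormalising the truncated kernel at the edges
    out <- matrix(0, nrow(m), ncol(m))
    wsum <- numeric(nrow(m))
    for (o in -half:half) {
      w <- k[o + half + 1]
      src <- seq_len(b) - o
      ok <- src >= 1 & src <= b
      out[ok, ] <- out[ok, ] + w * m[src[ok], ]
      wsum[ok] <- wsum[ok] + w
    }
    out / wsum
  }
  d <- dim(dens)
  for (ax in 1:4) {
    perm <- c(ax, setdiff(1:4, ax))
    m <- matrix(aperm(dens, perm), nrow = b)
    m <- conv1(m)
    dens <- aperm(array(m, d[perm]), order(perm))
  }
  dens
}

#' Look up the histogram density at feature vectors
#'
#' Piecewise-constant lookup (no interpolation): the density of the bin
#' containing each point, with out-of-grid values clipped into edge bins.
#'
#' @param pdd A [PDD4D-class].
#' @param x A 4-vector or an n x 4 matrix (columns p, q, T2n, PDn).
#' @return Density value(s).
#' @export
lookupDensity <- function(pdd, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  lin <- .linearIndex4(.binIndex4(x, pdd@grid), pdd@grid@bins)
  as.numeric(pdd@density)[lin]
}

#' Serialise a set of class PDDs to a plain-text archive directory
#'
#' Writes the shared edges, per-class dense densities (as gzipped CSV of
#' nonzero bins) and metadata to one directory.
#'
#' @param pdds Named list of [PDD4D-class], one per class.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
writePDDSet <- function(pdds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- pdds[[1]]@grid
  edges <- do.call(cbind, grid@edges)
  write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  meta <- data.frame(tissue = vapply(pdds, slot, "", "tissue"),
                     nSamples = vapply(pdds, slot, 1L, "nSamples"),
                     bins = grid@bins)
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (nm in names(pdds)) {
    nz <- which(pdds[[nm]]@density > 0)
    df <- data.frame(bin = nz, density = pdds[[nm]]@density[nz])
    con <- gzfile(file.path(dir, paste0("pdd_", nm, ".tsv.gz")), "w")
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read a PDD set written by [writePDDSet()]
#'
#' @param dir Archive directory.
#' @return Named list of [PDD4D-class].
#' @export
readPDDSet <- function(dir) {
  edges <- read.table(file.path(dir, "edges.tsv"), header = TRUE, sep = "\t")
  meta <- read.table(file.path(dir, "meta.tsv"), header = TRUE, sep = "\t")
  bins <- meta$bins[1]
  grid <- new("BinGrid4D",
              edges = list(p = edges$p, q = edges$q, T2n = edges$T2n,
                           PDn = edges$PDn),
              bins = as.integer(bins))
  pdds <- list()
  for (r in seq_len(nrow(meta))) {
    nm <- meta$tissue[r]
    df <- read.table(gzfile(file.path(dir, paste0("pdd_", nm, ".tsv.gz"))),
                     header = TRUE, sep = "\t")
    dens <- array(0, rep(bins, 4L))
    dens[df$bin] <- df$density
    pdds[[nm]] <- new("PDD4D", tissue = nm, grid = grid, density = dens,
                      nSamples = as.integer(meta$nSamples[r]))
  }
  pdds
}

#' Extract training samples for labelled voxels
#'
#' Collects the 4-channel feature vectors (p, q, T2n, PDn) of every
#' labelled voxel, grouped by tissue class.
#'
#' @param volume A [MultimodalVolume-class] with the classifier channels.
#' @param labels A [LabelVolume-class] on the same grid.
#' @return Named list, tissue class -> n x 4 matrix.
#' @export
extractClassSamples <- function(volume, labels) {
  stopifnot(identical(gridShape(volume), gridShape(labels)))
  feats <- cbind(p = as.numeric(getChannel(volume, "p")),
                 q = as.numeric(getChannel(volume, "q")),
                 T2n = as.numeric(getChannel(volume, "T2n")),
                 PDn = as.numeric(getChannel(volume, "PDn")))
  lab <- as.integer(labels@labels)
  out <- list()
  for (v in sort(unique(lab[lab != 0]))) {
    cls <- labels@classMap[[as.character(v)]]
    out[[cls]] <- feats[lab == v, , drop = FALSE]
  }
  out
}
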