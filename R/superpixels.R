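#' Per-slice SLIC superpixel segmentation
#'
#' Runs SLIC clustering independently on each axial slice using the PDn,
#' FLAIR and p channels (FLAIR separates CSF from oedema; q is excluded
#' because of its white-matter heterogeneity). Each channel is rescaled to
#' [0, 1] by its volume-wide 1-99 percentile range, each slice is
#' upsampled in-plane by `upsampleFactor` (nearest neighbour) before
#' clustering — mirroring clustering on a 1024 x 1024 matrix from a
#' 256 x 256 acquisition — and labels are mapped back to the native grid
#' by block majority vote. Superpixel ids are unique across slices.
#'
#' @param volume A [MultimodalVolume-class] with channels PDn, FLAIR, p.
#' @param brainMask Logical 3D array (default: all voxels).
#' @param gridSize SLIC grid size in upsampled pixels (default 30).
#' @param regularisation SLIC compactness parameter (default 0.2).
#' @param upsampleFactor Integer in-plane upsampling factor (default 4).
#' @param maxIter SLIC iterations (default 10).
#' @return 3D integer array of superpixel labels (0 outside the mask).
#' @export
computeSuperpixels <- function(volume, brainMask = NULL, gridSize = 30,
                               regularisation = 0.2, upsampleFactor = 4,
                               maxIter = 10) {
  need <- c("PDn", "FLAIR", "p")
  miss <- setdiff(need, channelNames(volume))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  shape <- gridShape(volume)
  if (is.null(brainMask)) brainMask <- array(TRUE, shape)
  chans <- lapply(need, function(nm)
    .percentileRescale(getChannel(volume, nm)))
  f <- as.integer(upsampleFactor)
  labels <- array(0L, shape)
  offset <- 0L
  for (z in seq_len(shape[3])) {
    m <- brainMask[, , z]
    if (!any(m)) next
    up <- lapply(chans, function(ch) .upsample2d(ch[, , z], f))
    upMask <- .upsample2d(m, f)
    H <- nrow(upMask); W <- ncol(upMask)
    img <- array(unlist(up), c(H, W, 3))
    sl <- slic_slice(as.numeric(img), H, W, 3L, upMask,
                     as.integer(gridSize), regularisation,
                     as.integer(maxIter))
    native <- block_majority(sl, f)
    native[!m] <- 0L
    pos <- native > 0L
    native[pos] <- native[pos] + offset
    if (any(pos)) offset <- max(native)
    labels[, , z] <- native
  }
  labels
}

#' Average posterior probabilities within superpixels
#'
#' For each superpixel the member voxels' posterior vectors are averaged
#' and the mean is renormalised to unit sum.
#'
#' @param posterior A [PosteriorMap-class].
#' @param labels 3D integer superpixel label array from
#'   [computeSuperpixels()].
#' @return A [SuperpixelMap-class].
#' @export
averageProbabilities <- function(posterior, labels) {
  shape <- gridShape(posterior)
  if (!identical(dim(labels), shape)) stop("label shape mismatch")
  inMask <- labels > 0
  idx <- which(inMask)
  ids <- labels[idx]
  nvox <- prod(shape)
  P <- vapply(1:7, function(k) posterior@probs[idx + (k - 1) * nvox],
              numeric(length(idx)))
  sums <- rowsum(P, group = ids)
  size <- as.integer(tabulate(factor(ids, levels = rownames(sums))))
  if (any(size == 0)) stop("empty superpixel id")
  means <- sums / size
  means <- means / rowSums(means)
  names(size) <- rownames(sums)
  colnames(means) <- tissueClasses()
  new("SuperpixelMap", labels = labels, spProbs = means, spSize = size,
      classOrder = tissueClasses())
}

#' Automatic lesion extraction
#'
#' Marks every superpixel whose abnormal-tissue probability
#' p(VO) + p(GII) + p(GIV) + p(Ne) strictly exceeds 0.5 and keeps the
#' largest 3D-connected component of the marked voxels (26-connectivity;
#' superpixels are in-slice connected so components are unions of whole
#' superpixels). Volume is reported in millilitres.
#'
#' @param spmap A [SuperpixelMap-class].
#' @param voxelSize Voxel dimensions in mm.
#' @param threshold Abnormality threshold (default 0.5, strict >).
#' @return A [LesionSegmentation-class]; empty if no superpixel passes.
#' @export
extractLesion <- function(spmap, voxelSize, threshold = 0.5) {
  abn <- rowSums(spmap@spProbs[, tissueIndex(c("VO", "GII", "GIV", "Ne")),
                               drop = FALSE])
  hot <- as.integer(rownames(spmap@spProbs))[abn > threshold]
  shape <- dim(spmap@labels)
  mask <- array(spmap@labels %in% hot, shape)
  if (!any(mask))
    return(new("LesionSegmentation", lesionMask = mask,
               componentCountConsidered = 0L, lesionVolumeMl = 0))
  comp <- label_components_26(as.logical(mask), shape[1], shape[2], shape[3])
  ncomp <- attr(comp, "ncomp")
  sizes <- tabulate(comp[comp > 0], nbins = ncomp)
  keep <- which.max(sizes)
  lesion <- array(comp == keep, shape)
  vol <- sum(lesion) * prod(voxelSize) / 1000
  new("LesionSegmentation", lesionMask = lesion,
      componentCountConsidered = as.integer(ncomp), lesionVolumeMl = vol)
}

#' Render the nosologic RGB tissue-type colour map
#'
#' Within the lesion each superpixel gets raw colour
#' (R, G, B) = (p(GIV), p(GII), p(Ne)); non-zero raw colours are
#' normalised to unit length and intensity-modulated by the tumour-tissue
#' probability p(GII) + p(GIV) + p(Ne), then clipped to [0, 1]. The
#' modulation makes pure vasogenic oedema black; everything outside the
#' lesion mask is black.
#'
#' @param spmap A [SuperpixelMap-class].
#' @param lesion A [LesionSegmentation-class].
#' @return A [TissueColourMap-class].
#' @export
renderColourMap <- function(spmap, lesion) {
  shape <- dim(spmap@labels)
  rgb <- array(0, c(shape, 3))
  ids <- as.integer(rownames(spmap@spProbs))
  inLesion <- spmap@labels > 0 & lesion@lesionMask
  if (any(inLesion)) {
    raw <- spmap@spProbs[, tissueIndex(c("GIV", "GII", "Ne")), drop = FALSE]
    nrm <- sqrt(rowSums(raw^2))
    mod <- rowSums(raw)  # p(GII) + p(GIV) + p(Ne)
    col <- raw
    pos <- nrm > 0
    col[pos, ] <- raw[pos, , drop = FALSE] / nrm[pos] * mod[pos]
    col[!pos, ] <- 0
    col[col > 1] <- 1
    lut <- matrix(0, max(ids), 3)
    lut[ids, ] <- col
    idxVox <- which(inLesion)
    lab <- spmap@labels[idxVox]
    nvox <- prod(shape)
    for (k in 1:3) rgb[idxVox + (k - 1) * nvox] <- lut[lab, k]
  }
  new("TissueColourMap", rgb = rgb)
}

#' High-grade tumour volume at a posterior threshold
#'
#' Total volume (ml) of lesion superpixels whose averaged p(GIV) strictly
#' exceeds the threshold.
#'
#' @param spmap A [SuperpixelMap-class].
#' @param lesion A [LesionSegmentation-class].
#' @param voxelSize Voxel dimensions in mm.
#' @param threshold Probability threshold (default 0.5, strict >).
#' @return Volume in millilitres.
#' @export
highGradeVolume <- function(spmap, lesion, voxelSize, threshold = 0.5) {
  ids <- as.integer(rownames(spmap@spProbs))
  giv <- spmap@spProbs[, tissueIndex("GIV")]
  # lesion membership per superpixel (lesion is a union of whole superpixels)
  lesionIds <- unique(spmap@labels[lesion@lesionMask & spmap@labels > 0])
  hot <- ids[giv > threshold & ids %in% lesionIds]
  sum(spmap@spSize[as.character(hot)]) * prod(voxelSize) / 1000
}

#' Per-superpixel summary table
#'
#' @param spmap A [SuperpixelMap-class].
#' @param lesion Optional [LesionSegmentation-class] to flag lesion
#'   membership.
#' @return Data frame with id, size, the 7 class probabilities and a
#'   lesion flag.
#' @export
superpixelTable <- function(spmap, lesion = NULL) {
  ids <- as.integer(rownames(spmap@spProbs))
  df <- data.frame(id = ids, size = as.integer(spmap@spSize))
  probs <- as.data.frame(spmap@spProbs)
  names(probs) <- paste0("p_", tissueClasses())
  df <- cbind(df, probs)
  if (!is.null(lesion)) {
    lesionIds <- unique(spmap@labels[lesion@lesionMask & spmap@labels > 0])
    df$lesion <- ids %in% lesionIds
  }
  rownames(df) <- NULL
  df
}
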