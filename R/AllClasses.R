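#' @useDynLib gliotype, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats quantile rnorm optim cor.test sd runif
#' @importFrom utils head read.table write.table
NULL

.CHANNELS <- c("p", "q", "T2w", "PDw", "T2n", "PDn", "FLAIR")

#' The seven tissue classes, in their fixed order
#'
#' The classifier works over seven tissue classes with a stable ordering
#' used everywhere a probability vector or a class axis appears:
#' GM (grey matter), WM (white matter), CSF (cerebrospinal fluid),
#' VO (vasogenic oedema), GII (grade II glioma), GIV (grade IV glioma),
#' Ne (necrosis). Label volumes encode class k as integer k in this order.
#'
#' @return Character vector of the 7 class names in canonical order.
#' @export
#' @examples
#' tissueClasses()
tissueClasses <- function() c("GM", "WM", "CSF", "VO", "GII", "GIV", "Ne")

#' Index of a tissue class in the canonical ordering
#'
#' @param name Character vector of class names (see [tissueClasses()]).
#' @return Integer indices (1-7).
#' @export
tissueIndex <- function(name) {
  idx <- match(name, tissueClasses())
  if (anyNA(idx)) stop("unknown tissue class: ",
                       paste(name[is.na(idx)], collapse = ", "))
  idx
}

#' MultimodalVolume: aligned stack of named 3D channels
#'
#' Holds co-registered scalar 3D volumes on one voxel grid. Channel names
#' are drawn from p, q, T2w, PDw, T2n, PDn, FLAIR; p and q are diffusivity
#' magnitudes in mm^2/s and must be non-negative. Volumes are indexed
#' (x, y, z) with z the slice axis used for per-slice superpixels.
#'
#' @slot channels Named list of 3D numeric arrays, all of identical dim.
#' @slot voxelSize Numeric length-3, mm per axis.
#' @exportClass MultimodalVolume
setClass("MultimodalVolume",
  representation(channels = "list", voxelSize = "numeric"),
  validity = function(object) {
    ch <- object@channels
    if (length(ch) == 0) return("no channels")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
      return("channels must be named")
    bad <- setdiff(names(ch), .CHANNELS)
    if (length(bad))
      return(paste0("unknown channel(s): ", paste(bad, collapse = ", ")))
    d <- dim(ch[[1]])
    if (length(d) != 3) return("channels must be 3D arrays")
    for (nm in names(ch)) {
      if (!identical(dim(ch[[nm]]), d))
        return(paste0("channel '", nm, "' has mismatched shape"))
    }
    if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive mm values")
    for (nm in intersect(c("p", "q"), names(ch))) {
      if (any(ch[[nm]] < 0, na.rm = TRUE))
        return(paste0("diffusivity channel '", nm, "' has negative values"))
    }
    TRUE
  })

#' Construct a MultimodalVolume
#'
#' @param channels Named list of 3D arrays on one grid.
#' @param voxelSize Numeric length-3 voxel dimensions in mm.
#' @return A [MultimodalVolume-class] object.
#' @export
multimodalVolume <- function(channels, voxelSize) {
  new("MultimodalVolume", channels = channels,
      voxelSize = as.numeric(voxelSize))
}

#' LabelVolume: integer tissue-class labels on an image grid
#'
#' @slot labels 3D integer array; 0 = unlabelled, k > 0 = class index.
#' @slot classMap Named character vector mapping label value (as name)
#'   to tissue class name.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", classMap = "character"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3) return("labels must be 3D")
    vals <- unique(as.integer(object@labels))
    vals <- vals[vals != 0]
    if (length(vals)) {
      missing <- setdiff(as.character(vals), names(object@classMap))
      if (length(missing))
        return(paste0("label(s) without classMap entry: ",
                      paste(missing, collapse = ", ")))
    }
    bad <- setdiff(object@classMap, tissueClasses())
    if (length(bad))
      return(paste0("classMap targets unknown class: ",
                    paste(bad, collapse = ", ")))
    TRUE
  })

#' Construct a LabelVolume
#'
#' @param labels 3D integer array (0 = unlabelled).
#' @param classMap Named character vector, names are label values as
#'   character, values are tissue class names. Defaults to the canonical
#'   1..7 mapping of [tissueClasses()].
#' @return A [LabelVolume-class] object.
#' @export
labelVolume <- function(labels,
                        classMap = structure(tissueClasses(),
                                             names = as.character(1:7))) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, classMap = classMap)
}

#' ReferenceHistogram for intensity normalisation
#'
#' @slot binEdges Monotone increasing numeric vector of bin edges.
#' @slot counts Non-negative numeric vector, length(binEdges) - 1.
#' @slot sourceId Free-text provenance tag.
#' @exportClass ReferenceHistogram
setClass("ReferenceHistogram",
  representation(binEdges = "numeric", counts = "numeric",
                 sourceId = "character"),
  validity = function(object) {
    if (length(object@counts) != length(object@binEdges) - 1)
      return("counts length must equal length(binEdges) - 1")
    if (any(diff(object@binEdges) <= 0))
      return("binEdges must be strictly increasing")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
  })

#' BinGrid4D: shared 4D bin-edge set over (p, q, T2n, PDn)
#'
#' One global bin grid is shared by all class histograms so that
#' cross-class likelihood ratios compare densities at the same point.
#'
#' @slot edges Named list of 4 strictly increasing numeric vectors
#'   (p, q, T2n, PDn), each of length bins + 1.
#' @slot bins Integer number of bins per axis (default pipeline value 50).
#' @exportClass BinGrid4D
setClass("BinGrid4D",
  representation(edges = "list", bins = "integer"),
  validity = function(object) {
    if (!identical(names(object@edges), c("p", "q", "T2n", "PDn")))
      return("edges must be named p, q, T2n, PDn in order")
    for (e in object@edges) {
      if (length(e) != object@bins + 1L)
        return("each edge vector must have bins + 1 entries")
      if (any(diff(e) <= 0)) return("edges must be strictly increasing")
    }
    TRUE
  })

#' PDD4D: per-class 4D probability density histogram
#'
#' A non-parametric class-conditional likelihood p(X | C): counts over the
#' shared 4D grid divided by n * bin hypervolume, so the density integrates
#' to 1 over the grid.
#'
#' @slot tissue Tissue class name.
#' @slot grid The shared [BinGrid4D-class].
#' @slot density 4D non-negative array (bins^4).
#' @slot nSamples Number of training samples.
#' @exportClass PDD4D
setClass("PDD4D",
  representation(tissue = "character", grid = "BinGrid4D",
                 density = "array", nSamples = "integer"),
  validity = function(object) {
    b <- object@grid@bins
    if (!identical(dim(object@density), rep(b, 4L)))
      return("density must be a bins^4 array")
    if (any(object@density < 0)) return("density must be non-negative")
    integral <- sum(object@density * .binHypervolume(object@grid))
    if (abs(integral - 1) > 1e-9 && object@nSamples > 0)
      return(sprintf("density integral is %.12f, not 1", integral))
    TRUE
  })

#' PosteriorMap: voxelwise posterior probabilities over the 7 classes
#'
#' @slot probs 4D array (x, y, z, class); rows sum to 1 at in-mask voxels,
#'   are all-zero outside the brain mask.
#' @slot outOfSupport 3D logical array, TRUE exactly where all seven class
#'   densities are zero (the posterior there is the uniform 1/7 vector).
#' @slot classOrder Character vector, the canonical class ordering.
#' @slot voxelSize Numeric length-3 voxel dimensions in mm.
#' @exportClass PosteriorMap
setClass("PosteriorMap",
  representation(probs = "array", outOfSupport = "array",
                 classOrder = "character", voxelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@probs)
    if (length(d) != 4 || d[4] != 7) return("probs must be (x, y, z, 7)")
    if (!identical(dim(object@outOfSupport), d[1:3]))
      return("outOfSupport shape mismatch")
    if (!identical(object@classOrder, tissueClasses()))
      return("classOrder must be the canonical tissue ordering")
    TRUE
  })

#' SuperpixelMap: per-slice superpixel labels with averaged probabilities
#'
#' @slot labels 3D integer array of superpixel ids, unique across slices;
#'   0 outside the brain mask.
#' @slot spProbs Numeric matrix (n superpixels x 7); each row is the mean
#'   posterior over member voxels, renormalised to unit sum. Rownames are
#'   superpixel ids.
#' @slot spSize Integer vector of member-voxel counts, names are ids.
#' @slot classOrder Canonical class ordering.
#' @exportClass SuperpixelMap
setClass("SuperpixelMap",
  representation(labels = "array", spProbs = "matrix", spSize = "integer",
                 classOrder = "character"),
  validity = function(object) {
    if (ncol(object@spProbs) != 7) return("spProbs must have 7 columns")
    if (nrow(object@spProbs) != length(object@spSize))
      return("spProbs/spSize length mismatch")
    s <- rowSums(object@spProbs)
    if (length(s) && any(abs(s - 1) > 1e-6))
      return("each spProbs row must sum to 1")
    TRUE
  })

#' LesionSegmentation: automatically extracted whole-lesion mask
#'
#' @slot lesionMask 3D logical array; union of whole superpixels forming
#'   the largest 3D-connected abnormal component.
#' @slot componentCountConsidered Number of connected components among
#'   abnormal superpixels before keeping the largest.
#' @slot lesionVolumeMl Lesion volume in millilitres.
#' @exportClass LesionSegmentation
setClass("LesionSegmentation",
  representation(lesionMask = "array", componentCountConsidered = "integer",
                 lesionVolumeMl = "numeric"))

#' TissueColourMap: nosologic RGB rendering of the lesion
#'
#' @slot rgb 4D numeric array (x, y, z, 3) in [0, 1]; zero outside the
#'   lesion mask.
#' @exportClass TissueColourMap
setClass("TissueColourMap",
  representation(rgb = "array"),
  validity = function(object) {
    d <- dim(object@rgb)
    if (length(d) != 4 || d[4] != 3) return("rgb must be (x, y, z, 3)")
    if (min(object@rgb) < 0 || max(object@rgb) > 1)
      return("rgb values must lie in [0, 1]")
    TRUE
  })

#' MRSIGeometry: mapping from an MRSI grid to image-voxel blocks
#'
#' Each MRSI voxel (gi, gj) covers the image-voxel block starting at
#' originVox and extending blockSize voxels along x, y and z (MRSI slabs
#' may span several image slices).
#'
#' @slot originVox Integer length-3, image-voxel (x, y, z) of the first
#'   block's corner (1-based).
#' @slot blockSize Integer length-3, block extent in voxels per axis.
#' @slot gridDim Integer length-2, MRSI grid size (ni, nj).
#' @exportClass MRSIGeometry
setClass("MRSIGeometry",
  representation(originVox = "integer", blockSize = "integer",
                 gridDim = "integer"),
  validity = function(object) {
    if (length(object@originVox) != 3 || any(object@originVox < 1))
      return("originVox must be 3 positive indices")
    if (length(object@blockSize) != 3 || any(object@blockSize < 1))
      return("blockSize must be 3 positive extents")
    if (length(object@gridDim) != 2 || any(object@gridDim < 1))
      return("gridDim must be 2 positive extents")
    TRUE
  })

#' Construct an MRSIGeometry
#'
#' @param originVox Image-voxel (x, y, z) of the grid corner, 1-based.
#' @param blockSize Block extent in image voxels per axis.
#' @param gridDim MRSI grid size (ni, nj).
#' @return An [MRSIGeometry-class] object.
#' @export
mrsiGeometry <- function(originVox, blockSize, gridDim) {
  new("MRSIGeometry", originVox = as.integer(originVox),
      blockSize = as.integer(blockSize), gridDim = as.integer(gridDim))
}

# ---- accessors -------------------------------------------------------------

#' @rdname MultimodalVolume-class
#' @param object,x A MultimodalVolume.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname MultimodalVolume-class
#' @export
setMethod("channelNames", "MultimodalVolume", function(x) names(x@channels))

#' @rdname MultimodalVolume-class
#' @param name Channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname MultimodalVolume-class
#' @export
setMethod("getChannel", "MultimodalVolume", function(x, name) {
  if (!name %in% names(x@channels)) stop("no channel '", name, "'")
  x@channels[[name]]
})

#' Voxel dimensions in mm
#' @param x An object with a voxel grid.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "MultimodalVolume", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PosteriorMap", function(x) x@voxelSize)

#' Grid shape in voxels
#' @param x An object with a voxel grid.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname gridShape
#' @export
setMethod("gridShape", "MultimodalVolume", function(x) dim(x@channels[[1]]))

#' @rdname gridShape
#' @export
setMethod("gridShape", "LabelVolume", function(x) dim(x@labels))

#' @rdname gridShape
#' @export
setMethod("gridShape", "PosteriorMap", function(x) dim(x@probs)[1:3])

#' Posterior probability array accessor
#' @param x A PosteriorMap.
#' @export
posteriorArray <- function(x) {
  stopifnot(is(x, "PosteriorMap"))
  x@probs
}

#' Superpixel probability table accessor
#' @param x A SuperpixelMap.
#' @return Matrix of per-superpixel renormalised mean probabilities,
#'   one row per superpixel id (rownames), 7 class columns.
#' @export
superpixelProbs <- function(x) {
  stopifnot(is(x, "SuperpixelMap"))
  x@spProbs
}

#' Superpixel label array accessor
#' @param x A SuperpixelMap.
#' @export
superpixelLabels <- function(x) {
  stopifnot(is(x, "SuperpixelMap"))
  x@labels
}

#' Superpixel size accessor
#' @param x A SuperpixelMap.
#' @export
superpixelSizes <- function(x) {
  stopifnot(is(x, "SuperpixelMap"))
  x@spSize
}

#' Lesion mask accessor
#' @param x A LesionSegmentation.
#' @export
lesionMask <- function(x) {
  stopifnot(is(x, "LesionSegmentation"))
  x@lesionMask
}

#' Lesion volume in millilitres
#' @param x A LesionSegmentation.
#' @export
lesionVolumeMl <- function(x) {
  stopifnot(is(x, "LesionSegmentation"))
  x@lesionVolumeMl
}

#' Colour array accessor
#' @param x A TissueColourMap.
#' @export
colourArray <- function(x) {
  stopifnot(is(x, "TissueColourMap"))
  x@rgb
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "MultimodalVolume", function(object) {
  d <- dim(object@channels[[1]])
  cat("MultimodalVolume:", paste(d, collapse = " x "), "voxels,",
      paste(sprintf("%.3g", object@voxelSize), collapse = " x "), "mm\n")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "LabelVolume", function(object) {
  tab <- table(factor(object@labels[object@labels != 0],
                      levels = names(object@classMap)))
  cat("LabelVolume:", paste(dim(object@labels), collapse = " x "), "\n")
  for (k in names(object@classMap))
    if (tab[k] > 0)
      cat(sprintf("  %s (%s): %d voxels\n", object@classMap[[k]], k, tab[k]))
})

setMethod("show", "PDD4D", function(object) {
  cat(sprintf("PDD4D [%s]: %d^4 bins, %d training samples, %d occupied\n",
              object@tissue, object@grid@bins, object@nSamples,
              sum(object@density > 0)))
})

setMethod("show", "PosteriorMap", function(object) {
  cat("PosteriorMap:", paste(dim(object@probs)[1:3], collapse = " x "),
      "voxels over", paste(object@classOrder, collapse = "/"), "\n")
  cat("  out-of-support voxels:", sum(object@outOfSupport), "\n")
})

setMethod("show", "SuperpixelMap", function(object) {
  cat("SuperpixelMap:", nrow(object@spProbs), "superpixels,",
      "median size", stats::median(object@spSize), "voxels\n")
})

setMethod("show", "LesionSegmentation", function(object) {
  cat(sprintf("LesionSegmentation: %.2f ml (%d voxels), %d component(s) considered\n",
              object@lesionVolumeMl, sum(object@lesionMask),
              object@componentCountConsidered))
})
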