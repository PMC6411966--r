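#' Load co-registered multimodal NIfTI channels
#'
#' Reads one NIfTI file per channel and assembles them into a
#' [MultimodalVolume-class]. Inputs must already be co-registered and
#' resliced onto one grid: the loader validates that every channel has the
#' same shape and voxel dimensions and fails rather than resampling,
#' naming the offending channel.
#'
#' @param paths Named character vector or list, channel name -> NIfTI path.
#'   Channel names must come from p, q, T2w, PDw, T2n, PDn, FLAIR.
#' @param tol Relative tolerance for voxel-size agreement (default 1e-4).
#' @return A [MultimodalVolume-class].
#' @export
#' @examples
#' \dontrun{
#' vol <- loadMultimodal(c(p = "p.nii.gz", q = "q.nii.gz",
#'                         T2n = "t2n.nii.gz", PDn = "pdn.nii.gz"))
#' }
loadMultimodal <- function(paths, tol = 1e-4) {
  paths <- unlist(paths)
  if (is.null(names(paths))) stop("paths must be named by channel")
  channels <- list()
  refDim <- NULL; refVox <- NULL; refName <- NULL
  for (nm in names(paths)) {
    img <- RNifti::readNifti(paths[[nm]])
    arr <- array(as.array(img), dim(img))
    if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
    if (length(dim(arr)) != 3)
      stop("channel '", nm, "' is not a 3D volume")
    vox <- RNifti::pixdim(img)[1:3]
    if (is.null(refDim)) {
      refDim <- dim(arr); refVox <- vox; refName <- nm
    } else {
      if (!identical(dim(arr), refDim))
        stop("alignment error: channel '", nm, "' shape (",
             paste(dim(arr), collapse = "x"), ") differs from '", refName,
             "' (", paste(refDim, collapse = "x"), ")")
      if (any(abs(vox - refVox) > tol * refVox))
        stop("alignment error: channel '", nm,
             "' voxel size differs from '", refName, "'")
    }
    channels[[nm]] <- arr
  }
  multimodalVolume(channels, refVox)
}

#' Load an integer label volume
#'
#' @param path NIfTI path of an integer-valued volume (0 = unlabelled).
#' @param classMap Named character vector mapping label values to tissue
#'   class names; defaults to the canonical 1..7 ordering.
#' @return A [LabelVolume-class].
#' @export
loadLabels <- function(path,
                       classMap = structure(tissueClasses(),
                                            names = as.character(1:7))) {
  img <- RNifti::readNifti(path)
  arr <- array(as.array(img), dim(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop("label volume must be 3D")
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("label volume is not integer-valued")
  labelVolume(array(as.integer(round(arr)), dim(arr)), classMap)
}

#' Write a 3D array or a MultimodalVolume channel set to NIfTI
#'
#' @param x A 3D numeric array, a [MultimodalVolume-class] or a
#'   [LabelVolume-class].
#' @param path Output path for an array/LabelVolume, or a directory for a
#'   MultimodalVolume (one `<channel>.nii.gz` per channel).
#' @param voxelSize Voxel dimensions in mm (taken from the object where it
#'   carries them).
#' @return Invisibly, the path(s) written.
#' @export
writeVolume <- function(x, path, voxelSize = c(1, 1, 1)) {
  writeOne <- function(arr, vox, p) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- vox
    RNifti::writeNifti(img, p)
    p
  }
  if (is(x, "MultimodalVolume")) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    out <- vapply(channelNames(x), function(nm) {
      writeOne(getChannel(x, nm), voxelSize(x),
               file.path(path, paste0(nm, ".nii.gz")))
    }, character(1))
    return(invisible(out))
  }
  if (is(x, "LabelVolume")) x <- x@labels
  invisible(writeOne(x, voxelSize, path))
}

#' Write a PosteriorMap as NIfTI
#'
#' The probability array is written as one 4D NIfTI whose 4th dimension
#' follows the canonical class order (GM, WM, CSF, VO, GII, GIV, Ne); the
#' out-of-support mask is written alongside as `<stem>_oos.nii.gz`.
#'
#' @param x A [PosteriorMap-class].
#' @param path Output NIfTI path (the mask path is derived from it).
#' @return Invisibly, the two paths written.
#' @export
writePosteriorMap <- function(x, path) {
  img <- RNifti::asNifti(x@probs)
  RNifti::pixdim(img) <- c(x@voxelSize, 1)
  RNifti::writeNifti(img, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oos <- file.path(paste0(stem, "_oos.nii.gz"))
  mimg <- RNifti::asNifti(array(as.integer(x@outOfSupport),
                                dim(x@outOfSupport)))
  RNifti::pixdim(mimg) <- x@voxelSize
  RNifti::writeNifti(mimg, oos)
  invisible(c(path, oos))
}

#' Read a PosteriorMap written by [writePosteriorMap()]
#'
#' @param path NIfTI path of the 4D probability volume.
#' @return A [PosteriorMap-class].
#' @export
readPosteriorMap <- function(path) {
  img <- RNifti::readNifti(path)
  probs <- array(as.array(img), dim(img))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  oos <- as.array(RNifti::readNifti(paste0(stem, "_oos.nii.gz"))) > 0.5
  new("PosteriorMap", probs = probs, outOfSupport = array(oos, dim(probs)[1:3]),
      classOrder = tissueClasses(), voxelSize = RNifti::pixdim(img)[1:3])
}
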