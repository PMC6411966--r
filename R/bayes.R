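#' Posterior tissue probabilities from class likelihoods
#'
#' Implements the two-step Bayesian rule of the method: the prior of class
#' i is its likelihood normalised over classes, P(Ci) = L_i / sum_j L_j,
#' and the posterior is P(Ci | X) = P(Ci) L_i / sum_j P(Cj) L_j — so the
#' posterior is proportional to the squared likelihood. With `prior =
#' "flat"` the posterior is instead proportional to the likelihood itself
#' (sensitivity analysis). When every likelihood is zero the vector is out
#' of support and the uniform 1/7 posterior is returned.
#'
#' @param likelihoods Non-negative 7-vector of class densities p(X | Ci),
#'   or an n x 7 matrix (one row per voxel).
#' @param prior "density" (default, the method's rule) or "flat".
#' @return For a vector input, a 7-vector summing to 1 with attribute
#'   `outOfSupport`; for a matrix, an n x 7 matrix with an
#'   `outOfSupport` logical attribute of length n.
#' @export
#' @examples
#' posteriorVector(c(0.2, 0.3, 0.5, 0, 0, 0, 0))
#' # (0.04, 0.09, 0.25)/0.38
posteriorVector <- function(likelihoods, prior = c("density", "flat")) {
  prior <- match.arg(prior)
  vec <- is.null(dim(likelihoods))
  L <- if (vec) matrix(likelihoods, nrow = 1) else likelihoods
  if (ncol(L) != 7) stop("likelihoods must have 7 classes")
  if (any(L < 0)) stop("negative likelihood")
  W <- if (prior == "density") L * L else L
  s <- rowSums(W)
  oos <- rowSums(L) == 0
  s[oos] <- 1
  post <- W / s
  post[oos, ] <- 1 / 7
  if (vec) {
    post <- as.numeric(post)
    attr(post, "outOfSupport") <- oos[1]
  } else {
    attr(post, "outOfSupport") <- oos
  }
  post
}

#' Classify every brain voxel into tissue-type posteriors
#'
#' Evaluates the seven class histogram densities at each in-mask voxel's
#' feature vector (p, q, T2n, PDn) and converts them to posteriors with
#' [posteriorVector()]. Voxels outside the brain mask carry zero
#' probability; voxels whose feature vector falls in a bin empty for all
#' classes get the uniform posterior and are flagged out-of-support.
#'
#' @param volume A [MultimodalVolume-class] with channels p, q, T2n, PDn.
#' @param pdds Named list of 7 [PDD4D-class] (one per tissue class), all
#'   sharing one bin grid.
#' @param brainMask Logical 3D array (default: all voxels).
#' @param prior Passed to [posteriorVector()].
#' @return A [PosteriorMap-class].
#' @export
classifyVolume <- function(volume, pdds, brainMask = NULL,
                           prior = c("density", "flat")) {
  prior <- match.arg(prior)
  classes <- tissueClasses()
  if (!all(classes %in% names(pdds)))
    stop("pdds must contain all 7 classes")
  grid <- pdds[[classes[1]]]@grid
  for (cl in classes)
    if (!identical(pdds[[cl]]@grid@edges, grid@edges))
      stop("PDD grid mismatch for class ", cl)
  shape <- gridShape(volume)
  if (is.null(brainMask)) brainMask <- array(TRUE, shape)
  stopifnot(identical(dim(brainMask), shape))

  idxMask <- which(brainMask)
  X <- cbind(p = as.numeric(getChannel(volume, "p"))[idxMask],
             q = as.numeric(getChannel(volume, "q"))[idxMask],
             T2n = as.numeric(getChannel(volume, "T2n"))[idxMask],
             PDn = as.numeric(getChannel(volume, "PDn"))[idxMask])
  lin <- .linearIndex4(.binIndex4(X, grid), grid@bins)
  L <- matrix(0, length(idxMask), 7)
  for (k in seq_along(classes))
    L[, k] <- as.numeric(pdds[[classes[k]]]@density)[lin]
  post <- posteriorVector(L, prior = prior)
  oosMask <- attr(post, "outOfSupport")

  probs <- array(0, c(shape, 7))
  nvox <- prod(shape)
  for (k in 1:7) probs[idxMask + (k - 1) * nvox] <- post[, k]
  oos <- array(FALSE, shape)
  oos[idxMask] <- oosMask
  new("PosteriorMap", probs = probs, outOfSupport = oos,
      classOrder = classes, voxelSize = voxelSize(volume))
}
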