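#' Resample a posterior map to the MRSI grid
#'
#' Block-averages the 7 posterior probabilities over the image-voxel block
#' of each MRSI voxel.
#'
#' @param posterior A [PosteriorMap-class].
#' @param geometry An [MRSIGeometry-class].
#' @return Matrix (ni * nj) x 7 of block-mean probabilities with columns
#'   in canonical class order and extra columns `i`, `j` as attributes
#'   `grid` (a data frame of MRSI indices, row-aligned).
#' @export
resampleToMRSI <- function(posterior, geometry) {
  shape <- gridShape(posterior)
  nd <- geometry@gridDim
  out <- matrix(0, prod(nd), 7)
  colnames(out) <- tissueClasses()
  gridIdx <- data.frame(i = integer(prod(nd)), j = integer(prod(nd)))
  r <- 0L
  for (gj in seq_len(nd[2])) {
    for (gi in seq_len(nd[1])) {
      r <- r + 1L
      blk <- .mrsiBlock(geometry, gi, gj, shape)
      sub <- posterior@probs[blk$xs, blk$ys, blk$zs, , drop = FALSE]
      out[r, ] <- apply(sub, 4, mean)
      gridIdx$i[r] <- gi; gridIdx$j[r] <- gj
    }
  }
  attr(out, "grid") <- gridIdx
  out
}

#' Group 7-class probabilities into normal / low-grade / high-grade
#'
#' Maps a 7-column probability matrix to the three-component summary used
#' for MRSI comparison: normal = p(GM) + p(WM) + p(CSF) + p(VO),
#' low-grade = p(GII), high-grade = p(GIV) + p(Ne).
#'
#' @param probs Matrix with 7 columns in canonical class order.
#' @return Matrix with columns normal, low_grade, high_grade.
#' @export
groupTissueFractions <- function(probs) {
  probs <- matrix(probs, ncol = 7)
  cbind(normal = rowSums(probs[, tissueIndex(c("GM", "WM", "CSF", "VO")),
                               drop = FALSE]),
        low_grade = probs[, tissueIndex("GII")],
        high_grade = rowSums(probs[, tissueIndex(c("GIV", "Ne")),
                                   drop = FALSE]))
}

#' Sample distance correlation between two multivariate samples
#'
#' Székely's sample distance correlation computed from double-centred
#' pairwise Euclidean distance matrices (the biased sample form of the
#' original technique, not the bias-corrected variant). Symmetric in its
#' arguments, invariant under affine maps of either side, in [0, 1], and
#' zero in the population exactly under independence.
#'
#' @param xs n x p numeric matrix (or vector).
#' @param ys n x q numeric matrix (or vector), same n >= 2.
#' @return The sample distance correlation.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20)
#' distanceCorrelation(x, 2 * x + 1)  # exactly 1
distanceCorrelation <- function(xs, ys) {
  xs <- as.matrix(xs); ys <- as.matrix(ys)
  n <- nrow(xs)
  if (nrow(ys) != n) stop("sample sizes differ")
  if (n < 2) stop("need at least 2 observations")
  A <- .doubleCentre(as.matrix(stats::dist(xs)))
  B <- .doubleCentre(as.matrix(stats::dist(ys)))
  dvarX <- mean(A * A)
  dvarY <- mean(B * B)
  if (dvarX == 0 || dvarY == 0)
    stop("distance variance is zero (constant input)")
  dcov2 <- mean(A * B)
  sqrt(max(dcov2, 0) / sqrt(dvarX * dvarY))
}

.doubleCentre <- function(d) {
  rm <- rowMeans(d); gm <- mean(d)
  d - outer(rm, rm, "+") + gm
}

#' Overlap metrics between two segmentation masks
#'
#' Dice = 2|A∩B| / (|A| + |B|); Jaccard = |A∩B| / |A∪B|;
#' Overlap (Szymkiewicz-Simpson) = |A∩B| / min(|A|, |B|).
#'
#' @param a,b Logical arrays of identical shape, not both empty.
#' @return Named list (dice, jaccard, overlap).
#' @export
#' @examples
#' a <- c(rep(TRUE, 4), rep(FALSE, 4))
#' b <- c(FALSE, rep(TRUE, 6), FALSE)
#' overlapMetrics(a, b)  # dice 0.6, jaccard 3/7, overlap 0.75
overlapMetrics <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) stop("both masks are empty")
  inter <- sum(a & b)
  list(dice = 2 * inter / (na + nb),
       jaccard = inter / sum(a | b),
       overlap = inter / min(na, nb))
}

#' Manual-vs-automatic volume agreement
#'
#' Pearson correlation (two-sided test) between manually and automatically
#' measured volumes, with a Bland-Altman analysis of the systematic
#' difference (auto minus manual): mean difference and 95% limits of
#' agreement (mean ± 1.96 sd).
#'
#' @param manualMl,autoMl Numeric vectors of equal length >= 3, in ml.
#' @return Named list (pearsonR, pValue, meanDiff, loaLower, loaUpper).
#' @export
volumeAgreement <- function(manualMl, autoMl) {
  if (length(manualMl) != length(autoMl)) stop("length mismatch")
  if (length(manualMl) < 3) stop("need at least 3 paired volumes")
  if (sd(manualMl) == 0 || sd(autoMl) == 0) stop("zero variance")
  ct <- cor.test(manualMl, autoMl, alternative = "two.sided")
  d <- autoMl - manualMl
  m <- mean(d); s <- sd(d)
  list(pearsonR = unname(ct$estimate), pValue = ct$p.value,
       meanDiff = m, loaLower = m - 1.96 * s, loaUpper = m + 1.96 * s)
}

#' Read / write MRSI tissue-fraction tables
#'
#' CSV with columns i, j, fraction_normal, fraction_GII, fraction_GIV and
#' an optional logical `train` column flagging voxels used to build the
#' tumour PDDs (excluded from evaluation statistics).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
readMRSIFractions <- function(path) {
  df <- utils::read.csv(path)
  need <- c("i", "j", "fraction_normal", "fraction_GII", "fraction_GIV")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readMRSIFractions
#' @param fractions Data frame to write.
#' @export
writeMRSIFractions <- function(fractions, path) {
  utils::write.csv(fractions, path, row.names = FALSE)
  invisible(path)
}

#' MRSI-grid comparison of imaging and spectroscopy tissue fractions
#'
#' Resamples the posterior map to the MRSI grid, groups both sources into
#' (normal, low-grade, high-grade) triples and computes the distance
#' correlation between the two 3D spaces, with and without the PDD
#' training voxels.
#'
#' @param posterior A [PosteriorMap-class].
#' @param geometry An [MRSIGeometry-class].
#' @param fractions MRS fraction data frame (see [readMRSIFractions()]).
#' @return List with `dcorAll`, `dcorExcludingTraining` (NA when no train
#'   column or no voxel excluded), `nAll`, `nExcluded`.
#' @export
compareWithMRSI <- function(posterior, geometry, fractions) {
  imaging <- resampleToMRSI(posterior, geometry)
  gridIdx <- attr(imaging, "grid")
  key <- paste(gridIdx$i, gridIdx$j)
  rows <- match(paste(fractions$i, fractions$j), key)
  if (anyNA(rows)) stop("fractions reference MRSI voxels outside geometry")
  img3 <- groupTissueFractions(imaging[rows, , drop = FALSE])
  # drop MRSI voxels whose image block lies wholly outside the brain mask
  # (no posterior mass): they carry no imaging information
  supported <- rowSums(img3) > 0
  fractions <- fractions[supported, , drop = FALSE]
  img3 <- img3[supported, , drop = FALSE]
  img3 <- img3 / rowSums(img3)
  mrs3 <- as.matrix(fractions[, c("fraction_normal", "fraction_GII",
                                  "fraction_GIV")])
  dAll <- distanceCorrelation(img3, mrs3)
  dEx <- NA_real_; nEx <- 0L
  if (!is.null(fractions$train) && any(fractions$train)) {
    keep <- !fractions$train
    nEx <- sum(!keep)
    if (sum(keep) >= 2)
      dEx <- distanceCorrelation(img3[keep, , drop = FALSE],
                                 mrs3[keep, , drop = FALSE])
  }
  list(dcorAll = dAll, dcorExcludingTraining = dEx,
       nAll = nrow(mrs3), nExcluded = nEx)
}
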