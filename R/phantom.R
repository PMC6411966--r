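#' Specification of a synthetic multimodal brain phantom
#'
#' The phantom emulates a 7-class brain on a 256 x 256 x 16 grid of
#' 0.9375 x 0.9375 x 5 mm voxels (a typical clinical dual-echo / DTI
#' geometry): a WM ellipsoid with a GM outer shell and CSF ventricles,
#' plus a nested tumour — necrotic centre inside a GIV core inside a GII
#' rim, all wrapped in a vasogenic-oedema shell. Channel intensities are
#' drawn from per-class mixtures of location-scale (diagonal Gaussian)
#' components over the five channels (p, q, T2n, PDn, FLAIR): two
#' components for GII, GIV and Ne to emulate the multi-cluster,
#' non-Gaussian tumour histograms seen in patient data, one component for
#' GM/WM/CSF/VO. One necrosis component sits above the 4e-3 mm^2/s
#' isotropic-diffusivity threshold so the necrosis ROI rule is
#' exercisable. Raw T2w/PDw channels are emitted as known affine
#' distortions of T2n/PDn so the normalisation stage has real work to do.
#'
#' @param shape Grid shape in voxels (default c(256, 256, 16)).
#' @param voxelSize Voxel dimensions in mm (default c(0.9375, 0.9375, 5)).
#' @param geometry Named list of region parameters in mm; see Details.
#' @param classModels Named list of per-class mixtures; see
#'   [defaultClassModels()].
#' @param noiseSd Named per-channel additive noise SD (p and q in mm^2/s).
#' @param t2wMap,pdwMap True normalising affine (scale, shift) such that
#'   T2n = scale * T2w + shift; the emitted raw channels invert these.
#' @param seed Integer RNG seed.
#' @return A `phantomSpec` list.
#' @details Geometry entries (all mm): `brainSemiAxes`, `gmShellFraction`
#'   (GM occupies ellipsoidal radii above this fraction),
#'   `ventricleSemiAxes`, `ventricleOffsets` (2 x 3 matrix),
#'   `tumourOffset` (from brain centre), and per-region semi-axis triples
#'   `voRadii`, `giiRadii`, `givRadii`, `neRadii` (strictly nested
#'   Ne < GIV < GII < VO where non-zero; zero radii omit the region, e.g.
#'   a pure low-grade phantom has zero `givRadii`/`neRadii`).
#' @export
phantomSpec <- function(shape = c(256, 256, 16),
                        voxelSize = c(0.9375, 0.9375, 5),
                        geometry = list(),
                        classModels = defaultClassModels(),
                        noiseSd = c(p = 1e-5, q = 1e-5, T2n = 1, PDn = 1,
                                    FLAIR = 1),
                        t2wMap = c(scale = 0.8, shift = -10),
                        pdwMap = c(scale = 1.25, shift = 5),
                        seed = 1L) {
  geo <- list(
    brainSemiAxes = c(105, 105, 34),
    gmShellFraction = 0.88,
    ventricleSemiAxes = c(10, 28, 8),
    ventricleOffsets = rbind(c(-16, -5, 0), c(16, -5, 0)),
    tumourOffset = c(45, 30, 0),
    voRadii = c(32, 32, 20),
    giiRadii = c(24, 24, 15),
    givRadii = c(15, 15, 9),
    neRadii = c(8, 8, 5))
  geo[names(geometry)] <- geometry
  .checkNested <- function(inner, outer, what) {
    if (any(inner > 0) && any(inner >= outer))
      stop("phantom geometry not nested: ", what)
  }
  .checkNested(geo$neRadii, geo$givRadii, "Ne within GIV")
  .checkNested(geo$givRadii, geo$giiRadii, "GIV within GII")
  .checkNested(geo$giiRadii, geo$voRadii, "GII within VO")
  for (m in classModels)
    if (abs(sum(m$weights) - 1) > 1e-9)
      stop("mixture weights must sum to 1")
  structure(list(shape = as.integer(shape), voxelSize = voxelSize,
                 geometry = geo, classModels = classModels,
                 noiseSd = noiseSd, t2wMap = t2wMap, pdwMap = pdwMap,
                 seed = as.integer(seed)),
            class = "phantomSpec")
}

#' Default per-class intensity mixture models
#'
#' Channel means are loosely anchored to 1.5 T physiology: p and q in
#' mm^2/s (WM ~0.7e-3, CSF ~3e-3, necrosis partly above 4e-3), T2n/PDn/
#' FLAIR on the normalised 0-100 intensity scale, CSF dark on FLAIR.
#' GII, GIV and Ne are two-component mixtures; normal classes are single
#' Gaussians. All values are overridable via [phantomSpec()].
#'
#' @return Named list: per class, `weights`, `means` (k x 5, columns
#'   p, q, T2n, PDn, FLAIR) and `sds` (k x 5).
#' @export
defaultClassModels <- function() {
  ch <- c("p", "q", "T2n", "PDn", "FLAIR")
  comp <- function(w, m, s) {
    m <- matrix(unlist(m), ncol = 5, byrow = TRUE,
                dimnames = list(NULL, ch))
    s <- matrix(unlist(s), ncol = 5, byrow = TRUE,
                dimnames = list(NULL, ch))
    list(weights = w, means = m, sds = s)
  }
  sdN <- c(3e-5, 3e-5, 2, 2, 2)
  list(
    GM = comp(1, list(c(0.80e-3, 0.35e-3, 50, 65, 65)), list(sdN)),
    WM = comp(1, list(c(0.70e-3, 0.70e-3, 40, 55, 60)), list(sdN)),
    CSF = comp(1, list(c(3.00e-3, 0.25e-3, 95, 80, 10)),
               list(c(1.5e-4, 3e-5, 3, 3, 3))),
    VO = comp(1, list(c(1.50e-3, 0.45e-3, 75, 78, 85)), list(sdN)),
    GII = comp(c(0.6, 0.4),
               list(c(1.20e-3, 0.40e-3, 80, 85, 80),
                    c(1.35e-3, 0.55e-3, 72, 90, 82)),
               list(sdN, sdN)),
    GIV = comp(c(0.6, 0.4),
               list(c(1.00e-3, 0.60e-3, 65, 75, 75),
                    c(1.15e-3, 0.75e-3, 60, 80, 78)),
               list(sdN, sdN)),
    Ne = comp(c(0.6, 0.4),
              list(c(4.60e-3, 0.30e-3, 85, 70, 50),
                   c(3.40e-3, 0.35e-3, 80, 72, 55)),
              list(c(1.5e-4, 3e-5, 2, 2, 2), c(1.5e-4, 3e-5, 2, 2, 2))))
}

# Ellipsoidal squared radius field for centre c and semi-axes s (mm).
.rho2 <- function(X, Y, Z, c, s) {
  ((X - c[1]) / s[1])^2 + ((Y - c[2]) / s[2])^2 + ((Z - c[3]) / s[3])^2
}

# Ground-truth label array from a phantom geometry.
.phantomLabels <- function(spec) {
  sh <- spec$shape; vs <- spec$voxelSize; geo <- spec$geometry
  cx <- (seq_len(sh[1]) - 0.5) * vs[1]
  cy <- (seq_len(sh[2]) - 0.5) * vs[2]
  cz <- (seq_len(sh[3]) - 0.5) * vs[3]
  X <- array(rep(cx, times = sh[2] * sh[3]), sh)
  Y <- array(rep(rep(cy, each = sh[1]), times = sh[3]), sh)
  Z <- array(rep(cz, each = sh[1] * sh[2]), sh)
  centre <- sh * vs / 2
  lab <- array(0L, sh)
  rhoBrain <- .rho2(X, Y, Z, centre, geo$brainSemiAxes)
  inBrain <- rhoBrain <= 1
  lab[inBrain] <- tissueIndex("WM")
  lab[inBrain & rhoBrain > geo$gmShellFraction^2] <- tissueIndex("GM")
  for (v in seq_len(nrow(geo$ventricleOffsets))) {
    vc <- centre + geo$ventricleOffsets[v, ]
    lab[inBrain & .rho2(X, Y, Z, vc, geo$ventricleSemiAxes) <= 1] <-
      tissueIndex("CSF")
  }
  tc <- centre + geo$tumourOffset
  paint <- function(lab, radii, cls) {
    if (all(radii > 0))
      lab[inBrain & .rho2(X, Y, Z, tc, radii) <= 1] <- tissueIndex(cls)
    lab
  }
  lab <- paint(lab, geo$voRadii, "VO")
  lab <- paint(lab, geo$giiRadii, "GII")
  lab <- paint(lab, geo$givRadii, "GIV")
  lab <- paint(lab, geo$neRadii, "Ne")
  list(labels = lab, brainMask = inBrain)
}

# Draw n 5-channel intensity vectors from one class mixture plus channel
# noise; diffusivities truncated at zero.
.drawClass <- function(model, n, noiseSd) {
  k <- length(model$weights)
  comp <- if (k == 1) rep(1L, n) else
    sample.int(k, n, replace = TRUE, prob = model$weights)
  out <- matrix(0, n, 5, dimnames = list(NULL, colnames(model$means)))
  for (c in 1:5) {
    out[, c] <- rnorm(n, model$means[comp, c], model$sds[comp, c]) +
      rnorm(n, 0, noiseSd[colnames(model$means)[c]])
  }
  out[, 1:2][out[, 1:2] < 0] <- 0
  out
}

#' Generate a synthetic multimodal brain phantom
#'
#' Deterministic given the spec's seed. Returns the channel stack
#' (p, q, T2w, PDw, T2n, PDn, FLAIR — the raw T2w/PDw being known affine
#' distortions of the normalised channels), the exact ground-truth label
#' volume, the brain mask, per-class true volumes in ml and the true
#' normalising affine maps.
#'
#' @param spec A [phantomSpec()].
#' @return List with `volume` ([MultimodalVolume-class]), `labels`
#'   ([LabelVolume-class]), `brainMask`, `truthVolumesMl` (named, ml),
#'   `abnormalMask` (VO+GII+GIV+Ne ground truth), `t2wMap`, `pdwMap`.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  set.seed(spec$seed)
  g <- .phantomLabels(spec)
  sh <- spec$shape
  chans <- list(p = array(0, sh), q = array(0, sh), T2n = array(0, sh),
                PDn = array(0, sh), FLAIR = array(0, sh))
  lab <- g$labels
  for (k in sort(unique(lab[lab != 0]))) {
    cls <- tissueClasses()[k]
    idx <- which(lab == k)
    draw <- .drawClass(spec$classModels[[cls]], length(idx), spec$noiseSd)
    for (c in names(chans)) chans[[c]][idx] <- draw[, c]
  }
  # raw channels: invert the true normalising map T2n = a*T2w + b
  a <- spec$t2wMap[["scale"]]; b <- spec$t2wMap[["shift"]]
  chans$T2w <- (chans$T2n - b) / a
  a <- spec$pdwMap[["scale"]]; b <- spec$pdwMap[["shift"]]
  chans$PDw <- (chans$PDn - b) / a
  vol <- multimodalVolume(chans[c("p", "q", "T2w", "PDw", "T2n", "PDn",
                                  "FLAIR")], spec$voxelSize)
  voxMl <- prod(spec$voxelSize) / 1000
  counts <- tabulate(lab[lab != 0], nbins = 7)
  truth <- structure(counts * voxMl, names = tissueClasses())
  abnormal <- array(lab %in% tissueIndex(c("VO", "GII", "GIV", "Ne")), sh)
  list(volume = vol, labels = labelVolume(lab), brainMask = g$brainMask,
       truthVolumesMl = truth, abnormalMask = abnormal,
       t2wMap = spec$t2wMap, pdwMap = spec$pdwMap)
}

#' Draw i.i.d. training samples per tissue class
#'
#' Samples the classifier channels (p, q, T2n, PDn) from each class
#' mixture (including the channel noise), independently of any phantom
#' volume — the idealised analogue of pooling labelled ROI voxels across
#' a training cohort.
#'
#' @param spec A [phantomSpec()].
#' @param nPerClass Samples per class (>= 1).
#' @param seed RNG seed (default: the spec seed + 1000).
#' @return Named list, tissue class -> nPerClass x 4 matrix.
#' @export
sampleTrainingSet <- function(spec, nPerClass, seed = spec$seed + 1000L) {
  stopifnot(inherits(spec, "phantomSpec"), nPerClass >= 1)
  set.seed(seed)
  out <- list()
  for (cls in tissueClasses()) {
    draw <- .drawClass(spec$classModels[[cls]], nPerClass, spec$noiseSd)
    out[[cls]] <- draw[, c("p", "q", "T2n", "PDn"), drop = FALSE]
  }
  out
}

#' Default MRSI geometry for a phantom
#'
#' A single-slab MRSI grid (nominal ~7 x 7 mm in-plane, 15 mm slab)
#' centred on the tumour, mapped to whole image-voxel blocks.
#'
#' @param spec A [phantomSpec()].
#' @param gridDim MRSI grid size (default c(12, 12)).
#' @return An [MRSIGeometry-class].
#' @export
phantomMRSIGeometry <- function(spec, gridDim = c(12, 12)) {
  block <- pmax(1L, as.integer(round(c(6.875, 6.875, 15) / spec$voxelSize)))
  centre <- spec$shape * spec$voxelSize / 2 + spec$geometry$tumourOffset
  centreVox <- round(centre / spec$voxelSize)
  # centre one block (and the z slab) on the tumour so pure-tumour MRSI
  # voxels exist whenever the tumour core exceeds a block
  origin <- as.integer(c(
    centreVox[1:2] - floor(gridDim / 2) * block[1:2] + floor(block[1:2] / 2),
    centreVox[3] - floor(block[3] / 2)))
  origin <- pmax(origin, 1L)
  # keep the whole grid inside the image
  maxOrigin <- spec$shape - c(gridDim * block[1:2], block[3]) + 1L
  origin <- pmin(origin, as.integer(maxOrigin))
  mrsiGeometry(origin, block, gridDim)
}

#' Ground-truth MRSI tissue-fraction table for a phantom
#'
#' Block-averages the ground-truth labels into (normal, GII, GIV)
#' fractions per MRSI voxel — the phantom's stand-in for a spectral
#' decomposition. Necrosis counts toward the GIV fraction; GM, WM, CSF,
#' VO and background count as normal. A `train` column flags voxels
#' passing the purity rule for the given grade (the voxels that would
#' seed the tumour PDDs).
#'
#' @param labels A [LabelVolume-class] of ground-truth labels.
#' @param geometry An [MRSIGeometry-class].
#' @param rules A [roiRules()] list (purity threshold for `train`).
#' @param grade Phantom grade, "GII" or "GIV".
#' @return Data frame with columns i, j, fraction_normal, fraction_GII,
#'   fraction_GIV, train.
#' @export
phantomMRSIFractions <- function(labels, geometry, rules = roiRules(),
                                 grade = c("GIV", "GII")) {
  grade <- match.arg(grade)
  shape <- gridShape(labels)
  nd <- geometry@gridDim
  rows <- vector("list", prod(nd))
  r <- 0L
  giiIdx <- tissueIndex("GII")
  hgIdx <- tissueIndex(c("GIV", "Ne"))
  for (gj in seq_len(nd[2])) {
    for (gi in seq_len(nd[1])) {
      r <- r + 1L
      blk <- .mrsiBlock(geometry, gi, gj, shape)
      sub <- labels@labels[blk$xs, blk$ys, blk$zs]
      n <- length(sub)
      fGII <- sum(sub == giiIdx) / n
      fGIV <- sum(sub %in% hgIdx) / n
      rows[[r]] <- data.frame(i = gi, j = gj,
                              fraction_normal = 1 - fGII - fGIV,
                              fraction_GII = fGII, fraction_GIV = fGIV)
    }
  }
  df <- do.call(rbind, rows)
  df$train <- df[[paste0("fraction_", grade)]] > rules$mrsiPurityThreshold
  df
}
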