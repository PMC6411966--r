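---
title: "Tissue-type mapping of gliomas: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-type mapping of gliomas: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotype)
```

## The problem

Gliomas grow infiltratively: the tumour core, its infiltration margin and
surrounding vasogenic oedema all look different across MRI contrasts, and
no single sequence separates them. `gliotype` implements a nosologic
mapping approach: every brain voxel is assigned a posterior probability
over seven tissue classes — grey matter (GM), white matter (WM),
cerebrospinal fluid (CSF), vasogenic oedema (VO), grade II glioma (GII),
grade IV glioma (GIV) and necrosis (Ne) — from four co-registered MRI
channels, and the result is rendered as an RGB map in which colour encodes
inferred tissue type rather than raw signal.

The four classifier channels are the isotropic (*p*) and anisotropic (*q*)
diffusion-tensor magnitudes (mm²/s) and intensity-normalised T2-weighted
(T2n) and proton-density-weighted (PDn) images. A FLAIR channel is used
only for superpixel geometry, never for classification.

## The model

**Class-conditional likelihoods.** Each tissue class *C~i~* gets a
non-parametric likelihood *p*(X | *C~i~*) over the feature vector
X = (*p*, *q*, T2n, PDn): a 4D histogram with 50 bins per axis built from
training voxels, normalised to unit integral ("unit volume") by dividing
counts by *n* × bin hypervolume. No Gaussian assumption is made — tumour
intensity distributions are visibly multi-modal — and no spatial prior is
used.

**Posterior.** The prior of class *i* at X is its normalised likelihood,

$$P(C_i) = \frac{p(X \mid C_i)}{\sum_j p(X \mid C_j)},$$

and Bayes' rule then gives

$$P(C_i \mid X) = \frac{P(C_i)\, p(X \mid C_i)}{\sum_j P(C_j)\, p(X \mid C_j)}
  \;\propto\; p(X \mid C_i)^2 .$$

The squared-likelihood consequence of this prior definition is implemented
literally because it is the published formulation; whether a flat prior
(posterior ∝ likelihood) was intended is not discussed in the source
method, so `classifyVolume(..., prior = "flat")` is provided for
sensitivity analysis and the squared form is the default. In practice the
squaring sharpens posteriors monotonically and does not change the argmax.

**Training ROIs.** Tumour training voxels come from MRSI: spectroscopy
voxels whose spectral decomposition is more than 90% one glioma grade
(strict >0.90) label their image block GII or GIV according to the
patient's grade (`deriveTumourROIs`). GIV ROI voxels with
*p* > 4×10⁻³ mm²/s are relabelled necrosis (`splitNecrosis`); this
threshold separates fluid-like necrotic cores from cellular tumour.
Normal-tissue masks (probabilistic segmentation thresholded at 0.95) and
expert-drawn oedema ROIs are consumed as inputs — this package does not
segment healthy controls or draw oedema.

**Superpixel regularisation.** Voxelwise posteriors are noisy, so they are
averaged over SLIC superpixels computed per axial slice on the PDn, FLAIR
and *p* channels (FLAIR separates CSF from oedema; *q* is excluded for its
white-matter heterogeneity). Slices are upsampled in-plane by a factor of
4 — 256² acquisition matrices become 1024² — and clustered with grid size
30 and regularisation 0.2; the mean class probabilities within each
superpixel are renormalised to unit sum.

**Lesion and colour map.** Superpixels with
*p*(VO) + *p*(GII) + *p*(GIV) + *p*(Ne) > 0.5 are abnormal; the largest
3D-connected component of abnormal superpixels is the lesion, and its
volume is reported in ml. Within the lesion each superpixel is coloured
(R, G, B) = (*p*(GIV), *p*(GII), *p*(Ne)), normalised to unit length and
intensity-modulated by *p*(GII) + *p*(GIV) + *p*(Ne), so pure oedema
renders black, high-grade tissue red, low-grade/infiltrated tissue green
and necrosis blue, with mixtures as colour blends. The high-grade tissue
burden is the total volume of lesion superpixels with *p*(GIV) > 0.5.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| histogram bins per axis | 50 | – | shared global grid over all classes |
| bin-grid span | pooled 0.5–99.5 percentile | channel units | out-of-range values clipped into edge bins |
| MRSI purity threshold | 0.90 (strict >) | fraction | tumour ROI rule |
| necrosis *p* threshold | 4×10⁻³ (strict >) | mm²/s | GIV → Ne relabelling |
| normal-mask probability | 0.95 | fraction | input contract for GM/WM/CSF masks |
| SLIC grid size | 30 | upsampled px | superpixel spacing |
| SLIC regularisation | 0.2 | – | spatial-vs-intensity weight on [0,1]-scaled channels |
| in-plane upsampling | 4 | – | 256² → 1024² before clustering |
| lesion threshold | 0.5 (strict >) | probability | abnormal-superpixel rule |
| high-grade threshold | 0.5 (strict >) | probability | *p*(GIV) volume rule |
| normalisation bins | 256 | – | reference histogram resolution |

## Intensity normalisation

T2w and PDw intensities are scanner-arbitrary, so before histogramming
they are mapped onto a cohort reference: `fitAffineIntensityMap` finds the
positive scale *a* and shift *b* minimising the L2 distance between the
unit-sum histogram of *a*·I + *b* (binned on the reference's edges) and
the unit-sum reference histogram. Because binning makes this objective
piecewise-constant in (*a*, *b*), a gradient method is unreliable; the
optimiser is a moment-matched coarse grid search followed by Nelder–Mead
refinement, which the test suite checks against an exhaustive grid search.
The reference histogram is an explicit, persisted artifact
(`writeReferenceHistogram`) rather than a volume chosen at run time, so
normalisation is reproducible; it spans the 0.1–99.9 percentile range with
256 bins (the 8-bit acquisition-matrix convention — the bin count is a
package choice, as is the use of the full skull-stripped brain mask
without CSF exclusion when histogramming).

## The phantom generator

No patient data ship with the method, so the package carries a synthetic
phantom (`phantomSpec`/`generatePhantom`) that defines the study
conditions for every test: a 256 × 256 × 16 grid of 0.9375 × 0.9375 × 5 mm
voxels (a typical dual-echo/DTI clinical geometry) holding a WM ellipsoid
with a GM shell and CSF ventricles, plus a nested tumour — necrotic centre
⊂ GIV core ⊂ GII rim — wrapped in an oedema shell. Channel intensities are
drawn from per-class mixtures of diagonal Gaussians: two components for
GII, GIV and Ne (emulating the multi-cluster, non-Gaussian tumour
histograms seen in patient data) and one for each normal class. Channel
means are loosely anchored to 1.5 T physiology (WM *p* ≈ 0.7×10⁻³ mm²/s,
CSF ≈ 3×10⁻³, one necrosis component above the 4×10⁻³ threshold so the
necrosis rule is exercisable; CSF dark on FLAIR) with class separations of
at least 3 SD in at least one channel. Raw T2w/PDw channels are emitted as
known affine distortions of T2n/PDn so the normalisation stage has real
work whose answer is known. The phantom also emits a synthetic MRSI
geometry (≈6.9 × 6.9 mm in-plane, 15 mm slab, centred on the tumour) and a
ground-truth fraction table standing in for a spectral decomposition, so
the MRSI-driven ROI rules and the evaluation battery run end to end.

What the phantom does **not** emulate: partial-volume mixing at region
boundaries, bias fields, k-space/PSF effects, registration error, and the
anatomical irregularity of real lesions. Passing the recovery tests
therefore demonstrates the correctness of the pipeline's machinery —
binning, Bayes rule, superpixel averaging, component extraction, metric
arithmetic — under known conditions, not clinical accuracy on real data.

## Numerical choices and degenerate inputs

* **Binning.** One global bin grid is shared by all classes (the
  cross-class likelihood ratio must compare densities at the same X);
  edges span the pooled 0.5–99.5 percentile range with uniform spacing,
  and out-of-grid values are clipped into edge bins, identically during
  construction and lookup. Lookup is piecewise-constant — no
  interpolation — as the plainest reading of a histogram density.
* **Unit volume** is read as unit *integral* (a density), not unit sum;
  the posterior is invariant to any common rescaling of all class PDDs,
  so the two readings cannot change the classification.
* **Out-of-support voxels** (all seven densities zero) receive the
  uniform 1/7 posterior and an explicit flag, keeping superpixel
  averaging defined; they are never silently zeroed. Note that the
  uniform vector counts 4/7 toward the abnormality sum, so a brain mask
  (skull-stripped convention) is required for meaningful lesion
  extraction.
* **Superpixels** are clustered in 2D per axial slice (5 mm slice gaps
  make 3D clustering physically inhomogeneous); 3D connectivity enters
  only at the lesion-component step, with 26-connectivity. Channels are
  rescaled to [0,1] by their 1–99 percentile range before clustering;
  upsampling is nearest-neighbour and labels return to the native grid by
  block majority vote (ties to the smaller id). SLIC is deterministic:
  grid initialisation, fixed scan order, 10 iterations, orphan regions
  below S²/4 pixels absorbed into a neighbour.
* **Renormalisation order.** Superpixel probabilities are renormalised
  before the lesion inequality is tested, following the order the
  procedure is described in; since in-mask posterior rows already sum to
  1, the mean does too and the renormalisation is a no-op except after
  masking asymmetries — the alternative order would give identical
  results in practice.
* **Thresholds are strict** (>, not ≥) everywhere a threshold is printed;
  exact ties are excluded.
* **Distance correlation** is Székely's biased sample statistic
  (double-centred distance matrices), the original form of the cited
  technique, not the bias-corrected variant. Constant inputs (zero
  distance variance) are an error, not a zero. Note dCor is invariant
  under similarity transforms (rotation, isotropic scaling, translation)
  of either argument, not under arbitrary affine maps.
* **MRSI comparison** drops spectroscopy voxels whose image block holds
  no posterior mass (wholly outside the brain mask) and excludes
  PDD-training voxels from the held-out statistic. Pearson's test on
  volume agreement is two-sided.
* **Degenerate inputs** fail loudly: misaligned channels name the
  offending channel (registration is out of scope — inputs must be
  pre-registered), constant intensities refuse normalisation, empty masks
  refuse histogramming, both-empty masks refuse overlap metrics.
* **Optional histogram smoothing** (`buildPDD(smoothSigma = ...)`,
  bin-space separable Gaussian, mass-preserving at boundaries) exists for
  sparse-data robustness but is off by default — the source method uses
  raw histograms.

## Configuration and randomness

`runPipeline` consumes a YAML configuration (this package uses YAML
because it is the structured-text format available in its dependency
stack) with every default equal to the printed method values, and routes
all randomness through a single integer seed; reruns with the same
configuration are bit-identical. The pipeline stages — normalise, build
priors, classify, superpixel map, evaluate — each log their parameters
and outputs. The thin command-line wrapper in `inst/cli/gliotype`
exposes `simulate`, `normalize`, `build-priors`, `classify`, `map`,
`evaluate` and `run`.

## Problem sizes used by the test suite

The test suite and the acceptance script regenerate everything from code:
the full-resolution phantom (256 × 256 × 16, ~358k brain voxels) with
10,000 training samples per class for the recovery checks; a coarse
96 × 96 × 8 phantom for module-level smoke and property tests; a
six-phantom cohort at 128 × 128 × 10 (tumour radii scaled 0.6–1.25,
three low-grade and three high-grade cases) for volume-agreement
statistics; and n = 10³ vs 10⁵ draws for convergence properties. These
sizes are the package's chosen test conditions: large enough for the
asymptotic properties to show, small enough to run everywhere.

## Known limitations

* The classifier is purely intensity-based; with 50⁴ bins and realistic
  training counts the histograms are sparse, and rare intensity
  combinations fall out of support (~3% of brain voxels in the phantom
  recovery run). Smoothing or more training data reduces this.
* The squared-likelihood posterior inherits any histogram noise twice;
  the `flat` prior option is provided for comparison.
* Accuracy on real data depends on registration and normalisation
  quality, neither of which this package measures; registration itself is
  explicitly out of scope.
* The seven-class set is fixed; adding classes (or channels) means adding
  PDDs (or histogram dimensions), which the data structures support but
  the pipeline surface does not currently expose.
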