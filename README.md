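# gliotype

Nosologic tissue-type mapping of glial brain tumours from multimodal MRI.

Gliomas are heterogeneous: a single lesion can hold high-grade tumour,
low-grade/infiltrated tissue, necrosis and vasogenic oedema, and their
extent drives surgery and radiotherapy planning. `gliotype` turns four
co-registered MRI channels — isotropic (*p*) and anisotropic (*q*)
diffusion maps plus intensity-normalised T2-weighted (T2n) and
proton-density-weighted (PDn) images — into voxelwise posterior
probabilities over seven tissue classes (GM, WM, CSF, oedema, grade II
glioma, grade IV glioma, necrosis), and renders the result as an RGB map
whose colours encode inferred tissue type. It is aimed at neuroimaging
researchers prototyping tumour-characterisation pipelines.

## Method in brief

Each class `C_i` gets a non-parametric likelihood `p(X | C_i)`: a 4D
histogram over `X = (p, q, T2n, PDn)` with 50 bins per axis on one shared
grid, normalised to unit integral. The prior is the normalised
likelihood,

    P(C_i) = p(X|C_i) / Σ_j p(X|C_j),

so Bayes' rule gives a posterior proportional to the *squared*
likelihood,

    P(C_i | X) = P(C_i) p(X|C_i) / Σ_j P(C_j) p(X|C_j) ∝ p(X|C_i)².

Posteriors are averaged within per-slice SLIC superpixels (grid size 30,
regularisation 0.2, on PDn/FLAIR/p upsampled 4× in-plane), the lesion is
the largest 3D-connected set of superpixels with
`p(VO)+p(GII)+p(GIV)+p(Ne) > 0.5`, and lesion superpixels are coloured
`(R,G,B) = (p(GIV), p(GII), p(Ne))`, unit-length normalised and
intensity-modulated by `p(GII)+p(GIV)+p(Ne)` (pure oedema renders black).
Training ROIs follow the MRSI rules: >90%-pure spectroscopy voxels seed
the tumour classes, and GIV voxels with `p > 4e-3 mm²/s` become necrosis.
Tumour burden is reported as the volume of lesion superpixels with
`p(GIV) > 0.5`.

Because no patient data are distributable, the package includes a
synthetic 7-class brain phantom (nested tumour geometry, per-class
non-Gaussian intensity mixtures, ground-truth labels and a synthetic MRSI
fraction table) so every stage is testable end to end, plus the
evaluation battery: distance correlation against MRSI fractions,
Dice/Jaccard/Overlap coefficients and Bland–Altman volume agreement.

## Worked example

```r
library(gliotype)

spec <- phantomSpec(seed = 1)          # 256 x 256 x 16 synthetic brain
ph   <- generatePhantom(spec)
ph$volume
#> MultimodalVolume: 256 x 256 x 16 voxels, 0.938 x 0.938 x 5 mm
#>   channels: p, q, T2w, PDw, T2n, PDn, FLAIR

train <- sampleTrainingSet(spec, 10000)
grid  <- fitBinGrid(train, bins = 50)
pdds  <- lapply(names(train), function(cl) buildPDD(train[[cl]], grid, cl))
names(pdds) <- names(train)
pdds$GIV
#> PDD4D [GIV]: 50^4 bins, 10000 training samples, 3261 occupied

post <- classifyVolume(ph$volume, pdds, ph$brainMask)
post
#> PosteriorMap: 256 x 256 x 16 voxels over GM/WM/CSF/VO/GII/GIV/Ne
#>   out-of-support voxels: 27208

labels <- computeSuperpixels(ph$volume, ph$brainMask)
spm    <- averageProbabilities(post, labels)
lesion <- extractLesion(spm, voxelSize(ph$volume))
lesion
#> LesionSegmentation: 86.60 ml (19706 voxels), 1 component(s) considered

highGradeVolume(spm, lesion, voxelSize(ph$volume))
#> [1] 6.543457
overlapMetrics(lesionMask(lesion), ph$abnormalMask)$dice
#> [1] 0.9999493
```

The phantom's true abnormal volume is 86.59 ml and its GIV core (with
necrotic centre) totals 8.6 ml: the automatic lesion recovers the
abnormal region almost exactly (Dice 0.99995), and 6.5 ml of superpixels
exceed the 0.5 high-grade probability threshold — the boundary shell of
the core is shared with low-grade tissue, so the strict threshold
undershoots the anatomical core volume slightly.

`runPipeline()` (or the CLI, `inst/cli/gliotype run --config cfg.yaml`)
chains normalisation → priors → classification → superpixel mapping →
evaluation with logging, and subcommands `simulate`, `normalize`,
`build-priors`, `classify`, `map` and `evaluate` expose the stages
individually.

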