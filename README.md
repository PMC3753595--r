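# lddmmseg

Greedy LDDMM image registration and atlas-based subcortical segmentation
in R, with a synthetic-phantom harness that makes the whole pipeline
verifiable end to end.

## What it is for

Segmenting subcortical brain structures (caudate, putamen, globus
pallidus, hippocampus, amygdala, thalamus, ventricles) by deformable
registration of labeled atlases: register an atlas image onto a subject
with a diffeomorphic map, then carry the atlas ROI charts through that
map. The package implements

* **Greedy LDDMM**: minimize
  `E(v) = ∫‖Lv_t‖² dt + (1/σ²)‖I₀∘φ⁻¹ − I₁‖²` over a time-dependent
  velocity field with `L = −α∇² + γId`, by per-timestep gradient descent
  `v_t ← v_t − ε(2v_t − K[(2/σ²)|Dφ_{t,1}|(J⁰_t − J¹_t)∇J⁰_t])`, the
  smoothing kernel `K = (L†L)⁻¹` applied in the Fourier domain. The flow
  is discretized into `T` timesteps (default 10; `T = 1` is the
  small-deformation approximation) and every produced map is certified
  diffeomorphic by a positive Jacobian determinant.
* **Cascading**: stages with decreasing α (default 0.01 → 0.005 → 0.002,
  γ = 1), composing the backward maps — robust registration of large
  deformations at small final α.
* **Segmentation**: histogram matching, moment-based pre-alignment,
  single-atlas label propagation, and multi-atlas fusion by an EM
  Gaussian-mixture likelihood model with convex per-voxel weights
  (majority vote included as baseline).
* **Metrics**: the kappa statistic, percent volume difference
  `100|V_A − V_M|/V_M`, and the L1 misclassification error
  `(|A∪M| − |A∩M|)/(|A∪M|/2)`, per ROI with per-subject means.
* **Phantoms**: 14-structure subcortical-style labeled images with known
  ground-truth diffeomorphisms and populations thereof, so every claim
  above is testable without any data download.

## Worked example

```r
library(lddmmseg)

# a 64x64 phantom atlas and one deformed, noisy subject
spec  <- defaultPhantomSpec(c(64, 64), seed = 1)
atlas <- makePhantom(spec)
pop   <- makePopulation(spec, 1, deformAmplitude = 2, seed = 71)
subj  <- pop[[1]]

# single-atlas segmentation: histogram match, cascaded LDDMM, label transfer
seg <- segmentSingleAtlas(
  AtlasEntry(subjectImage(atlas), subjectLabels(atlas)),
  subjectImage(subj),
  LDDMMParams(sigma = 0.2, nTimeSteps = 10, maxIter = 20),
  alphas = c(0.01, 0.005, 0.002))

m <- evaluateROIs(seg, subjectLabels(subj))
head(m[, c("name", "kappa", "vd", "l1")], 4)
#>                   name     kappa       vd         l1
#> 1       left_ventricle 0.9929792 1.388889 0.02739726
#> 2         left_caudate 1.0000000 0.000000 0.00000000
#> 3         left_putamen 0.9903525 1.923077 0.03773585
#> 4 left_globus_pallidus 0.9534771 3.125000 0.17647059
attr(m, "means")
#>      kappa         vd         l1
#> 0.97929425 2.16434317 0.07887843
```

Each row scores one ROI of the automated segmentation against the
subject's ground-truth labels: `kappa` is chance-corrected voxel
agreement (0.8 counts as good for brain structures), `vd` the volume
difference in percent, `l1` the normalized symmetric-difference error
(0 = perfect, 2 = disjoint). A registration alone:

```r
res <- registerLDDMM(subjectImage(atlas), subjectImage(subj),
                     LDDMMParams(alpha = 0.01, sigma = 0.2))
tail(energyTrace(res), 1)       # total = reg + mismatch, non-increasing
#>    iter      total          reg   mismatch     stepSize stage
#> 19   18 0.01560963 0.0005270931 0.01508254 0.0009765625     1
min(intensities(jacobianDeterminant(inverseMap(res))))  # > 0
#> [1] 0.8578944
```

A command-line wrapper over the same functions lives at
`inst/scripts/lddmm-tool` with subcommands `simulate`, `register`,
`segment`, `fuse`, `evaluate` and `experiment` (the α × T parameter
grid); every run writes its resolved YAML configuration beside its
outputs.

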