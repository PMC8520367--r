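# tensorCut

Interactive (seeded) graph-cut segmentation for 2D/3D scalar images and
diffusion-tensor (DTI) volumes, with a synthetic lesion phantom generator
and utilities for two-group inference from printed summary statistics.

## Who this is for

Medical-image analysts who need a small, exact, fully auditable binary
segmenter: mark a handful of target and background voxels, get the globally
optimal labeling of everything else. The motivating application is lesion
delineation in delayed post-hypoxic leukoencephalopathy (e.g. after severe
carbon monoxide poisoning), where lesions appear as bilateral, symmetric,
ovoid periventricular regions on CT/MRI and as altered diffusion tensors on
DTI — hence first-class support for tensor-valued voxels.

## The model

A labeling `x` (1 = target, 0 = background) minimises

    E(x) = alpha * sum_i R(i, x_i)
         + (1 - alpha) * sum_{(i,j) adjacent, x_i != x_j} B(i, j)

- Seeds are hard constraints: a flipped seed costs `K`, chosen per instance
  so that no minimum cut can afford it.
- Unknown voxels pay the normalised effective distance to the seed sets,
  `R(i, target) = D_i^O / (D_i^O + D_i^B)` where
  `D_i^S = mean_{s in S} d(f_i, f_s)`.
- Neighbouring voxels with different labels pay the Gaussian boundary
  penalty `B(i,j) = exp(-d(f_i,f_j)^2 / (2 sigma^2))` (8-neighbourhood on
  slices; opt-in 6-neighbourhood for full 3D).
- For scalar images `d` is absolute intensity difference; for tensor fields
  it is the log-Euclidean distance `||log T_i - log T_j||_F` by default
  (Frobenius and affine-invariant metrics are pluggable).

The energy is minimised *exactly* by a minimum s/t cut (max-flow duality);
the result object carries both the recomputed energy and the flow value,
which must agree — a built-in audit of the graph encoding.

The package also recomputes two-sample t statistics from printed
`mean ± SD, n` table cells, `t = |m1 - m2| / sqrt(s1^2/n + s2^2/n)`, and
ships a 20-row clinical comparison fixture that it verifies at the printed
3-decimal precision.

## Worked example

```r
library(tensorCut)

spec    <- phantomSpec()               # 64x64 slice, two mirrored lesions,
                                       # log-tensor noise SD 0.05
phantom <- makeTensorPhantom(spec)
seeds   <- phantomSeeds(spec)          # 2 target + 5 background voxels
res     <- segmentImage(phantom$field, seeds)
res
#> SegmentationResult: 246 target / 3850 background voxels; E=341.268,
#>   flow=341.268 (metric logEuclidean, alpha 0.5)
diceCoefficient(labeling(res) == 1L, phantom$truth)
#> [1] 1
paramsUsed(res)
#> EnergyParams: alpha=0.5, sigma=0.2169231, K=8.958708, metric=logEuclidean
```

The 246 recovered target voxels are exactly the phantom's lesion voxels
(Dice 1): the two-seed regional term plus the boundary term suffice at this
noise level. `E` is the energy of the returned labeling recomputed from
scratch and `flow` the min-cut value — their agreement certifies the graph
construction. `sigma` was resolved data-adaptively (mean neighbour
dissimilarity) and `K` per instance so seeds can never be flipped.

Verifying a printed clinical table:

```r
report <- verifyTableFixture()
head(report[report$timepoint == "after", c("variable", "printed_t", "computed_t", "pass")], 3)
#>      variable printed_t computed_t pass
#> 2  CK-MB(U/L)    10.924  10.924544 TRUE
#> 4 cTnI(ng/ml)     6.105   6.104521 TRUE
#> 6   Myo(ug/L)     2.273   2.272644 TRUE
```

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "tensorcut", package = "tensorCut"))') \
    phantom --out p/
# then
... tensorcut segment-dti --in p/tensors.nii.gz --seeds p/seeds.nii.gz --out r/
... tensorcut stats verify
```

## Documentation

The methods vignette (`vignettes/seeded-graph-cut-dti.Rmd`) documents the
energy, the tensor metrics, the parameter defaults and their rationale, the
phantom's scope and limits, and all numerical edge cases.
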