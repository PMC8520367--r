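---
title: "Seeded graph-cut segmentation of scalar and diffusion-tensor images"
author: "tensorCut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded graph-cut segmentation of scalar and diffusion-tensor images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorCut)
```

# The model

tensorCut implements interactive binary segmentation by exact energy
minimisation. The user marks a few voxels as target (the set $O$) and a few
as background ($B$); every other in-mask voxel is unknown ($U$). A labeling
$x$ assigns each voxel $x_i \in \{\text{target}, \text{background}\}$, and
the labeling returned is the global minimiser of

$$
E(x) \;=\; \alpha \sum_i R(i, x_i) \;+\;
(1-\alpha) \sum_{\substack{(i,j)\in N \\ x_i \neq x_j}} B(i,j),
$$

subject to the seeds keeping their labels. The two sums encode four
penalties:

1. **Target-seed constraint.** $R(i,\text{target}) = 0$ and
   $R(i,\text{background}) = K$ for $i \in O$, with $K$ large (below).
2. **Background-seed constraint.** Mirrored for $i \in B$.
3. **Closest-set term.** For unknown voxels, the *effective distances*
   $D_i^O$ and $D_i^B$ are the average feature dissimilarity from voxel $i$
   to each seed set,
   $D_i^S = \tfrac{1}{|S|}\sum_{s\in S} d(f_i, f_s)$, and the regional
   penalty is the normalised form
   $R(i,\text{target}) = D_i^O / (D_i^O + D_i^B)$,
   $R(i,\text{background}) = D_i^B / (D_i^O + D_i^B)$. Normalisation makes
   the two penalties sum to one, so every unknown voxel carries the same
   total regional weight and only the *relative* proximity to the two seed
   sets matters. When both distances are zero the voxel is uninformative and
   both penalties are 0.5 (a symmetric prior).
4. **Boundary term.** Adjacent voxels with different labels pay
   $B(i,j) = \exp\!\big(-d(f_i,f_j)^2 / 2\sigma^2\big)$: cutting between
   similar neighbours is expensive (the penalty is maximal, 1, for identical
   features) and cutting across a real edge is nearly free.

The energy is minimised exactly by a minimum s/t cut: terminals $s$
(target side) and $t$ (background side) are connected to every voxel with
capacities $\alpha R(i,\text{background})$ and $\alpha R(i,\text{target})$
respectively, neighbours are linked with $(1-\alpha)B(i,j)$, and max-flow
duality makes the minimum cut value equal the minimal energy. Both the
energy recomputed from the returned labeling and the flow value are stored
in the result and must agree to $10^{-6}$ — a built-in audit of the graph
encoding.

## From scalars to tensors

For scalar images the voxel feature is the intensity and
$d(f_i,f_j) = |P_i - P_j|$. For diffusion-tensor images each voxel carries a
symmetric positive-definite (SPD) $3\times 3$ tensor and $d$ becomes a
tensor dissimilarity. The default is the **log-Euclidean distance**

$$ d(T_i, T_j) = \lVert \log T_i - \log T_j \rVert_F, $$

chosen because it has the behaviour a tensor contrast needs — zero exactly
at equality, symmetric, diverging to infinity as either tensor approaches
singularity — while remaining cheap: the matrix logarithms are computed once
per voxel and all pairwise distances reduce to Euclidean distances in the
6-dimensional log-embedding
$(\ell_{11}, \ell_{22}, \ell_{33}, \sqrt2\,\ell_{12}, \sqrt2\,\ell_{13},
\sqrt2\,\ell_{23})$. The metric is a strategy seam: `"frobenius"`
($\lVert T_i - T_j\rVert_F$, flat, does not diverge near singularity) and
`"affineInvariant"`
($\lVert\log(T_i^{-1/2} T_j T_i^{-1/2})\rVert_F$, invariant under any
invertible congruence but with no global embedding, hence quadratic cost in
seed-set size) can be swapped in per call, and the name used is recorded in
every result and audit file. Tensors are validated as SPD (smallest
eigenvalue above $10^{-10}$) before any metric is evaluated; invalid in-mask
voxels abort segmentation with the offending voxel named, and file readers
instead mask them out with a reported count — repair is never silent.

# Tunable parameters

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `alpha` | weight of the regional vs boundary sum, in (0,1) | 0.5 | balanced trade-off; our convention fixes $\alpha$ on the regional sum |
| `sigma` | boundary kernel scale, in feature-distance units | mean neighbour-pair dissimilarity of the image | data-adaptive: puts the kernel's transition at the image's own contrast scale; 1 if the image is perfectly uniform (the kernel is then 1 everywhere regardless) |
| `hardConstraintWeight` (K) | regional penalty for flipping a seed | $(1 + M)/\alpha$, $M$ = largest per-node sum of incident n-link capacities | the seed t-link capacity becomes $\alpha K = 1 + M$, strictly larger than everything the cut could gain by flipping the seed — for *every* $\alpha \in (0,1)$. A fixed additive form ($1 + M$ without the $1/\alpha$) fails this guarantee at small $\alpha$, which is why the instance-scaled form is used |
| `metric` | tensor dissimilarity | `"logEuclidean"` | see above |

Neighbourhoods: 2D slices use the 8-neighbourhood. That notion is
inherently planar, so 3D volumes are processed slice-wise by default, with
an opt-in `connectivity = "full6"` face-adjacent 3D mode.

# Determinism and tie-breaking

The pipeline has no randomness. Among co-optimal minimum cuts the partition
is fixed by a documented rule: after computing a maximum flow, voxels
reachable from $s$ in the residual graph are labelled target, all others
background. (A consequence worth knowing: a node with no residual path from
$s$ — e.g. in a graph whose terminals are disconnected — lands on the
*background* side.) Identical inputs therefore give bit-identical labelings.
Duality is asserted with absolute tolerance $10^{-9}$ on floating-point
capacities and exactly on integer ones.

# The synthetic phantom

`makeTensorPhantom()` and `makeScalarPhantom()` generate the package's test
bed: a $64\times 64$ slice with two elliptical lesions (semi-axes 5 rows
$\times$ 8 columns) mirrored exactly about the midline column — emulating
the bilateral, symmetric, ovoid periventricular lesion geometry reported in
delayed post-hypoxic leukoencephalopathy. Background voxels carry the
isotropic tensor $\mathrm{diag}(1,1,1)\times 10^{-3}\,\mathrm{mm^2/s}$,
lesion voxels the anisotropic $\mathrm{diag}(1.8,0.6,0.6)\times 10^{-3}$
(principal axis along x), a log-Euclidean contrast of
$\sqrt{\ln^2 1.8 + 2\ln^2 0.6} \approx 0.9313$.

Tensor noise is applied in log-tensor space: the six lower-triangular
components of each voxel's matrix logarithm receive iid
$\mathcal N(0, 0.05^2)$ perturbations and the matrix exponential maps back.
Every generated tensor is SPD *by construction* at any noise level; the
alternative — perturbing raw components and clipping eigenvalues — was
rejected because clipping distorts the noise distribution near the SPD
boundary. The default noise SD of 0.05 log-units against a 0.93 contrast
makes the default task comfortably solvable from two target seeds (one per
lesion centre) and five background seeds, yet non-trivial: per-component
noise accumulates to neighbour distances of the same order as sigma.
Generation uses a private, fully specified RNG (Mersenne-Twister with
inversion sampling), so a fixed spec seed yields bit-identical phantoms
without touching the caller's RNG stream.

What the phantom does **not** emulate: Rician acquisition noise on
diffusion-weighted images, partial-volume mixing at lesion borders, blurred
or graded lesion margins, anatomy outside the lesions. Passing phantom
tests therefore demonstrates correctness of the energy model and solver on
piecewise-constant-plus-noise data, not clinical-grade robustness.

# Summary-statistics module

Clinical comparison tables often print only mean ± SD per arm with the group
size and a t value. `tFromSummaries()` recomputes

$$ t = \frac{|\bar x_1 - \bar x_2|}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}, $$

which for equal group sizes coincides with the pooled-variance two-sample
statistic, so the Welch/pooled ambiguity is immaterial for balanced designs.
The value is unsigned, matching tables that print positive t regardless of
direction. The packaged fixture (`clinicalTablesPath()`) mirrors a published
three-table comparison (cardiac function; inflammatory and endothelial
markers; serum NO/NOS/iNOS; n = 36 per arm, units preserved verbatim
including their oddities), and `verifyTableFixture()` recomputes every row's
t and checks it against the printed value at ±0.001 — agreement at the
printed 3-decimal precision. All 20 rows reproduce. Within-group
before/after comparisons would need the paired correlation, which summary
tables do not print; they are out of scope. `chiSquare2x2()` is the Pearson
statistic without continuity correction (no printed chi-squared values exist
to compare against, so the choice is property-tested rather than
fixture-verified).

# Numerical choices and edge cases

- **SPD tolerance** $10^{-10}$ on the smallest eigenvalue; matrix symmetry
  is accepted up to relative $10^{-8}$ (absorbing floating-point asymmetry
  from rotations) and symmetrised before the spectral decomposition.
- **Uniform images**: the adaptive sigma would be 0; it is set to 1, which
  is immaterial because all boundary penalties are then $\exp(0)=1$.
- **Fully seeded images**: the unknown set is empty, effective distances are
  skipped, and the result equals the seed labels.
- **Zero-distance ties** ($D^O_i = D^B_i = 0$): both regional penalties 0.5.
- **Masked voxels** are excluded from the graph entirely (no node, no
  links), not silently labelled background — this keeps $|U|$ and the
  regional normalisation meaningful.
- **Energy/flow agreement** is asserted to $10^{-6}$ relative on every run.

# Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: exhaustive labeling
enumeration on instances with at most 12 unknown voxels (4096 labelings);
the brute-force cut oracle on random graphs with up to 12 non-terminal nodes
(mixed integer and floating capacities, 100 instances); and 20 noisy
$64\times 64$ tensor phantoms for the recovery statistics. These sizes give
exact, enumerable ground truth for the solver while keeping the default
check run fast on a single CPU.

# Known limitations

- Binary labels only; multi-label energies are out of scope.
- The regional term is the normalised-distance form; negative-log-likelihood
  regional models are not implemented.
- The 8-neighbourhood is planar; full-3D mode uses face adjacency (6), not
  26-connectivity.
- Tensor fitting from raw diffusion-weighted data, tractography and
  registration are out of scope: inputs are already-estimated tensor fields.

# A worked example

```{r example, eval = FALSE}
spec <- phantomSpec()                 # 64x64, two mirrored lesions, noise 0.05
phantom <- makeTensorPhantom(spec)
seeds <- phantomSeeds(spec)           # 2 target + 5 background voxels
res <- segmentImage(phantom$field, seeds)
res
diceCoefficient(labeling(res) == 1L, phantom$truth)
```
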