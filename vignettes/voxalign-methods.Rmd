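---
title: "Correlating light-sheet and microCT volumes: methods and design"
author: "voxalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating light-sheet and microCT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxalign)
```

## The problem

Light-sheet fluorescence microscopy localises gene products (antibody or
in-situ labels) in a whole small specimen at sub-micrometre resolution,
but it only shows what is labelled. X-ray microtomography of the same
specimen after contrast staining shows every tissue at histology-like
detail, but carries no molecular identity. voxalign registers the
tomography volume onto the light-sheet volume so that expression
patterns can be read in their full anatomical context, and then
quantifies marker content per segmented tissue.

The workflow has three parts, mirroring how such data are processed in
practice:

1. **Compression.** The raw volumes are large (tens of gigabytes). The
   fluorescence channels are binned by block averaging to the tomography
   voxel size (0.406 um to 1.22 um is a factor-3 bin), everything is
   reduced to 8-bit with robust percentile clipping, and all channels
   are summed into a single fixed volume. Summation matters: individual
   marker channels can be sparse and structurally poor, and registration
   quality rises with the structural content of the fixed image.
2. **Registration.** A similarity transform (rotation, isotropic scale,
   translation) is estimated from at least five manually picked landmark
   pairs, refined automatically by block matching over a multiresolution
   pyramid with a robust similarity fit (20 iterations per level by
   default), and finished with one dense displacement-field pass for
   smooth residual deformation. All stages are merged into a single
   composite transform.
3. **Correlation and analysis.** The merged transform is applied once to
   the original full-precision tomography volume (pull-back,
   linear interpolation; nearest-neighbour for label volumes). Marker
   content is quantified per tissue with Otsu thresholds, and the scale
   component of the fitted similarity yields the specimen's linear
   shrinkage caused by ethanol dehydration before contrast staining.

## Coordinate and transform conventions

* Arrays are slice-major, `data[depth, row, column]`, matching TIFF
  stack page order. The world coordinate (um) of zero-based voxel
  index `(i, j, k)` is `origin + spacing * c(i, j, k)`. Spacing is
  isotropic by construction; anisotropic input is an error, never a
  silent resample.
* Transforms map **moving-space world coordinates to fixed-space world
  coordinates** (tomography is the moving modality, light-sheet the
  fixed one). All transforms are stored in micrometres, never voxels, so
  grids at 0.406 um and 1.22 um interoperate without special cases.
* Resampling pulls back: `output(x) = moving(T^-1(x))` for every
  reference voxel centre `x`. Similarity stages invert exactly;
  displacement-field stages invert by fixed-point iteration (at most 20
  sweeps, tolerance 0.01 voxel), with a warning and last-iterate
  fallback on non-convergence.
* A `CompositeTransform` applies right-to-left, like a matrix product;
  adjacent similarity stages are pre-multiplied into a single matrix
  when composed.
* Displacement fields live in fixed space as coarse lattices of
  3-vectors, interpolated trilinearly and extended with the clamped
  edge value outside the lattice; the zero field is the identity.

## Landmark initialisation

`estimateSimilarity()` uses the closed-form least-squares absolute
orientation solution (SVD of the paired cross-covariance, with scale).
It is deterministic, exact on exact data for any scale in [0.5, 2], and
requires at least 5 non-degenerate pairs -- fewer, or collinear
configurations, raise errors. If the SVD proposes a reflection the
smallest singular axis is flipped: landmark click errors must not
produce mirror registrations.

## Block-matching refinement

For each block of the fixed volume with enough intensity variance, the
best integer displacement within a search radius is found by exhaustive
normalized cross-correlation (NCC). NCC is the similarity metric because
the modalities share structure (nuclei, tissue boundaries) but not
intensity scale, and NCC is invariant to affine intensity maps. Ties
break deterministically: smallest displacement norm, then lexicographic.

A similarity transform is fitted to the correspondence field by
iterated trimmed least squares (drop the worst 25% by residual, refit,
until membership stabilises), composed with the current estimate, and
the loop repeats -- up to 20 iterations per pyramid level, coarse to
fine, each level binned by 2.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `blockSize` | 8 voxels | block edge length |
| `blockStride` | 8 voxels | lattice stride (also the dense-field node spacing) |
| `searchRadius` | 4 voxels | exhaustive integer search range |
| `iterations` | 20 | match/fit rounds per level |
| `varianceFloor` | 75th percentile | block eligibility threshold |
| `trimFraction` | 0.25 | robust-fit trimming |
| `pyramidLevels` | 3 | coarse-to-fine levels, binning by 2 each |

Design choices worth explaining:

* **Variance floor at the 75th percentile of block variances.** Most of
  a fluorescence volume is background; background blocks produce noise
  matches that a 25% trim cannot absorb. Keeping only the top quartile
  of blocks by variance restricts matching to textured specimen
  regions. (Blocks with essentially zero variance are always excluded:
  NCC is undefined there.) The floor is a plain parameter for data
  where a different fraction is appropriate.
* **Integer-displacement search only.** Sub-voxel accuracy comes from
  the pyramid and from least-squares averaging over many blocks, not
  from per-block peak interpolation, which is fragile on flat NCC
  surfaces. A consequence on small grids: once every residual block
  displacement rounds to zero, iteration cannot improve further, so the
  loop also stops when the fitted correction moves the domain corners
  by less than 0.05 voxel or when the mean displacement has not
  improved for 5 iterations.
* **Scale precision and grid size.** A scale error `e` moves a block at
  radius `r` voxels by `e * r`; integer matching cannot see it until
  `e * r > 0.5`. On desk-scale grids (a ~40-voxel specimen at
  tomography resolution) this bounds the recoverable scale at roughly
  2%, which is why the shrinkage analysis registers with the fixed
  volume at native fluorescence resolution (a 4-level pyramid supplies
  the coarse levels). On real acquisition grids (hundreds of voxels
  across) the bound is ~0.1% and registering at tomography resolution
  loses nothing.
* **Divergence is loud.** If the mean correspondence displacement grows
  (by more than 5%) three iterations in a row, or the median NCC drops
  to zero (no cross-modal agreement anywhere -- typically a
  non-overlapping initialisation), registration aborts with a
  diagnostic condition carrying the residual log, rather than returning
  a silently wrong transform.
* **The dense field runs once, after the similarity stage.** One
  block-matching pass on the block lattice gives a node vector field;
  Gaussian normalized convolution (sigma = 1 node) regularises it and
  fills textureless nodes from their neighbours. The stored vectors are
  oriented so that resampling through `composeTransforms(field,
  similarity)` reads each fixed voxel at its matched moving position
  (exact to first order in the field amplitude, which is a few
  micrometres at most for the smooth dehydration bulges this stage
  targets). Interleaving the field with the similarity iterations would
  let the non-rigid stage absorb errors the global stage should fix.

Registration is fully deterministic given its inputs; the only
randomness anywhere in the package is the seeded phantom generator.

## Quantification

The Otsu threshold is computed per channel on a 256-bin histogram over
`[min, max]` of the voxels inside the *combined* tissue labels (e.g.
retina plus brain); voxels outside the combined region never enter the
histogram. The exhaustive search maximises the between-class variance
`w0 w1 (mu0 - mu1)^2`; ties take the lowest cut (note a consequence: for
a perfectly bimodal sample with an empty gap, every separating cut ties
and the threshold lands just above the lower mode). The mask rule is the
strict `value > threshold`, so voxel counts are bit-reproducible. The
per-tissue fraction is `marker voxels / tissue voxels` -- a
dimensionless quantity, with tissue volume reported separately as
`voxels * spacing^3`. The fraction is invariant under affine monotone
intensity rescalings, which the tests verify with `x -> 2x + 7`.

Linear shrinkage is `(1 - 1/s) * 100` percent, where `s` is the scale of
the fitted moving-to-fixed similarity (`s > 1` means the stained
specimen is smaller than its fluorescence image). The scale factor is
exposed directly, so a volumetric convention `(1 - (1/s)^3)` can be
recomputed if preferred.

No hypothesis tests are attached to group comparisons: the comparisons
this supports are typically one specimen per phenotype, and fabricated
inference would misrepresent the data.

## The phantom generator

`generatePhantom()` builds a paired multimodal specimen with known
ground truth so every stage is testable without any external data:

* Ellipsoidal tissues (body, retina, brain, lens by default) on a
  128^3 fluorescence grid at 0.406 um; nuclei placed uniformly inside
  tissues and rendered as Gaussian blobs (radius 1.8 um, peak 100).
* Fluorescence channels render only marker-expressing nuclei. The
  default channel set includes a nuclear counterstain expressed by every
  nucleus -- as in real protocols, where a DAPI-class stain is imaged
  alongside the markers -- plus retina-specific, brain-specific and
  shared channels with expression probabilities 0.8/0.8/0.5. Channel
  values are rounded to uint16 with additive Gaussian noise
  (sigma 10 = SNR 10 against the blob peak).
* The tomography rendering shows *all* nuclei plus ~1 um tissue-boundary
  shells and a faint interior level -- dense, histology-like contrast.
  It is evaluated on its own ~3x coarser grid (1.22 um) by forward
  mapping each tomography voxel through the true transform, then
  corrupted with Gaussian noise.
* The true transform composes a similarity (default scale 0.795, i.e.
  20.5% linear shrinkage, the reported mean for dehydrated stained
  specimens; rotation 5 degrees; configurable translation) with an
  optional band-limited warp: at most 3 sinusoidal components, peak
  amplitude <= 5 um, component amplitude falling off as 1/frequency so
  the warp stays smooth and invertible.
* Ground-truth landmarks (tissue centroids plus interior points, at
  least 8) and a held-out landmark set are returned in both spaces,
  consistent with the composite transform to 1e-9.

One seeded stream drives everything; the caller's random state is saved
and restored, and a rerun with the same spec is bit-identical.

What the phantom does **not** emulate: optical point-spread anisotropy
and fusion artifacts of multiview acquisition, tomography
reconstruction artifacts (rings, beam hardening), intensity
inhomogeneity, partial labelling failures, and tearing or folding
deformations (the warp is smooth by design). Passing phantom tests
therefore demonstrates correctness of the algorithms under controlled
geometry and noise, not robustness to every acquisition pathology.

## Numerical choices

* 8-bit conversion clips at percentiles (0.5, 99.5) by default and
  rounds half-up -- deterministic across platforms; a constant volume
  maps to all zeros.
* Binning drops trailing partial blocks rather than padding, avoiding
  edge bias; the origin moves to the centre of the first block so world
  coordinates stay consistent.
* Block variance uses the population formula; eligibility requires
  variance at or above the floor and strictly positive.
* The robust fit trims to a fixed count `ceiling((1 - trim) * n)` from
  the full correspondence set each round, so membership oscillation
  cannot shrink the set.
* Degenerate inputs fail explicitly: constant Otsu samples, empty
  tissues, missing spacing metadata, collinear landmarks, sub-minimum
  landmark counts, crops outside the grid.

## Problem sizes used in the validation suite

The test-suite and the acceptance script exercise: transform recovery on
twenty 128^3-grid phantoms registered at tomography resolution;
shrinkage recovery on one 128^3 phantom registered at native
fluorescence resolution; the dense-field benefit on one 128^3 phantom
evaluated at half resolution within the body labels; oracle equivalence
on fifty 16^3 block-matching instances, fifty robust-fit fields and one
hundred Otsu histograms. These sizes keep a full run in the order of a
minute or two on one CPU while leaving each property genuinely
informative; all of them scale up by changing `PhantomSpec`.

## Known limitations

* The similarity stage assumes the initial landmark fit overlaps the
  volumes; there is no global search. Non-overlap aborts loudly.
* The dense field is a single-pass, heavily regularised correction for
  smooth residuals of a few micrometres; it cannot represent sharp or
  large deformations, and its node spacing ties it to the block stride.
* NRRD support covers the subset the pipeline writes (3D/4D, raw or
  ascii little-endian, isotropic spacings); oblique space directions
  are rejected.
* Shrinkage precision is quantization-limited by grid size (see above);
  at desk scale use native-resolution registration for scale readouts.
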