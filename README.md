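# voxalign

Correlative registration of light-sheet fluorescence microscopy and
X-ray microtomography volumes of the same specimen, with downstream
per-tissue marker quantification.

## The problem

Light-sheet microscopy shows *where genes are expressed* in a whole
small specimen (a fish embryo, an organoid) at sub-micrometre
resolution, but only the labelled structures are visible. Contrast-stained
X-ray microtomography of the same specimen shows *every* tissue with
histology-like detail, but carries no molecular information. Fusing the
two requires registering the tomography volume (the moving modality)
onto the light-sheet volume (the fixed modality) across a large
resolution gap (~1.22 µm vs ~0.4 µm voxels), different contrast
mechanisms, and an isotropic specimen shrinkage caused by the ethanol
dehydration that precedes contrast staining.

voxalign implements the full pipeline:

1. **Compression** — crop, block-mean binning of the fluorescence
   channels to the tomography voxel size, 8-bit conversion with robust
   percentile clipping, and summation of all channels into one
   structurally rich fixed volume.
2. **Registration** — a similarity transform `T(x) = s·R·x + t`
   (rotation `R`, isotropic scale `s`, translation `t`) estimated from
   ≥ 5 paired landmarks by the closed-form absolute-orientation
   solution, refined by block matching: for many fixed-image blocks the
   best integer displacement within a search radius is found by
   exhaustive normalized cross-correlation, a similarity is fitted to
   the correspondence field by iterated trimmed least squares (20
   iterations per pyramid level), and a final dense displacement field
   absorbs smooth residual deformation. All stages are merged into one
   composite transform.
3. **Correlation & analysis** — the merged transform is applied once to
   the original full-precision tomography data (pull-back convention,
   `output(x) = moving(T⁻¹(x))`). Marker content per tissue is
   quantified with Otsu thresholds computed inside the combined tissue
   labels (`fraction = marker voxels / tissue voxels`), and linear
   specimen shrinkage is read off the fitted scale as
   `(1 − 1/s) · 100 %`. Checkerboard composites and held-out-landmark
   target registration error (TRE) provide quality control.

A seeded phantom generator produces paired multimodal volumes
(ellipsoidal tissues, Gaussian-blob nuclei, sparse marker channels plus
a nuclear counterstain, dense tomography contrast, known
similarity + warp ground truth) so the whole pipeline is testable
without any external data.

## Worked example

```r
library(voxalign)

# a synthetic specimen: 96^3 fluorescence grid at 0.406 um, tomography
# at 1.22 um, 15% linear shrinkage, 6 degree rotation
spec <- phantomSpec(dims = c(96L, 96L, 96L), seed = 42,
                    shrinkageScale = 0.85, rotationAngle = 6,
                    translation = c(4, -3, 2), warpAmplitude = 0)
ph <- generatePhantom(spec)

# compression: bin channels to tomography resolution, sum, 8-bit
binned <- lapply(channels(ph$spim), binVolume, targetSpacing = 1.22)
fixed  <- sumChannels(MultiChannelVolume(binned))
ct8    <- to8bit(ph$ct)

# landmark initialisation (0.4 um click noise), then block matching
init <- estimateSimilarity(lmNoisy)       # lmNoisy: jittered landmarks
reg  <- registerSimilarity(fixed, ct8, init$transform, blockMatchParams())

targetRegistrationError(reg$transform, ph$truth$heldout)$mean
shrinkagePercent(reg$transform)
```

Output from this run:

```
landmark fit: scale 1.1893, RMS residual 0.83 um
landmark-only held-out TRE: 0.82 um
refined held-out TRE: 0.50 um (tomography voxel = 1.22 um)
estimated shrinkage: 15.2 % (phantom truth: 15.0 %)
```

The landmark fit alone leaves ~0.8 µm of error; block-matching
refinement brings the held-out TRE well under one tomography voxel, and
the scale component of the fitted similarity recovers the simulated
dehydration shrinkage to a fraction of a percentage point.

Marker quantification on the same phantom:

```r
ids <- labelTable(ph$labels)[c("retina", "brain")]
markerFraction(channels(ph$spim)$chanA, ph$labels, ids, ids["retina"], "chanA")
#>   tissue channel threshold marker_voxels tissue_voxels fraction volume_um3
#> 1 retina   chanA      46.8          2391          8939  0.26748        598
```

`chanA` is simulated as retina-specific: its fraction is 0.267 in the
retina and 0.005 in the brain, read off the same Otsu threshold
computed over the combined retina + brain region.

A shell entry point wrapping the same steps
(`simulate`, `compress`, `register`, `apply`, `quantify`,
`checkerboard`; YAML config, outputs plus config echo per run) is
installed at `inst/scripts/voxalign`.

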