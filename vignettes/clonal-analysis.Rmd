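---
title: "Volumetric clonal analysis of cleared mammary gland stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric clonal analysis of cleared mammary gland stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(clonemap3d)
```

## Background

Lineage tracing with a stochastic, low-frequency reporter asks a simple
question of a complicated image: what fraction of a mammary duct's
cellular volume descends from a single labelled founder cell?  In
cleared whole-gland confocal stacks the duct is a curved, branched tube;
the labelled clone is a ribbon of EYFP+ cells along it; and the luminal
(K8+) and basal (SMA+) lineages occupy the inner and outer layer of the
same bilayer.  `clonemap3d` implements the full measurement chain on 3D
multi-channel stacks, together with a synthetic stack generator that
provides voxel-level ground truth for validating every stage.

The reciprocal of the volumetric ratio carries the biological
conclusion: if a clone grown from one founder occupies a fraction $f$ of
the duct's cellular volume, then at least $1/f$ founders built the duct.

## The measurement chain

### 1. Duct segmentation

The duct is segmented from the K8 channel at a coarse level of a 3D
multiresolution (Haar) transform: block averaging suppresses
single-cell texture so the tube reads as one bright object, which a
robust threshold (median + 3 MAD) separates from the background.  The
coarse mask is upsampled and closed morphologically.  The z direction is
decomposed more shallowly than x/y in proportion to the voxel
anisotropy, so the effective physical scale is isotropic.

```{r duct, eval = FALSE}
sim <- simulate_stack(sim_config(seed = 1, target_label_fraction = 0.05))
k8 <- stack_channel(sim$stack, "K8")
duct <- segment_duct(k8, wavelet_params(coarse_level = 3))
duct
```

### 2. Significant (cellular) voxels

Within the duct, cellular voxels are distinguished from smooth
background by plane-wise FDR control on the fine Haar detail
coefficients of each z-plane: per sub-band p-values under a robust
Gaussian null (MAD-scaled), Benjamini–Hochberg adjustment across all
three detail bands, and expansion of each significant coefficient to
its 2×2 support.  On pure-noise planes the flagged fraction stays at
the nominal FDR level; on real texture it recovers the cellular
compartment.

```{r sig, eval = FALSE}
sig <- detect_significant_voxels(k8, duct, fdr_q = 0.05)
duct <- set_significant_mask(duct, sig)
```

### 3. EYFP+ cell detection

Cells are band-pass filtered with a difference of Gaussians matched to
the cell radius (sigma r/3 and 3r), thresholded at median + 3 MAD of
the filtered stack, cleaned of components smaller than a cell volume,
and clipped to the duct.  For the basal variant, touching elongated
cells are split by a seeded watershed: seeds are connected components
of the thresholded Euclidean distance transform, flooded on the negated
distance.  The seed threshold is the one genuinely manual parameter of
the original method; `seed_count_profile()` emits the seed-count-vs-
threshold curve used to choose it.

### 4. Luminal / basal classification

Each detected cell is called luminal or basal by a majority vote over
eight intensity thresholds (100 to 1500 by 200 on the 12-bit scale): at
each threshold the cell's voxels are counted against the K8 and the SMA
channel, the larger count wins (ties to basal, the dimmer marker), and
the majority across thresholds is the call.  Cells in regions where SMA
is undetectable (no signal in the dilated neighbourhood within the
duct) are excluded rather than guessed.

### 5. Quantification

The volumetric ratio divides the EYFP+ voxel volume by the duct's
cellular volume per duct region; the basal variant divides by the
SMA-significant basal compartment instead.  Distinct labelled regions
more than 1 mm apart count as separate clones (single-linkage grouping
on surface distances).  A two-sample KS test compares the K8 intensity
distribution inside EYFP+ cells against the whole duct, to ask whether
the label is enriched in the K8-high subpopulation.  Finally the
reciprocal of the mean ratio, floored to the nearest multiple of 5,
is reported as the minimum progenitor bound.

```{r worked}
# the two worked examples from the source publication's arithmetic:
min_progenitor_estimate(0.047)   # luminal: 4.7% -> at least 20
min_progenitor_estimate(0.058)   # basal:   5.8% -> at least 15
```

## The basal variant

Basal clones live in deep, noisy stacks of thin spindle-shaped cells,
and four things change:

1. **Restoration first**: Anscombe-stabilized Haar shrinkage denoising
   followed by Richardson–Lucy deblurring (30 iterations by default) on
   every channel.
2. **Union duct mask**: the duct is segmented from K8 *and* SMA and the
   masks are united, since a K8-only mask would clip away the outer
   basal layer under study.
3. **Watershed splitting** with a spindle-shaped minimum cell size
   (`elongated_detection_params()`).
4. **Basal denominator**: the ratio is taken against the SMA-significant
   compartment.

```{r basal, eval = FALSE}
res <- run_basal_variant(sim$stack)
```

## Validation against ground truth

The generator renders a branched duct tree with a luminal/basal bilayer,
clonal or scattered EYFP labelling at a target volume fraction, optics
(Gaussian PSF, depth attenuation), autofluorescence texture, and
Poisson-Gaussian noise — and returns the truth: per-cell registry,
voxel ownership map, and the realized labelled fraction.  The test
suite uses it to verify, among other things, that

- estimated ratios track true labelled fractions across 2–10%
  (parameter recovery),
- detected cells are classified to the correct lineage (fidelity),
- the FDR and KS machinery hold their nominal error rates on null data,
- the watershed splits touching ellipsoids into exactly two labels.

Known limitations, measured rather than hidden: per-true-cell detection
sensitivity for thin basal spindles is ~89% (sub-threshold after
restoration), and side-by-side spindles merged along a duct cannot
always be separated by distance-transform seeds.

## Reproducing the analysis

```sh
Rscript analysis/01_simulate_stacks.R
Rscript analysis/02_ductal_analysis.R
Rscript analysis/03_basal_variant.R
Rscript analysis/04_summary.R
```

writes stacks, reports, masks and the summary JSON under `results/`.
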