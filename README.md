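# clonemap3d

Volumetric clonal analysis of multi-channel 3D fluorescence stacks of
cleared mammary epithelium, with a ground-truth synthetic stack
generator for validating every stage.

## The science

In lineage-tracing experiments, a stochastic reporter labels rare
founder cells in the pubertal mammary gland; weeks later, each label
has grown into a clone — a ribbon of EYFP+ progeny along the ductal
tree. The gland is cleared, imaged as deep confocal stacks with three
channels (EYFP reporter, K8 marking the inner luminal layer, SMA
marking the outer basal layer), and the question is quantitative: **what
fraction of a duct's cellular volume does one clone occupy?** If a
single founder's clone fills a fraction *f* of the duct, at least
*1/f* founder cells built that duct — the volumetric ratio converts an
image into a lower bound on progenitor numbers.

The measurement chain implemented here:

1. **Duct segmentation** — the K8 channel at a coarse level of a 3D
   multiresolution (Haar) transform, thresholded at median + 3×MAD, so
   the duct reads as one tube rather than many cells. The z-axis is
   decomposed more shallowly in proportion to voxel anisotropy.
2. **Significant (cellular) voxels** — plane-wise FDR control
   (Benjamini–Hochberg, robust Gaussian null) on fine wavelet detail
   coefficients inside the duct, separating cellular texture from
   smooth background at a known error rate.
3. **EYFP+ cell detection** — 3D difference-of-Gaussians band-pass
   matched to the cell radius, robust threshold, minimum-size cleanup,
   clipped to the duct.
4. **Watershed splitting** (basal variant) — touching elongated cells
   split by a seeded watershed on the anisotropic distance transform;
   `seed_count_profile()` emits the seed-count-vs-threshold diagnostic
   that replaces the method's one manual choice.
5. **Luminal/basal classification** — per cell, a majority vote over
   eight intensity thresholds of "more K8 voxels or more SMA voxels?",
   with ties to the dimmer basal marker and a principled exclusion of
   cells in SMA-undetectable regions.
6. **Quantification** — volumetric ratio per duct region, KS comparison
   of K8 intensity distributions (is the label enriched in the K8-high
   subpopulation?), clone grouping at 1 mm separation, minimum
   progenitor bound (reciprocal ratio floored to the nearest 5), and
   alveolar occupancy counts for lactating-gland stacks.

The basal-clone variant additionally restores the deeper, noisier
stacks first (Anscombe-stabilized wavelet denoising, then
Richardson–Lucy deblurring), segments the duct as the **union** of the
K8 and SMA segmentations (a K8-only mask would clip off the basal layer
under study), and takes the ratio against the SMA-significant basal
compartment.

Because real cleared-gland stacks are not publicly deposited, the
package ships a generator of synthetic stacks — branched bilayered duct
trees, clonal or scattered labelling at a target volume fraction, PSF
blur, depth attenuation, autofluorescence texture, Poisson-Gaussian
noise — that returns voxel-level ground truth (per-cell registry,
ownership map, realized labelled fraction). All validation rests on it.

## Worked example

```r
library(clonemap3d)

sim <- simulate_stack(sim_config(seed = 1001, target_label_fraction = 0.05))
res <- run_ductal(sim$stack)
print(res)
```

Real output:

```
<pipeline_result> (ductal variant)
<duct_model> 105856 duct voxels, 85464 significant voxels
<cell_segments> 11 segments, 4747 voxels total
  calls: luminal=9, unclassified=2
<clone_report> 1 region(s): ratio 0.045 +/- 0.000 -> >= 20 progenitors (raw 22.3)
```

The generator placed a luminal clone occupying a true 4.74% of the
duct's cellular volume; the pipeline recovers 4.5% and reports the
bound "at least 20 progenitors" — the same arithmetic that turns a
measured 4.7% mean ratio into a minimum of 20 ductal progenitors, and
5.8% into 15 for the basal lineage:

```r
min_progenitor_estimate(0.047)
#> [1] 21.2766
min_progenitor_estimate(0.058)
#> [1] 17.24138
```

## Reproduction

Run the numbered drivers from the repository root (each writes to
`results/`):

```sh
Rscript analysis/01_simulate_stacks.R    # synthetic ductal/basal/scattered stacks + ground truth
Rscript analysis/02_ductal_analysis.R    # luminal-clone analysis -> results/ductal/
Rscript analysis/03_basal_variant.R      # basal variant + watershed seed diagnostic -> results/basal/
Rscript analysis/04_summary.R            # combined summary -> results/summary.json
```

The final summary from a full run:

```json
{
  "ductal_mean_ratio": 0.0448,
  "ductal_min_progenitors_bound": 20,
  "ductal_ks_direction": "hi-enriched",
  "ductal_clone_count": 1,
  "basal_mean_ratio": 0.1509,
  "basal_min_progenitors_bound": 5,
  "basal_clone_count": 1,
  "scattered_true_cells": 14,
  "scattered_detected_cells": 14,
  "scattered_recall": 1
}
```

The acceptance script computes the headline quantities (worked-example
bounds, parameter recovery, lineage fidelity, FDR/KS error control,
watershed splitting) into a single JSON file:

```sh
Rscript scripts/acceptance.R --seed 42 --out acceptance.json
```

## Tests

```r
# from the package root
testthat::test_dir("tests/testthat", package = "clonemap3d",
                   load_package = "installed")
```

The suite covers unit and property tests per module plus
`test-acceptance.R` with one block per acceptance criterion (worked
examples, brute-force oracle equivalence, parameter recovery across
labelled fractions 2–10%, lineage fidelity for both founder lineages,
FDR/KS statistical control, instance splitting).

Known, measured limitations (documented in the vignette): per-true-cell
detection sensitivity for thin basal spindles is ~89%, and side-by-side
spindles merged along a duct are not always separable by
distance-transform seeds. Calls that are made are lineage-faithful.

## Package layout

- `R/`, `src/` — the analysis pipeline and generator (Rcpp kernels for
  filtering, distance transform, watershed).
- `analysis/` — numbered workflow drivers; computation lives in the
  package.
- `scripts/acceptance.R` — headline quantities as JSON.
- `tests/testthat/` — unit, property, and acceptance suites.
- `vignettes/clonal-analysis.Rmd` — methods vignette.
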