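# demict

Dual-energy micro-CT two-material decomposition and tumor vascular
biomarkers in R.

## What it does

Lung tumors can be characterized functionally by their vasculature:
**fractional blood volume** (FBV, the perfused vascular volume fraction)
and **vascular permeability** (observed as extravascular nanoparticle
accumulation). With two long-circulating contrast agents — gold
nanoparticles injected two days before imaging and liposomal iodine
injected immediately before it — a *single* dual-energy CT scan yields
both: the iodine map measures FBV, the gold map measures accumulation.

Per voxel, measured attenuation at the two tube voltages is a linear
combination of the material concentrations,

    CT_40 = CT_I,40 * C_I + CT_Au,40 * C_Au
    CT_80 = CT_I,80 * C_I + CT_Au,80 * C_Au

with a 2×2 sensitivity matrix (HU per mg/mL) calibrated on vials of known
concentration; inverting it voxel-wise and projecting onto nonnegative
concentrations gives independent iodine and gold maps. Downstream:

    FBV        = C_tracer,tissue / C_tracer,blood     (immediately post-injection)
    C_Au,accum = C_Au,tot - FBV * C_Au,blood          (intravascular subtraction)

The package implements the full chain — calibration
(`fit_sensitivity()`), joint bilateral filtration
(`joint_bilateral_filter()`), constrained decomposition (`decompose()`),
gold-threshold tumor segmentation (`segment_tumors()`), biomarker algebra
(`fractional_blood_volume()`, `accumulated_gold()`, `blood_half_life()`),
comparison statistics, NIfTI-1 volume I/O, a JSON-configured pipeline
driver with CLI — plus a synthetic **digital mouse phantom**
(`mouse_phantom_spec()`, `build_phantom()`) that emulates the imaging
physics and physiology so that every stage is testable end to end without
scanner data.

## Worked example

A reduced-scale study: simulate the day-3 mixed-contrast scan of a 64³
phantom with 20 HU noise, filter, decompose, and quantify with the
single-scan two-material method:

```r
library(demict)
study <- phantom_study(n = 64, seed = 1, noise_sd = 20, method = "both")
subset(study$records, method == "two-material",
       select = c(roi, n_voxels, fbv, c_au_tot, c_au_accum))
#>        roi n_voxels   fbv c_au_tot c_au_accum
#> 9    liver     6043 0.324     3.21      1.370
#> 10  spleen      692 0.468     6.21      3.554
#> 11  kidney      628 0.323     2.73      0.901
#> 12 tumor_1      264 0.165     1.74      0.802
#> 13 tumor_2      114 0.167     1.67      0.726
#> 14 tumor_3       65 0.160     1.82      0.921
#> 15 tumor_4       40 0.176     1.71      0.716

blood_half_life(48, 0.54)   # h; blood at 54% of initial after 48 h
#> [1] 53.99515
```

Reading the table: the spleen FBV (0.468) and liver FBV (0.324) recover
their ground truth (0.44, 0.29) to within the pipeline's accuracy; the
four segmented tumors carry ~0.7–0.9 mg/mL accumulated gold against a
ground truth of 0.7. Tumor FBV (~0.16–0.18 vs truth 0.13) is inflated by
the un-subtracted tissue-baseline pseudo-concentration — a known,
quantified bias of the measured-attenuation workflow discussed in the
methods vignette (`vignettes/dual-energy-vascular-biomarkers.Rmd`).

The same pipeline is file-driven via `run_pipeline()` /
`pipeline_config()` or the CLI:

```sh
exec/demict run --config inst/extdata/demo_config.json
exec/demict calibrate --vials inst/extdata/vials.csv --out matrix.json
```

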