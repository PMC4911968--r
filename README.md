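# conjview

Planar kidney dosimetry in ¹⁷⁷Lu radionuclide therapy relies on estimating the
kidney activity concentration from 2D gamma-camera images, after subtracting a
background region of interest (ROI) that is supposed to represent the activity
in the tissue over- and underlying the kidney. Where that background ROI is
placed matters enormously: high-uptake organs (liver, spleen, tumours) sit
ventrally and cranially to the kidneys, so differently placed background ROIs
can over- or underestimate the true background severalfold, biasing the dose
estimate that decides whether a therapy cycle continues.

`conjview` is an R package for studying this problem quantitatively without
patient data. It

* builds labelled synthetic SPECT/CT torso phantoms with known ground-truth
  concentrations (kidneys ≈ 150 ml with elevated uptake, hot cranio-ventral
  liver/spleen surrogates, uniform soft-tissue background, Gaussian PSF blur,
  Poisson counting noise, 128×128×64 grid at 2.21×2.21×4.42 mm);
* converts CT Hounsfield volumes to 208 keV attenuation maps,
  μ = μ_w + HU·μ_w/1000, and forms attenuated anterior/posterior planar
  projections;
* constructs the analysis regions automatically: kidney VOI, body mask
  (5-count threshold), body-clipped column VOI, true-background VOI
  TB = column − kidney, ten 36°-sector background ROIs B1–B10 at a 2-pixel
  gap and 4-pixel width around the kidney silhouette, and the surrounding
  ROI B11 = B1 ∪ … ∪ B10;
* estimates the kidney activity concentration by the conjugate-view (ConjV)
  and posterior-view (PostV) methods,

  AC_ConjV = μ t_k √(A_net P_net) / [e^(−μ t_p/2) (e^(μ t_k/2) − e^(−μ t_k/2)) v_k]

  AC_PostV = (P_net / v_k) · e^(μ d_k) · t_k μ / (1 − e^(−μ t_k))

  with t_k the kidney AP thickness, t_p the patient AP thickness, d_k the
  back-to-kidney distance (all measured on the centroid transverse slice)
  and v_k the kidney volume;
* reports cohort statistics: background-to-true-background ratios (BTR),
  coefficients of variation, negative-net-count fractions (CNC for ConjV,
  PNC for PostV), relative concentrations against the volumetric SPECT-style
  reference, and paired two-sided t-tests between the methods, with ROIs
  admitted to the method comparison only when their negative-count fraction
  is ≤ 10%.

## Worked example

A 4-subject noiseless slab cohort (uniform background, every net count
positive) runs in a few seconds:

```r
library(conjview)
rep <- run_pipeline(pipeline_config(n_subjects = 4, seed = 11, phantom = "slab",
                                    psf_fwhm_mm = 0, poisson = FALSE))
subset(rep$fig4, roi == "B11")
#>  roi   side method mean_rel_ac cv_pct n p_value significant
#>  B11 kidney  ConjV   1.0420263      0 4       0        TRUE
#>  B11 kidney  PostV   0.9864863      0 4       0        TRUE
```

Both methods recover the SPECT reference within ~4% on this structure-free
control (`mean_rel_ac ≈ 1`; noiseless slab subjects are identical, hence
CV = 0 and a degenerate p value). The residual bias is real methodology, not
a bug: the background ROI samples tissue columns whose depth distribution
differs slightly from the over/underlying tissue of the kidney column, so
even a uniform background does not cancel exactly under attenuation. On the
default anatomical cohort, with the hot liver
surrogate at 5× kidney uptake, the picture changes to the clinically familiar
one: cranial background sectors overestimate the true background (BTR ≈ 3),
caudal sectors underestimate it (BTR ≈ 0.2), ConjV overestimates the kidney
concentration severalfold for most small ROIs, and PostV with the
surrounding ROI B11 is the most accurate combination:

```r
rep <- run_pipeline(pipeline_config(n_subjects = 20, seed = 1))
colMeans(abs(subset(rep$runs, bg_label == "B11",
                    c(rel_ac_conjv, rel_ac_postv)) - 1), na.rm = TRUE)
#> rel_ac_conjv rel_ac_postv
#>    0.6423007    0.1611421
```

## Command line

```sh
./exec/conjview run --config cfg.yaml --out results_dir
```

Subcommands `phantom`, `project`, `vois`, `quantify`, `report`, `run` expose
each stage; volumes are written as MetaImage (.mha), planar images and
reports as CSV, and the YAML config mirrors `pipeline_config()` (defaults:
threshold 5 counts, gap 2 px, width 4 px, 10 sectors, μ_w = 0.136 cm⁻¹).

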