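# ctiq — objective CT image quality from edge profiles and noise maps

`ctiq` is an R package for observer-independent image-quality evaluation of
computed tomography slices, built for comparing reconstruction techniques or
scanner generations (e.g. ultra-high-resolution vs. normal-resolution neck CT)
on the same footing. It implements three measurement families plus the
synthetic phantoms needed to validate them:

- **Edge sharpness.** A reader marks a straight segment along a tissue
  interface (typically the fat/muscle border). Ten gray-value profiles are
  sampled perpendicular to the marking over ±4.5 mm. For each profile the
  package estimates the upper and lower plateau baselines and the steepest
  slope of the transition over three consecutive samples (HU/mm, negative
  under the bright-to-dark traversal convention); medians over the ten
  profiles summarize the border.
- **Noise.** Transition pixels are masked by a gradient threshold; a 5 mm ×
  5 mm window slides over the remaining image; in each edge-free window a full
  second-order 2D polynomial `a + bx + cy + dx² + exy + fy²` is fitted and
  subtracted to remove low-frequency drifts, and the residual standard
  deviation is written to a noise map. The image noise is the smallest value
  in the map. SNR = upper baseline / noise, CNR = (upper − lower) / noise.
- **Dose and statistics.** DLP normalization to a reference scan length
  (`CTDIvol × L_ref`), effective dose via ICRP body-region factors
  (head/neck k = 0.0058 mSv per mGy·cm), and the reader-study statistics:
  two-way mixed consistency ICC(3,1) with agreement bands, Cohen's kappa,
  exact/tie-corrected Mann–Whitney, Welch t, and a KS normality screen that
  selects mean±SD vs. median/IQR reporting.

Everything is testable without patient data: `generate_edge_phantom()` builds
two-tissue slices whose steepest slope, baselines, transition width and noise
SD are known exactly, and companion generators produce rater tables and dose
cohorts with known structure.

## Worked example

```r
library(ctiq)

# a 40 x 40 mm phantom: muscle 50 HU / fat -100 HU, edge slope -150 HU/mm,
# white noise 6 HU, 0.5 mm pixels
ph <- generate_edge_phantom(phantom_spec(
  width_mm = 40, height_mm = 40, pixel_spacing_mm = 0.5,
  hu_high = 50, hu_low = -100, edge_slope_hu_per_mm = -150,
  noise_sd_hu = 6, seed = 17))

report <- evaluate_image(ph$image, phantom_border(ph$truth))
report
#> <ct_quality 'phantom_seed17'>
#>   median steepest slope: -151.2 HU/mm (distance -0.50 mm)
#>   baselines: upper 49.0 / lower -99.3 HU
#>   noise: 4.8 HU (map min over 3968 windows)
#>   SNR 10.2, CNR 31.0
```

The median steepest slope (−151.2 HU/mm) recovers the true −150 within 1%;
the baselines recover the 50/−100 HU plateaus within their standard error.
The noise value 4.8 HU is the *minimum* of the window-SD map and therefore
sits below the true 6 HU — `report$noise_note` quantifies that bias
(map median 5.76 HU, min/median ratio 0.83), which is why the pipeline CNR
(31.0) lands above the analytic contrast/noise = 150/6 = 25 by the inverse of
the same factor. `glance(report)` returns the one-row summary, `tidy(report)`
the ten per-profile analyses, and `plot_profiles()` / `autoplot()` draw the
profiles and the noise map.

Dose cohorts and reader agreement:

```r
co_nr  <- generate_dose_cohort(40, 14.0, 0.9, 25, 1.5, seed = 1)  # NR-like
co_uhr <- generate_dose_cohort(40, 10.0, 0.7, 25, 1.5, seed = 2)  # UHR-like
compare_dose(co_nr, co_uhr)[, c("cohort", "effective_dose_mean_msv", "reduction_percent")]
#>      cohort effective_dose_mean_msv reduction_percent
#> 1 reference                   2.042             28.51
#> 2       new                   1.460             28.51

tab <- generate_rater_table(40, 2, latent = rep(1:5, 8), disagreement_sd = 0.5, seed = 3)
icc_consistency(tab)
#> <ICC(3,1)> 0.907 (excellent), 40 items x 2 raters
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "ctiq.R", package = "ctiq")` with subcommands `simulate`,
`sharpness`, `noise`, `snr`, `dose`, `agree`, `all`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","ctiq.R",package="ctiq"))')" \
  dose --ctdivol 10 --reflen 25
#> DLP (at 25 cm): 250.0 mGy.cm
#> effective dose: 1.45 mSv
```

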