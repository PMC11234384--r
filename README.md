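# mcsquant

Quantification of fluorescence-microscopy readouts at ER–mitochondrial
membrane contact sites (ERMCS): object-based colocalization of
diffraction-limited puncta, proximity ligation assay (PLA) spot densities,
and dual-indicator Ca²⁺ responses.

## What it is for

IP₃ receptors (IP₃Rs) are ER Ca²⁺-release channels that appear as
diffraction-limited puncta in fluorescence images; their relationship to
partner proteins (such as the tether KRAP) and to mitochondria is
quantified with a small set of recurring image analyses. This package
implements those analyses as tested, reusable R functions for anyone
quantifying puncta-to-puncta association, protein proximity, or
indicator-based Ca²⁺ signals in single cells:

1. **Object-based colocalization.** Spots are segmented to intensity-weighted
   centroids; each reference punctum gets the nearest-neighbour
   centre-to-centre distance (nm) to the partner channel, and is classified
   colocalized when d < 233 nm (3 pixels at 77.7 nm/px, about the confocal
   lateral resolution). Significance comes from a within-cell permutation
   null: the partner field is shuffled uniformly over the cell mask (100×),
   and the observed colocalized fraction is compared to the 2.5–97.5
   percentile band of the shuffled fractions. For a chance fraction *p*
   from the null and observed fraction *obs*, the truly paired fraction is
   estimated as (obs − p)/(1 − p). Against the closed-form CSR expectation
   1 − (1 − πr²/A)ⁿ, the empirical null is verified to Monte-Carlo
   precision. Mask-restricted subsets (mitochondria-associated vs not)
   reuse the same machinery.
2. **Pixel-based colocalization.** Thresholded Manders split coefficients
   M1/M2 and a Costes-style block-scrambling P-value.
3. **PLA quantification.** Max z-projection → background subtraction →
   binarization → component counting with an area filter; nuclei counted
   from DAPI; results reported as spots per cell per field, compared
   across conditions by t-test / one-way ANOVA with Tukey /
   repeated-measures ANOVA with Bonferroni.
4. **Ca²⁺ traces.** ROI traces normalized to the saturated indicator
   signal (F/F_max); peak responses reported as ΔF/F_max = peak − baseline,
   with a flag when responses leave the linear-fluorescence regime
   (> 0.5 F_max).

A synthetic-data module generates scenes, PLA fields and trace pairs with
exact ground truth (colocalized fraction, mitochondrial fraction, spot
counts, ΔF/F_max), so the whole pipeline is validated end-to-end without
any external data.

## Worked example

Simulate one cell with known structure (30% of IP₃R puncta truly paired
with a KRAP punctum at a 50 nm offset, 25% of them on mitochondria), then
recover that structure through the full analysis chain:

```r
library(mcsquant)

spec  <- scene_spec(seed = 42, gaussian_sd = 2, poisson_scaling = 1)
masks <- make_cell_and_mito_masks(spec, mito_area_frac = 0.25)
gt    <- place_puncta(masks$cell, masks$mito, n_ref = 200, n_partner = 200,
                      f_coloc = 0.3, f_mito = 0.25, seed = 7)

bg <- mcs_mask({m <- matrix(TRUE, 256, 256); m[4:253, 4:253] <- FALSE; m},
               77.7, "background")
ip3r <- detect_puncta(subtract_background(
  render_channel(gt$ref$x_nm, gt$ref$y_nm, spec, 1000,
                 channel = "ip3r", noise_seed = 1), bg))
krap <- detect_puncta(subtract_background(
  render_channel(gt$partner$x_nm, gt$partner$y_nm, spec, 1000,
                 channel = "krap", noise_seed = 2), bg))
ip3r
#> <puncta_field> 200 puncta, channel 'ip3r', pixel 77.7 nm

mito  <- make_organelle_mask(subtract_background(
  render_mask_channel(masks$mito, spec), bg), cell = masks$cell)
parts <- subset_by_mask(ip3r, mito, dilate_px = 1)
# mitochondria-associated: 50 of 200 puncta (25.0%)

rt <- randomization_test(parts$inside, krap, masks$cell,
                         threshold_nm = 233, n_iter = 100, seed = 11)
rt
#> <rand_test_result> observed 0.400 vs null [0.060, 0.260] (100 shuffles): significant
chance_corrected_fraction(rt$observed_fraction, mean(rt$null_fractions))
#> 0.294
```

All 200 puncta are detected; the generated mitochondrial fraction (0.25)
is recovered exactly; the observed colocalized fraction of
mitochondria-associated puncta (0.40) lies far above the shuffle null
(chance alone gives ~0.14 at these densities), and correcting for chance
returns 0.294 — the generated truth was 0.3.

Three pipeline drivers bind the stages together from a single YAML-backed
configuration (`default_config()`, `run_coloc_pipeline()`,
`run_pla_pipeline()`, `run_calcium_pipeline()`); a thin command-line
wrapper lives at `inst/scripts/mcsquant`. Identical seeds give
byte-identical reports.

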