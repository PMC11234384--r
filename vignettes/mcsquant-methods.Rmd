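---
title: "Quantification methods in mcsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in mcsquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mcsquant quantifies three fluorescence-microscopy readouts that are central
to studying IP~3~ receptor (IP~3~R) function at ER--mitochondrial contact
sites: object-based colocalization of diffraction-limited puncta (e.g.
IP~3~R versus the tethering protein KRAP), proximity ligation assay (PLA)
spot densities, and dual-indicator Ca^2+^ responses normalized to the
saturated indicator signal. This vignette explains the models and
estimators behind each analysis, the defaults and why they were chosen,
and what the synthetic-data generator does and does not emulate.

## Object-based colocalization

Two spot channels are reduced to puncta fields: sets of centroids in
physical units (nm). For every *reference* punctum we record the Euclidean
centre-to-centre distance to its nearest *partner* punctum, and call the
pair colocalized when that distance is strictly below a threshold. The
default threshold is 233 nm -- three pixels at the default 77.7 nm pixel
size -- close to the lateral resolution of a confocal microscope: at
smaller separations two emitters cannot be resolved, so "colocalized"
operationally means "not resolvable as separate".

Distances are computed in nm, not pixels, so the threshold is independent
of magnification. The exact boundary case (distance equal to the
threshold) is *not* colocalized; the inequality is strict. Ties between
equidistant partners resolve to the lowest partner index, which makes the
output deterministic. The default search bins partners on a uniform grid
and expands rings outward; it is exactly equivalent to the exhaustive
all-pairs search (`method = "brute"`), which the test suite verifies on
random configurations.

The relation is directional: the nearest-KRAP-distance distribution of
IP~3~R puncta is not the mirror of the nearest-IP~3~R-distance
distribution of KRAP puncta. The package computes the direction you pass
in (`nearest_neighbour_distances(ref, partner)`); both directions are
available by swapping arguments, and reports should state which one they
used. The default orientation in `run_coloc_pipeline()` measures from the
reference (IP~3~R-like) channel to the partner (KRAP-like) channel.

Mitochondria-associated subsets are formed with `subset_by_mask()`: a
punctum is associated when its centroid pixel falls on the organelle mask,
optionally after dilating the mask by 1 px (the default) to absorb
centroid jitter at mask boundaries. "Association" by centroid-in-mask is a
deliberate, simple operationalization; overlap-area rules would need a
punctum-shape model the data do not provide.

### The shuffle null and significance

An observed colocalized fraction is only meaningful against the fraction
expected by chance at the same puncta densities. `randomization_test()`
shuffles the partner field uniformly over the cell mask (100 iterations by
default, the conventional count for this analysis), recomputes the
colocalized fraction each time, and takes the empirical 2.5th and 97.5th
percentiles of the null fractions as a 95% interval; the observation is
significant when it falls outside. Percentiles interpolate linearly
between order statistics (`quantile` type 7). The summarized null
statistic is the per-cell colocalized fraction; full null distance sets
can be retained (`keep_null_distances = TRUE`) for frequency-distribution
plots. Only the partner field is shuffled; shuffling the reference instead
is a matter of swapping arguments. Nuclei are not excluded from the
shuffle region by default, since the shuffle is defined "within the cell";
callers can pass any region mask.

For convex regions with negligible edge effects the null has a closed
form: with $n$ partners uniform over area $A$, a reference punctum whose
threshold disc lies inside the region is within $r$ of at least one
partner with probability $1 - (1 - \pi r^2 / A)^n$
(`csr_expected_fraction()`). The test suite checks the empirical null
against this form using reference points placed at least $r$ from the
region boundary, which removes the edge-loss term exactly rather than
approximating it.

The chance-corrected estimate of the truly paired fraction inverts
$\mathrm{obs} = f + (1 - f)\,p$, where $p$ is the null-mean chance
fraction: `chance_corrected_fraction()`. This assumes truly paired puncta
classify as colocalized with probability near 1, which holds when the
pairing offset is well below the threshold (at the generator default of
50 nm the Rayleigh tail beyond 233 nm is ~2e-5).

## Spot segmentation

The spot detector follows the standard blob-detection recipe: Gaussian
smoothing at the PSF scale (default sigma 100 nm), a global threshold at
mean + 3 sd of the smoothed image, connected-component labelling, and
splitting of merged components when they contain two or more local maxima
at least 3 px apart (non-maximum suppression keeps the brighter maximum;
split pixels join their nearest surviving maximum). Centroids are
intensity-weighted on the background-corrected image. Coordinates follow a
0-based pixel-centre convention: pixel index $p$ maps to $p \times$
pixel-size nm. This convention matters because the colocalization
threshold is length-based; it is applied consistently by the generator and
the detector, so sub-pixel positions round-trip.

The mean + k·sd threshold is parameter-light and deterministic but global:
it assumes roughly uniform background after background subtraction, and it
will miss dim puncta in images dominated by a few bright ones. The
defaults were calibrated on synthetic scenes only (the test suite requires
F1 >= 0.95 at SNR >= 10 and 6 px spacing); real images with uneven
illumination may need `k_sd` or `min_area_px` adjusted.

Background correction is the subtraction of the mean intensity over a
region outside the cell, clipped at zero (`subtract_background()`).
Organelle masks use Gaussian smoothing plus Otsu thresholding within the
cell, with a minimum-object-size filter. Nucleus counting is
connected-component counting after smoothing and Otsu; nuclei closer than
about one diameter merge and count as one -- a documented limitation
shared by any component-counting approach, and one reason PLA results are
reported per field rather than per cell.

## Pixel-based colocalization

`manders_split()` computes thresholded Manders split coefficients: M1 is
the fraction of channel A's supra-threshold intensity residing in pixels
where channel B is also supra-threshold, and symmetrically for M2. The
numerator is restricted to pixels above threshold in *both* channels; this
keeps both coefficients in [0, 1] (a one-sided numerator can exceed its
denominator when sub-threshold A intensity lies under B-positive pixels).
Thresholds default to per-channel Otsu within the analysis mask and are
always reported alongside the coefficients, since Manders values are only
interpretable relative to their thresholds. Both coefficients are
invariant under positive scaling of either channel.

`costes_pvalue()` scrambles channel A by permuting square pixel blocks and
reports the percentage of scrambles whose Pearson correlation with channel
B falls below the observed correlation. The default block edge of 5 px
exceeds the PSF full width at the default pixel size; blocks smaller than
the autocorrelation length would leave residual local correlation in the
null and make it anticonservative. Block permutation preserves the
marginal intensity histogram exactly. For a genuinely colocalized pair the
expected readout is 100%; under independence the value is approximately
uniform on [0, 100].

## PLA quantification

A field of view is quantified as: maximum z-projection, background
subtraction, binarization at mean + 4 sd, connected-component counting
with an area filter (2--100 px by default, removing single-pixel noise and
large aggregates), and nucleus counting on the DAPI channel. The reported
unit is spots per cell per field; fields are the replication unit for all
statistics, never pooled pixels or cells. A field with no detected nuclei
is an error and is excluded with a logged reason rather than scored 0/0.
At spot densities where spots overlap, component counting undercounts;
the generator's default minimum spot spacing keeps synthetic fields in the
resolvable regime, and the exactness tests apply only there.

## Ca^2+^ trace quantification

Traces are per-frame ROI means minus the per-frame mean of a background
region, clipped at zero. Each trace is normalized to F~max~, the
fluorescence of the Ca^2+^-saturated indicator measured during a terminal
saturation plateau (experimentally produced by saturating the indicator
pharmacologically at the end of the recording). Working in F/F~max~ units
makes responses comparable across cells and indicators; as long as
responses stay below about half of F~max~, fluorescence changes are
approximately linear in Ca^2+^ concentration, and `peak_delta()` raises a
linearity flag whenever the peak exceeds 0.5 so users know when that
assumption is strained.

Estimators were chosen for robustness to frame noise:

* **F~max~** is the mean of the top decile of the *lightly smoothed*
  (3-frame boxcar) plateau window. A raw top-decile estimate of a flat
  noisy plateau is biased upward by order 1.75 sd of the frame noise;
  smoothing first cuts that bias by ~sqrt(3) while keeping robustness to
  single-frame outliers. The window must contain the saturated signal: if
  its estimate falls below the maximum of the rest of the trace by more
  than 5%, the window is rejected as invalid.
* **Baseline** is the mean over the pre-stimulus window.
* **Peak** is the maximum of the 3-frame boxcar-smoothed response window.
  A raw per-frame maximum inherits a positive noise-selection bias
  (selecting the luckiest frame); smoothing trades a small curvature
  underestimate (~2% of the transient amplitude for the default kinetics)
  against that selection bias. The package's recovery tests bound the net
  bias below 0.01 and the RMSE below 0.03 in F/F~max~ units across 1--5%
  noise.

Windows are specified by frame index because stimulus and saturation
times are experimental metadata, not inferable from the trace. No
bleaching or drift correction is applied; `check_baseline_drift()` warns
when the baseline slope exceeds a configurable bound. Quantification of
one channel never reads the other channel, mirroring the experimental
requirement of no spectral bleed-through.

## Group statistics

`compare_groups()` reproduces the conventional reporting toolkit: group
mean, sd and sem; two-tailed Student's t-tests (classical equal-variance
by default, matching the conventional naming, with Welch as an option);
one-way ANOVA with Tukey's multiple comparisons for more than two groups;
and repeated-measures one-way ANOVA with Bonferroni-adjusted paired
comparisons for matched designs. Matched designs require complete blocks:
every replicate contributes every condition. Significance is judged at
alpha = 0.05.

## The synthetic-data generator

Every analysis is validated on generated data with known ground truth.
The generator emulates the statistical structure the analyses rely on:

* **Geometry**: a smooth star-convex cell; a mitochondrial network built
  from dilated random-walk tubules (~4 px wide) covering a controllable
  fraction of the cell area (default 0.25). Any tubular texture with a
  controllable area fraction serves; no claim of biological realism is
  made for the network topology.
* **Puncta**: `n_ref` reference and `n_partner` partner puncta; a fraction
  `f_coloc` of references receives a partner at a Gaussian sub-resolution
  offset (sd 50 nm, truncated at 3 sd so all true pairs stay below the
  233 nm threshold); a fraction `f_mito` of references is constrained to
  the mitochondrial mask, with the remainder excluded from a 3 px
  neighbourhood of it so the generated fraction is crisp. A minimum
  same-channel spacing (default 6 px) keeps puncta individually
  resolvable. Pair counts are exact by construction:
  `round(f_coloc * n_ref)`.
* **Rendering**: each punctum is a discrete Gaussian (sd 100 nm) whose
  mass equals its amplitude, so integrated intensity is conserved; noise
  is Poisson shot noise plus Gaussian read noise, the standard camera
  model.
* **PLA fields**: disjoint nuclear discs plus a spot count drawn
  Poisson(mean spots per cell x number of cells), the natural counting
  model for independent interaction sites.
* **Ca^2+^ traces**: baseline at `baseline_frac` of F~max~, a
  double-exponential stimulus transient peaking at `peak_frac` (the
  sampled peak is normalized to hit `peak_frac` exactly, so ground truth
  is exact), then a step to the F~max~ plateau, plus Gaussian noise.

Puncta densities per cell are not well constrained by published data;
the defaults (100--500 per cell, 200 in the validation scenes) are
plausible placeholders exposed in the configuration. What passing tests
show is that the estimators recover known structure *under this model*:
diffraction-limited spots on a dark, background-subtracted interior,
spatially uniform noise, no deconvolution artefacts, no z-structure, no
photobleaching. They do not certify performance on images that violate
those assumptions (dense overlapping puncta, strong autofluorescence,
uneven illumination), and 3-d analysis is out of scope throughout.

## Determinism and problem sizes

Every stochastic stage takes an explicit seed; pipeline runs fan a single
global seed out through a counter scheme, so identical configurations
yield byte-identical reports, which the test suite checks by hashing
outputs of repeated runs. The validation suite uses 256x256 px scenes
(≈20x20 µm at 77.7 nm/px) with 200 puncta per channel, 50 scenes per
condition for recovery checks, 200 null scenes for type-I calibration,
100 PLA fields for counting exactness and 100 traces for Ca^2+^ recovery
-- sizes chosen so the whole validation runs comfortably on a laptop while
keeping Monte-Carlo error well below the tolerances being checked.

## Known limitations

* Global thresholds (mean + k·sd, Otsu) assume reasonably uniform
  background within the analysis region.
* Component counting merges touching nuclei and overlapping PLA spots.
* The chance-correction formula assumes near-perfect classification of
  true pairs; with pairing offsets approaching the threshold it would
  underestimate the paired fraction.
* The Costes null needs blocks larger than the autocorrelation length;
  with very small cells or large PSFs too few blocks remain for a stable
  percentage.
* Repeated-measures designs require complete blocks; unbalanced matched
  data need a mixed-model treatment that is deliberately out of scope.
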