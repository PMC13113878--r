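---
title: "Quantifying stress-granule formation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress-granule formation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgquant)
```

## The measurement problem

Acute oxidative stress — for instance exposure of bronchial epithelial
cells to cigarette-smoke extract — activates the integrated stress
response: eIF2&alpha; is phosphorylated, translation initiation stalls,
and untranslated mRNA condenses with RNA-binding proteins such as G3BP1
into cytoplasmic stress granules (SGs). Two complementary quantities
describe this response in confocal immunofluorescence images:

* **Cluster analysis.** Bright G3BP1 puncta are segmented and counted per
  region of interest (ROI, one confocal field treated as one biological
  sample). Each granule contributes its area in µm², its mean
  fluorescence, and its cumulative (integrated) fluorescence; summing
  cumulative fluorescence over all granules measures the total G3BP1
  sequestered into SGs in that ROI.
* **Nucleus-based analysis.** DAPI defines the nuclear mask; everything
  else in a fully cell-covered field is cytoplasm. The cytoplasmic
  cumulative intensity is the ROI total minus the summed nuclear
  contribution — an exact identity, not an estimate — and the mean
  cytoplasmic intensity is that quantity divided by the cytoplasmic area
  in µm². This is the readout used for diffuse markers such as
  p-eIF2&alpha;.

Because deposited raw images are not available for this kind of
experiment, every stage of the pipeline is validated against synthetic
ROIs with exact ground truth; the generator is first-class, tested code.

## The synthetic ROI generator

`generate_roi()` emulates a confocal field fully occupied by an
epithelial monolayer at the acquisition geometry of a laser-scanning
confocal: 1024 × 1024 pixels at 0.1 µm/pixel by default (0.06 µm/pixel is
supported for higher-sampling instruments).

**Nuclei** are non-overlapping ellipses with semi-axes drawn uniformly in
2.5–4.5 µm, tiled until 15–25 % of the frame is nuclear. Nuclear geometry
is not constrained by any reported measurement; the values are chosen to
resemble an epithelial monolayer at confluence. DAPI amplitude varies
±15 % between nuclei.

**The marker channel** is a sum of three exactly bookkept terms:

1. a constant additive background everywhere (autofluorescence plus
   nonspecific antibody binding). Its default level solves
   `bg / (diffuse_vehicle + bg) = 0.45`, i.e. the background is 45 % of
   the vehicle-condition mean cytoplasmic signal — the empirically
   measured combined background fraction for this staining system (the
   autofluorescence-only fraction is ~35 %);
2. a diffuse cytoplasmic level, the vehicle level (100 a.u.) times the
   condition's fold change, restricted to the non-nuclear area (G3BP1 is
   not nuclear);
3. planted granules, rendered as **hard disks of uniform extra
   amplitude** rather than Gaussian spots. Hard disks make the planted
   area and intensity exact, so segmentation recovery can be tested
   pixel-for-pixel; an optional Gaussian point-spread blur (σ in µm,
   default 0.1 when enabled) is available for realism, and is off by
   default precisely to keep ground truth exact.

The granule count per ROI is drawn from a zero-truncated Poisson with the
condition's mean and recorded exactly; per-granule areas are lognormal
with the condition mean and a CV of 0.25 (a modest, realistic spread that
keeps the distribution mean exactly at the preset value). Granule centres
are placed uniformly over the cytoplasm by rejection sampling with a
minimum centre separation of one summed radius plus two pixels (capped at
10 000 attempts per granule), so planted disks never touch: merges in the
recovered label image can then only come from the segmentation itself,
which is what the watershed tests need to isolate. Disks are kept clear
of nuclei entirely (a stronger condition than only their centres being
cytoplasmic) so that nuclear exclusion during segmentation cannot clip
planted objects.

**Noise** is photon-like Poisson on the total signal followed by additive
Gaussian read noise (default SD 2 % of the condition's diffuse level),
after which intensities are rounded to integers and clipped to the 16-bit
range. Integer-valued images make the nuclear/cytoplasmic conservation
identity testable bit-exactly.

**Granule contrast** — the disk amplitude relative to the diffuse
cytoplasmic level — is not constrained by any reported measurement. It
defaults to 3× the condition's diffuse level and is exposed in the
configuration (`granule_contrast`); the recovery results reported by the
acceptance tests hold comfortably at this contrast and degrade only when
granules approach the noise floor.

### Condition presets

`preset_registry()` fixes the generator's per-condition statistics at the
reported condition means for this exposure system:

| condition | #SG/ROI | mean area (µm²) | cytoplasmic fold | P(form) |
|-----------|--------:|----------------:|-----------------:|--------:|
| vehicle (0 %)  | 0  | —    | 1.0 | 0   |
| 7.5 % / 2 h    | 50 | 1.33 | 2.0 | 0.6 |
| 15 % / 2 h     | 87 | 1.42 | 4.0 | 1   |
| 30 % / 2 h     | 73 | 0.82 | 2.5 | 1   |
| 50 % / 2 h     | 42 | 0.49 | 1.8 | 1   |
| 15 % / 1 h     | 82 | 1.09 | 2.5 | 1   |
| 15 % / 4 h     | 71 | 1.19 | 3.0 | 1   |
| 15 % / 6 h     | 54 | 1.12 | 2.0 | 1   |

Notes on three deliberate choices:

* The 15 %/2 h condition appears in both the concentration series and the
  time series of the underlying characterisation, with slightly different
  means (87 vs 85 granules; 1.42 vs 1.34 µm²) — ordinary
  between-experiment variation. The registry carries the
  concentration-series values for this cell and represents the 2 h time
  point with the same preset.
* 7.5 % is a borderline concentration: granules form in roughly three of
  five experiments, encoded as `formation_probability = 0.6`. An ROI that
  fails to form has exactly zero granules.
* The cytoplasmic fold is reported only at its peak (≈4-fold for
  p-eIF2&alpha; at 15 %/2 h), with the statement that it decreases
  gradually at higher concentrations and longer times. The intermediate
  folds in the table are calibrated once to that qualitative profile
  (monotone on either side of the peak) and are not revisited.

### What the generator does not emulate

Real SGs are irregular, sometimes lobed; real cytoplasm is textured by
organelles; illumination is never perfectly flat; real fields contain
debris and out-of-focus light; granule brightness varies. Passing
recovery tests on these synthetic ROIs therefore demonstrates that the
*measurement chain* (thresholding, watershed, per-object accounting,
compartment segregation) is correct and unbiased at realistic densities
and noise levels — not that segmentation of any particular real dataset
is error-free. The semi-automated absolute-threshold entry point exists
exactly because real data need a human in the loop.

## Segmentation

Both masks are intensity-threshold based, mirroring standard
semi-automated practice.

* **Nuclei:** Otsu threshold on the whole DAPI frame → fill holes →
  remove components below `min_nucleus_area` (default 10 µm²) → label. A
  constant DAPI image has zero dynamic range and yields zero nuclei with
  a warning rather than an arbitrary mask.
* **Granules:** threshold on the marker channel, restricted to the
  non-nuclear area; components below `min_granule_area` (default
  0.04 µm², 4 pixels at 0.1 µm) are removed; touching objects are split
  by a watershed on the Euclidean distance transform.

The default granule threshold is Otsu computed on the *cytoplasmic*
pixels only, with a robust floor: foreground must also exceed the
cytoplasmic median + 5 MAD. The floor is what makes vehicle-condition
images behave correctly: with no granules present, Otsu would happily
split the noise distribution in half, whereas the median + 5 MAD floor
leaves at most a handful of isolated noise pixels, which the minimum-area
filter then removes — so diffuse-only images yield exactly zero granules
under the defaults. A fixed absolute threshold can be supplied instead to
reproduce a manually chosen cutoff, and a threshold above the image
maximum yields zero granules rather than an error.

**Watershed parameters.** Peaks of the distance transform are merged
within `min_peak_separation` (default 0.3 µm — safely below the ≈0.4 µm
radius of the smallest condition-mean granules) and within a depth
tolerance of 0.5 distance-map pixels. The tolerance was chosen from
geometry: for two equal disks of radius r whose centres are 1.2 r apart,
the saddle of the distance transform sits ≈0.2 r below the two peaks
(>0.5 px for any granule this pipeline should split), while a single
digitised disk's distance transform fluctuates by well under 0.5 px, so
lone disks are never fragmented. Removing the watershed can only merge,
never create, objects — a monotonicity the test suite asserts.

Granules touching the frame edge are kept and flagged rather than
discarded; areas are always pixel count × pixel-size², and coordinates
are 0-based pixel indices.

## Quantification conventions

* "Mean fluorescence per SG averaged over all SGs" is the **unweighted
  mean of per-granule means** — each granule votes once, regardless of
  size — matching the two-step phrasing of the definition. The
  pixel-weighted alternative would be `total_cumulative_sg / total
  granule pixels` and is not what is reported.
* Intensities stay in native arbitrary units; no flat-field, bleaching or
  background subtraction is applied inside the metrics (acquisition-side
  control is assumed, and the background correction below is a separate,
  explicit step).
* `nuclear + cytoplasmic = total` cumulative intensity holds exactly (on
  integer images, bit-exactly), and all ROI aggregates equal brute-force
  recomputation from the per-granule table; both are asserted in the
  tests rather than assumed.

## Dose model

The biologically effective exposure variable is the volume of 100 %
extract each cell receives: `dose_per_cell = (pct/100) × volume /
n_cells`. The 100 % stock itself is defined spectrophotometrically (an
optical density of 0.65 at 320 nm is 100 %; denser stocks read above
100 %). Equal per-cell dose, not equal percentage, predicts equal granule
formation across plating formats: `match_exposure()` solves for the free
variable (extract percentage at fixed volume, or volume at fixed
percentage) to keep the dose constant, refusing percentage solutions
above 100 %. The worked in-dish exposure (15 % of 1000 µL over 1.5 × 10⁵
cells → 10⁻³ µL/cell) is about five times the per-cell dose of smoking a
single cigarette (10 mL of stock over ~5 × 10⁷ airway epithelial cells →
2 × 10⁻⁴ µL/cell). That airway cell count is an expert estimate, not a
validated constant; it is a default, not hard-wired.

## Background correction of fold changes

Quantitative immunofluorescence underestimates fold changes because a
condition-independent additive background (autofluorescence plus
nonspecific binding) inflates both group means. With the background
expressed as a fraction `b` of the vehicle mean, subtracting the same
constant from numerator and denominator gives

`corrected_fold(f, b) = (f − b) / (1 − b)`

which is the identity at `b = 0`, fixes `f = 1`, and is strictly
increasing in `b` for any true increase. At the measured `b = 0.45`, a
measured 3.5-fold becomes (3.5 − 0.45)/0.55 ≈ 5.55-fold — moving the
imaging estimate into the 5–7-fold range that immunoblotting reports for
the same biology. Note the arithmetic ceiling: with these inputs the
formula cannot produce more than ≈5.5, so claims of a still larger
corrected fold require either a larger measured fold or a larger
background fraction than these defaults. A measured fold below `b` means
the signal sits below the background estimate; the function warns and
returns the non-positive value rather than silently clamping.

## Statistical layer

* **ROUT (robust regression and outlier removal), one-sample form.** The
  centre is fitted by iteratively reweighted least squares with
  Lorentzian weights `1/(1 + (r/s)²)`; the robust residual SD is the
  68.27th percentile of the absolute residuals with an `n/(n−1)`
  correction for the one fitted parameter; each point's `|r|/s` is a t
  ratio on `n − 1` df; and a false-discovery-rate step-up at rate Q
  (default 1 %) scans from the most extreme residual inward. At least 5
  values are required — below that the percentile scale estimate is
  meaningless. Flags are invariant to affine rescaling. Only the location
  form is implemented; the regression form is out of scope. Outlier
  removal is applied per group *before* testing, mirroring how the
  figure-legend bookkeeping reports "outliers identified and excluded".
* **Kruskal–Wallis + Dunn.** The tie-corrected H statistic comes from
  `stats::kruskal.test()`; Dunn's z on mean ranks uses the tie-corrected
  pooled variance, with a Bonferroni adjustment over the compared pairs.
  Which Dunn multiplicity variant "the recommended Dunn's test" refers to
  is not specified anywhere authoritative; this package uses the
  classical Dunn–Bonferroni family (not a Holm step-down), and the
  comparison set — all pairs versus each-vs-control — is an explicit
  switch, defaulting to all pairs.
* **Welch's t** (`stats::t.test`, unequal variances), **Welch ANOVA**
  (`stats::oneway.test`) and the **Brown–Forsythe F\*** (between-group
  sum of squares over `Σ(1 − nᵢ/N)sᵢ²`, Satterthwaite df — implemented
  here, as no installed package provides the means-ANOVA form) are
  reported together for ≥3 heteroscedastic groups; the two-sample
  **Kolmogorov–Smirnov** test delegates to `stats::ks.test` (exact p for
  small tie-free samples).
* Degenerate inputs are results, not errors: identical groups give
  H = 0/t = 0/D = 0 with p = 1.
* Every report carries mean ± SEM per group (SEM = SD/√n), a
  Shapiro–Wilk normality screen that is *reported but never used to
  auto-switch tests* (test choice is explicit), and the N-vs-n
  bookkeeping slot (N independent experiments, n technical replicates,
  n = N × replicates per experiment; each ROI is one biological sample).

## Problem sizes and determinism

Every stochastic stage takes an explicit integer seed and is bit-
reproducible: identical (preset, geometry, seed) gives identical images,
ground truth, and downstream tables; `run_pipeline()` derives one seed
per ROI from its base seed and records them, with the configuration hash,
in the run log. The validation suite exercises: full-frame (1024²)
recovery over 30 seeded ROIs per condition for the count/area claims;
generator expectations over 100 seeds at 512²; the condition-ordering
study over six conditions × 8 ROIs at 1024²; and 100 random fixtures per
statistical test against independently coded references (enumeration for
exact KS p values, brute-force prefix scans for ROUT). These sizes were
chosen so each claim's Monte-Carlo error is several times smaller than
the tolerance it is tested at.

## Known limitations

* No 3D stacks, time-lapse disassembly kinetics, or optics beyond the
  optional Gaussian blur; no per-cell cytoplasm instances (the whole
  non-nuclear field is one cytoplasmic compartment, which is only valid
  for fully cell-covered ROIs); no machine-learned segmentation; no
  colocalization metrics.
* Cumulative metrics use native intensities; whether they should be
  background-subtracted first is a judgement call this package leaves to
  the explicit correction step.
* The Dunn variant and comparison set, and the exact manual thresholds of
  any particular semi-automated analysis, are unknowable from the outside;
  both are exposed as configuration rather than guessed silently.
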