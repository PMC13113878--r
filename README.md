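# sgquant

Quantitative stress-granule (SG) image analysis for multi-channel
confocal immunofluorescence, with a synthetic ground-truth generator that
makes every stage of the pipeline testable without real data.

When epithelial cells meet an acute oxidative stressor (the motivating
system is bronchial epithelium exposed to cigarette-smoke extract), the
integrated stress response phosphorylates eIF2α and G3BP1-positive
stress granules condense in the cytoplasm. Two standard readouts
quantify this in 2D confocal fields ("ROIs", each treated as one
biological sample):

* **Cluster analysis** — segment the bright G3BP1 puncta (Otsu on the
  cytoplasmic pixels plus a median + 5·MAD robust floor; watershed on the
  distance transform to separate touching puncta) and report, per ROI:
  the SG count, SG size in µm², the mean G3BP1 fluorescence per SG
  averaged over SGs, the cumulative (integrated) fluorescence per SG, and
  the total cumulative fluorescence over all SGs — the total sequestered
  G3BP1.
* **Nucleus-based analysis** — mask nuclei from DAPI and segregate
  compartments exactly: `cytoplasmic = total − nuclear` cumulative
  intensity, and mean cytoplasmic intensity = cytoplasmic cumulative /
  cytoplasmic area (µm²). Used for diffuse markers such as p-eIF2α.

Around these sit the pieces a full study needs: exposure-condition
presets, smoke-extract dose arithmetic (`dose_per_cell = pct/100 ×
volume / n_cells`, constant dose-per-cell rescaling, concentration from
OD₃₂₀ with 0.65 ≡ 100 %), an additive background correction for fold
changes (`(f − b)/(1 − b)`), and the statistical layer: ROUT outlier
removal (Q = 1 % default), Kruskal–Wallis with Dunn's post hoc z tests,
Welch's t, Brown–Forsythe and Welch ANOVA, two-sample
Kolmogorov–Smirnov, and immunoblot normalization.

The package is aimed at cell-biology labs doing quantitative IF of
punctate structures who want their measurement chain validated against
planted ground truth rather than taken on faith.

## Worked example

Simulate one full-frame ROI of the peak-formation condition (15 %
extract, 2 h), segment it, and quantify both analyses:

```r
library(sgquant)

sim <- generate_roi(sg_preset(15, 2), seed = 42)   # 1024x1024, 0.1 um/px
nuc <- segment_nuclei(sim$roi$channels$DAPI)
gr  <- segment_granules(sim$roi$channels$G3BP1, nuc)
cm  <- cluster_metrics(sim$roi$channels$G3BP1, gr)
nq  <- nucleus_based_metrics(sim$roi$channels$G3BP1, nuc)

nuc
#> <nucleus_mask> 68 nuclei, 2549.8 um2 nuclear area (threshold 315.8)
gr
#> <granule_labels> 93 granules (5 at frame border), threshold 1046
cm$summary
#>   sg_count mean_sg_area mean_of_mean_intensity mean_cumulative_per_sg
#> 1       93        1.337                   1682                 224955
#>   total_cumulative_sg
#> 1            20920844
nq
#> <cytoplasm_quant> total 4.181e+08 = nuclear 2.086e+07 + cytoplasmic 3.973e+08;
#>   mean cytoplasmic 5.006e+04 a.u./um2 over 7936 um2
sim$truth$granule_count
#> [1] 93
```

This ROI's ground truth planted 93 granules (a Poisson draw around the
preset mean of 87) and the cluster analysis recovered all 93; the mean
recovered area (1.337 µm²) sits by chance a little under the preset mean
of 1.42 µm². The nucleus-based sums obey `nuclear + cytoplasmic = total`
exactly.

The surrounding arithmetic in one breath:

```r
dose_per_cell(15, 1000, 1.5e5)   # uL of 100% extract per cell
#> [1] 0.001
corrected_fold(3.5, 0.45)        # background-corrected fold change
#> [1] 5.545455
kruskal_wallis_dunn(list(`15` = c(4.1, 4.3, 3.9, 4.4),
                         `50` = c(1.7, 1.9, 1.8, 2.0),
                         `30` = c(2.4, 2.6, 2.5, 2.7)))
#> <test_report> Kruskal-Wallis / Dunn
#>   H = 9.84615
#>   p(kruskal_wallis) = 0.007277
#>   comparisons:
#>  group1 group2      z    p_raw    p_adj
#>      15     50  3.138 0.001702 0.005106
#>      15     30  1.569 0.116664 0.349993
#>      50     30 -1.569 0.116664 0.349993
#> ...
```

`run_pipeline()` chains simulation (or a directory of TIFFs with JSON
sidecars), segmentation, quantification and the group comparison into
one deterministic, logged run; a thin command-line wrapper lives at
`inst/cli/sgquant-cli.R` (subcommands `simulate`, `dose`, `run`).

The methods vignette (`vignettes/sgquant-methods.Rmd`) documents the
generator's condition presets, the threshold and watershed parameter
choices, the correction algebra and the statistical conventions.

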