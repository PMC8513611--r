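# colonyquant

Quantitative image analysis of micropatterned human pluripotent stem-cell
colonies ("2D gastruloids") for researchers studying self-organized
germ-layer patterning and TGFβ-family signaling.

When hESCs confined to 500 µm adhesive discs are stimulated with BMP4,
they pattern into concentric domains — a central SOX2⁺ ectoderm, a BRA⁺
mesodermal ring and a CDX2⁺ extraembryonic-like edge — and the geometry of
this pattern (domain areas, signaling-ring widths, fractions of responding
nuclei, receptor placement relative to the apical ZO-1 plane, reporter
dynamics) is the quantitative phenotype. `colonyquant` implements the full
measurement pipeline from raw image tiles to those numbers, plus a
synthetic-scene generator with exported ground truth so every stage is
testable without experimental data.

## What it computes

| readout | functions |
|---|---|
| field assembly and background correction | `stitch_tiles()`, `correct_background()` |
| colony detection, exclusion, extraction | `detect_colonies()`, `filter_colonies()`, `extract_colony()` |
| nuclear segmentation and per-cell medians | `find_nucleus_seeds()`, `segment_nuclei()`, `extract_cell_table()`, `segment_colony_cells()` |
| positive-cell calling | `normalize_to_dapi()`, `fit_binary_threshold()`, `classify_positive()` |
| radial profiles and ring width | `radial_profile()`, `ring_width()`; width = analysis radius − innermost stable half-max crossing |
| centre vs edge, fractions, secretor range | `center_edge_summary()`, `fraction_positive()`, `secretor_proximity()` |
| three-domain segmentation and area change | `segment_domains()`, `domain_areas()`, `relative_central_change()` |
| apical surface and signed distances | `interpolate_apical_surface()`, `distance_to_apical()`, `compare_polarity()` |
| time-lapse radius and N:C traces | `reporter_radius_trace()`, `nc_ratio_trace()`, `summarize_nc_cohort()` |
| TEER, ΔΔCt, group tests, orchestration | `teer_unit_area()`, `qpcr_fold_change()`, `compare_groups()`, `run_pipeline()` |
| synthetic scenes with ground truth | `scene_spec()`, `generate_colony_image()`, `generate_multicolony_field()`, `generate_transwell_field()`, `generate_zstack()`, `generate_timelapse()` |

Cells are called positive for a marker by dividing each nucleus' median
intensity by its median DAPI, fitting a two-Gaussian model for QC, and
cutting at Otsu's threshold — strictly above is positive. All ring widths
and inhibition ranges are half-maximum crossings of radial (or
distance-to-secretor) profiles, linearly interpolated between bin
centres.

## Worked example

Simulate an activin-response colony whose cells at radial positions
≥ 170 µm activate nuclear signaling (an 80 µm edge ring on an r = 250 µm
colony), then recover that geometry with the pipeline:

```r
library(colonyquant)

sp <- scene_spec(seed = 42,
                 channel_models = list(pSMAD1 = chan_ring(170, Inf)))
scene <- generate_colony_image(sp)
scene$image
#> colony_image: 521 x 521 px, center (260.0, 260.0) um, analysis radius 250 um, channels: DAPI, pSMAD1

cells <- segment_colony_cells(scene$image, nucleus_radius = 5)
nrow(cells)                      # 714 of 726 true nuclei segmented
cells <- normalize_to_dapi(cells, "pSMAD1")
fit <- fit_binary_threshold(cells$norm_pSMAD1)
fit
#> mixture_fit: means 0.389 / 0.797, sds 0.096 / 0.109, weights 0.46 / 0.54, threshold 0.597
cells <- classify_positive(cells, "pSMAD1", fit)

prof <- radial_profile(cells, "norm_pSMAD1", bin_width = 10)
ring_width(prof)
#> $width_um   80.7
#> $r_half_um  169.3
#> $no_ring    FALSE
```

The recovered half-max boundary (169.3 µm) and ring width (80.7 µm) match
the generating geometry (170 µm onset, 80 µm ring) to well within one
10 µm profile bin. The positive fraction, 0.531 here, matches the
geometric truth: cells beyond 170 µm are 1 − (170/250)² ≈ 54% of a
uniformly packed disc.

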