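---
title: "Quantifying self-organized patterning in micropatterned colonies: methods and design notes"
author: "colonyquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying self-organized patterning in micropatterned colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyquant)
```

# The measurement problem

Human pluripotent stem cells confined to 500 µm adhesive discs
("micropatterns") and stimulated with BMP4 self-organize into concentric
germ-layer domains — a SOX2-positive ectodermal centre, a BRA-positive
mesodermal ring, and a CDX2-positive extraembryonic-like edge — a system
often called a 2D gastruloid. Changes in signaling (BMP, activin/NODAL,
WNT, and the secreted inhibitor noggin) shift the sizes of these domains,
the width of signaling-positive rings at the colony edge, the fraction of
responding nuclei in monolayer sheets, and the localization of receptors
relative to the apical tight-junction plane. `colonyquant` implements the
image-quantification pipeline for all of these readouts, together with a
synthetic-scene generator that renders every geometry with exported ground
truth, so each stage can be validated end to end without experimental
images.

# Pipeline overview

1. **Field assembly** (`stitch_tiles`, `correct_background`): tile grids
   are feathered together linearly across their overlaps; the background
   of each channel is estimated by morphological opening with a disc of
   diameter `window` (default 50 µm — well above the nucleus scale, below
   the colony scale) and subtracted, clipping at 0.
2. **Colony detection** (`detect_colonies`, `filter_colonies`,
   `extract_colony`): Otsu thresholding of a smoothed DAPI channel,
   closing with a disc of radius `expected_radius / 5` to obtain solid
   footprints, then exclusion of merged or poorly isolated objects (area
   outside 0.5–1.5 × the expected disc area or circularity
   $4\pi A/P^2 < 0.8$). Each accepted colony is cropped with its centre
   and a 250 µm analysis radius recorded.
3. **Nuclear segmentation** (`find_nucleus_seeds`, `segment_nuclei`,
   `extract_cell_table`): Laplacian-of-Gaussian blob detection at the
   nucleus scale ($\sigma = r_n/\sqrt2$, minimum seed separation
   $1.5\,r_n$), seeded watershed (EBImage's `propagate`) restricted to an
   Otsu foreground mask, and per-cell median intensities per channel.
   Medians are taken over each label's 1-px-eroded core because boundary
   pixels carry anti-aliased rims and bleed-over from adjacent nuclei.
4. **Positive-cell calling** (`normalize_to_dapi`,
   `fit_binary_threshold`, `classify_positive`): per-cell channel medians
   are divided by the DAPI median; a two-component Gaussian mixture is
   fitted for quality control while the cut-off itself comes from Otsu's
   criterion on the value histogram; cells strictly above the cut are
   positive. Cells whose DAPI median falls below 20% of the cohort median
   are excluded as debris — after background subtraction such fragments
   have near-zero denominators and unbounded ratios.
5. **Spatial statistics** (`radial_profile`, `ring_width`,
   `center_edge_summary`, `fraction_positive`, `secretor_proximity`):
   profiles bin per-cell values (or pixels) by radial position; all
   ring/range boundaries are half-maximum crossings of the profile with
   linear interpolation between bin centres.
6. **Germ-layer domains** (`segment_domains`, `domain_areas`,
   `relative_central_change`): three-region Otsu of the in-disc histogram
   of the central marker, solid footprints by closing (the raster
   equivalent of an alpha shape), and cohort-level percent change of the
   central-domain area.
7. **Apicobasal polarity** (`interpolate_apical_surface`,
   `distance_to_apical`): the apical plane is the intensity-weighted mean
   z of the background-subtracted ZO-1 profile per lateral position;
   signed channel distances are positive basal.
8. **Dynamics** (`reporter_radius_trace`, `nc_ratio_trace`): per-frame
   reporter-domain radius as the outermost half-max crossing of a
   foreground-occupancy profile, and nuclear-to-cytoplasmic reporter
   ratios with nearest-centroid tracking.
9. **Derived assays** (`teer_unit_area`, `qpcr_fold_change`,
   `compare_groups`): closed-form TEER per unit area, efficiency-2
   ΔΔCt fold changes normalized first to a reference gene and then to a
   pre-stimulus baseline condition, and delegation to the standard rank
   tests for group comparisons.

# The synthetic-scene generator

`scene_spec()` parameterizes one colony: geometry in micrometres, a
nuclear packing, per-channel spatial rules
(`chan_central_disc`, `chan_ring`, `chan_edge_band`, `chan_mixture`,
`chan_secretor`, `chan_suppression`) and an intensity model. Nuclei are
dart-thrown with a minimum centre separation of $1.6\,r_n$ — a cheap
surrogate for non-overlapping epithelial packing — and rendered as
anti-aliased filled discs; where discs overlap the brighter value wins.
Noise is additive Gaussian, clipped at zero. Every generator consumes a
single RNG stream seeded from the spec, so identical spec + seed gives
bit-identical rasters and truth.

Defaults are fixed once and shared by all tests:

| parameter | default | rationale |
|---|---|---|
| `pixel_size` | 1 µm/px | typical 10× widefield sampling; keeps test rasters small |
| `colony_radius` | 250 µm | the 500 µm disc micropattern |
| `density` | 3700 nuclei/mm² | a dense pluripotent epithelium; gives ~730 nuclei per colony, inside the published 683–785 per-colony range |
| `nucleus_radius` | 5 µm | hESC nuclei at this magnification |
| background / noise sd | 0.05 / 0.01 a.u. | camera offset plus shot-scale noise |
| DAPI class | N(0.5, 0.02) | a tight stoichiometric DNA stain |
| marker classes | N(0.2, 0.05) vs N(0.4, 0.05) | negative/positive separated by four class standard deviations |

`generate_multicolony_field` lays colonies into a field (optionally with a
deliberately merged pair at 1.6 colony radii for testing exclusion);
`generate_transwell_field` renders rectangular monolayer sheets with an
exact number of positive nuclei and optional secretor clusters with a
suppression zone; `generate_zstack` renders a ZO-1 apical surface (base
height plus sinusoidal undulation) with channels at signed offsets; and
`generate_timelapse` renders a reporter-positive disc following a radius
schedule on a fixed packing.

What the generator deliberately does **not** emulate: signaling physics
(no reaction–diffusion — class labels are assigned geometrically),
nuclear texture or 3D nucleus shape, photobleaching, stage drift, cell
division and movement, and the contiguous cytoplasmic staining of real
tissue. Passing tests therefore demonstrate that the *estimators* recover
the generating geometry under realistic packing, intensity overlap and
noise; they do not certify performance on real micrographs, where
segmentation is harder and staining is structured.

# Numerical choices

* **Otsu on value histograms.** The binary threshold uses a histogram
  whose bin count scales as $2\sqrt n$ (capped at 256): per-cell samples
  of a few hundred values get a smooth histogram, pixel samples keep full
  resolution. For well-separated classes the between-class variance is
  flat across the empty gap between them, so the cut is taken at the
  middle of the maximal plateau. Ties at the threshold are negative
  (strict `>`).
* **Three-region cut.** `multi_otsu3` minimizes the weighted within-class
  variance over all two-threshold splits of the histogram — the
  three-region criterion used for domain segmentation (background,
  marker-negative nuclei, marker-positive nuclei).
* **Separation guard for domains.** A marker only contributes a domain
  when its nucleus-core intensity distribution is genuinely bimodal: an
  equal-variance two-component mixture must beat one component by BIC and
  separate its means by at least twice the component sd. Core pixels are
  taken after a 2 px erosion — partial-coverage rim pixels otherwise
  smear the classes. With free variances one component can absorb the
  other class's tail and mask real bimodality, which is why the guard
  fixes the variances equal.
* **Alpha shapes as closing.** The solid-footprint step is implemented as
  morphological closing with a disc of radius α (20 µm for domains,
  `expected_radius/5` for colony detection) followed by hole filling —
  the raster equivalent of an alpha shape on the foreground points. The
  central footprint keeps its largest connected component only.
* **Half-maximum boundaries.** All ring widths and recovery ranges are
  crossings of $(\min+\max)/2$ of the profile, linearly interpolated
  between bin centres, with the *last upward* crossing used for
  edge-restricted rings (robust to sparse noisy bins near the colony
  centre) and the *outermost* crossing for reporter-domain radii. A flat
  profile (range below 10% of its level) has no internal boundary and is
  treated as everywhere-high.
* **Apical surface.** Per z-profile, the 10th percentile is subtracted
  and the profile clipped at zero before taking the intensity-weighted
  mean z; positions whose total falls below 20% of the median total are
  masked invalid and filled from neighbours; the height map is smoothed
  laterally with σ = 2 µm. Centroids are sub-plane accurate, which is
  why they are preferred over the argmax plane.
* **Degenerate inputs** fail loudly and specifically: infeasible packing
  names the achievable count, missing tiles name the grid slot, empty
  centre/edge groups name the band, a stack with no junction signal
  reports "no apical surface", and colonies whose high-channel region is
  not innermost are flagged rather than silently relabelled.

# Known estimator properties and limitations

* **Domain boundaries are sampled by discrete nuclei.** With ~9 µm
  nucleus spacing, any footprint of a nucleus-sampled domain deviates
  from the generating circle by about half that spacing. On synthetic
  three-ring colonies a tessellation oracle given perfect per-nucleus
  classification reaches ~95% per-pixel agreement with the analytic
  rings; the pixel pipeline reaches 90–92%, with the boundary *radius*
  recovered essentially unbiased (within ~3 µm across central radii of
  85–200 µm). Cohort-level area changes, which are ratios of mean areas,
  are insensitive to the small shared bias.
* **Threshold classification at skewed class weights is biased.** For a
  sheet with 20% positives and classes four sd apart, false positives
  from the 80% majority outweigh false negatives, so the recovered
  fraction is intrinsically near 22% rather than 20% — a Monte-Carlo of
  the exact intensity model with *perfect* segmentation gives
  22.2 ± 1.1% for one sheet, and the full imaging pipeline reads the
  same. The package reports the classification result as defined rather
  than a bias-corrected estimate; the mixture-fit weights offer a less
  biased alternative when that is wanted.
* **Live-imaging segmentation is threshold-based.** The published
  analyses used learned classifiers for some segmentation steps; this
  package deliberately replaces them with the classical matched-filter +
  watershed and Otsu paths so results are reproducible with no training
  data. Nucleus counts on full-density colonies stay within 3% of truth,
  which is sufficient for the cohort statistics computed here.
* **Hypothesis testing is delegated**, not re-implemented: rank-sum and
  t tests for two groups, Kruskal–Wallis with pairwise rank-sum post-hoc
  (Holm) for several. Dunn's z-based post-hoc is not shipped by the
  installed stack; the pairwise rank-sum post-hoc fills that contract.
* **File formats.** Rasters travel as multi-page 32-bit-float TIFF with a
  JSON sidecar (channel names, pixel size, z geometry, intensity scale)
  rather than OME-XML; the sidecar is the package's lightweight
  equivalent of OME metadata.

# Problem sizes used in the validation suite

The test suite renders every geometry at its natural scale where the
quantity depends on it (full 500 µm colonies at ~730 nuclei for ring
widths, domain cohorts of 10 colonies per condition, 700-nucleus
transwell sheets) and smaller colonies (r = 80–120 µm) where only the
operator contract is under test. Time-lapse fixtures use 4–10 frames
except for the frame-timing check, which uses the full 101-frame, 30-min
schedule on a miniature colony. These sizes keep the whole suite in the
low minutes on a single core while preserving the packing density and
intensity overlap that make the estimation problems non-trivial.
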