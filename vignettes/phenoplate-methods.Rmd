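---
title: "Methods: high-content phenotyping of iPSCs on substrate gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-content phenotyping of iPSCs on substrate gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenoplate)
```

## The assay and what the pipeline measures

Dissociated human induced pluripotent stem cells (iPSCs) are plated at a
fixed seeding density on 96-well plates coated with a fibronectin
concentration gradient (1, 5 and 25 µg/ml; `Fn1`, `Fn5`, `Fn25`), fixed
about one cell cycle later, pulsed with EdU for the final 30 minutes,
and imaged at 10× in four channels: DAPI (nuclei), EdU-488
(S-phase label), a plasma-membrane stain (cell bodies) and brightfield
(acquisition control). Conditions are laid out in technical triplicates
randomised per column, and border wells stay empty to buffer edge
effects. Because the endpoint sits within one cycle of plating, the
retrieved cell number mostly reflects adhesion and survival rather than
proliferation; the EdU fraction probes proliferation separately.

From every field the pipeline extracts one row per retained cell with
nine phenotypic features — six morphology (nucleus and cell area,
roundness, width-to-length), two intensity (DAPI and EdU medians) and
one context feature (the number of cells in the clump the cell belongs
to) — and aggregates them per well. Wells are then compared across
substrate conditions, including by principal component analysis.

## Segmentation

The instrument vendor's nucleus-detection algorithm is unpublished; the
package substitutes an open algorithm that honours the semantics of the
three documented parameters:

* **nucleus diameter** (default 18 µm) sets the Gaussian smoothing scale
  (diameter/8 in pixels) and a debris floor of 10% of the nominal
  nucleus area;
* **common threshold** (default 0.05) places the detection threshold at
  background (image median) plus 0.05 times a robust signal range;
* **splitting coefficient** (default 0.40) is the watershed
  seed-suppression depth as a fraction of each component's maximum
  interior distance — smaller values split touching nuclei more
  aggressively.

Two numerical choices matter and are deliberate. First, the robust
signal range is the 99.9th percentile minus the median of the smoothed
image rather than an interquantile range: on sparse fields (foreground
below 1% of pixels) any percentile below the foreground fraction sits in
the background and the threshold collapses into noise. A floor of six
robust SDs (MAD) of the smoothed image keeps genuinely empty fields
empty. Second, after thresholding, each component is refined to its
half-maximum contour. Gaussian blur moves a step edge's half-maximum
position very little, so the refined mask tracks the true object
outline; without this step a 5%-of-range threshold on a blurred image
inflates areas roughly 2.4-fold, which corrupts both the area filters
and the region medians (a mask that is mostly halo has a background
median).

Cells are grown from nucleus seeds into the membrane-stain foreground by
seeded region growing (`EBImage::propagate`), guaranteeing exactly one
cell per nucleus with the nucleus contained in its cell; touching cells
partition the shared foreground along the propagation boundary. Nuclei
with no surrounding membrane foreground keep their nucleus as the cell
region and are flagged. Objects whose cell region touches the field
border are removed before any per-cell statistics.

Connectivity is 8-neighbour throughout (the 4-connected labelling of the
underlying library is merged across diagonal contacts).

## The object-filter cascade

Objects pass four stages, named after the populations they produce:
`nuclei` → `nuclei2` → `cell_unselected` → `cell`. The `nuclei2` filter
keeps nucleus area in the closed window [60, 600] µm², EdU median
strictly below 10,000, DAPI median in [500, 10,000] and brightfield
median strictly above 0; border-object removal produces
`cell_unselected`; the final filter keeps cell area strictly below
6000 µm², which removes the rare oversized feeder-cell contaminants
(mouse embryonic fibroblasts carried over from maintenance culture).
"Between" is read as closed, "below"/"over" as strict; a `strict = FALSE`
switch flips the strict comparisons for users whose instruments bin
intensities coarsely. Every removed row carries a machine-readable
reason.

## Clumps and the context feature

Two retained cells belong to the same clump when their regions are
adjacent at distance 0. Since region growing can leave a one-pixel
separation line between touching cells, adjacency is evaluated on
regions dilated by one pixel — equivalently, two labels are adjacent
when any pair of their pixels is within Chebyshev distance 2. Clumps are
the connected components of this region-adjacency graph; a single cell
is a clump of size 1, and each cell's clump size is tagged back as its
context feature (`n_per_clump`). Clumps are field-local: border cells
are removed beforehand and fields are non-contiguous acquisitions, so
no cross-field merging is attempted.

## Morphology and intensity measurements

Area is the pixel count times the pixel area. Roundness is the
isoperimetric score 4πA/P², clipped to (0, 1] because discretisation can
exceed the continuous bound; the perimeter is the Moore boundary chain
length with Vossepoel–Smeulders step weights (0.948 isothetic, 1.340
diagonal), which removes most rasterisation bias — a radius-10 disk
scores ≥ 0.95 instead of ~0.6 with naive edge counting. Width-to-length
is the minor/major axis ratio of the second-central-moment equivalent
ellipse (with the 1/12 pixel-extent term). Intensity medians are taken
over the nucleus region by default: DAPI and EdU are nuclear signals,
and the source workflow computed them before cytoplasm detection; the
region is switchable to the cell mask.

## Well aggregation

Features are variance-stabilised before averaging: log10 for the
strictly positive right-skewed quantities (areas, intensity medians),
squaring for the left-skewed ratios bounded at 1 (roundness,
width-to-length). The mapping is configurable; non-positive values under
log10 are excluded with a warning. Each well reports the mean and SD of
every transformed feature over all cells and separately over single
cells (SD is missing, not zero, when a single value contributes), plus
the cell count and three derived statistics:

**EdU-positive fraction.** EdU medians in a well form a dominant
low-intensity population (EdU-negative cells) and a high-intensity
S-phase population. Following the density-residual construction — the
positive fraction is the area under the empirical density not explained
by a Gaussian main peak — the estimator log10-transforms the values,
estimates the density by Gaussian KDE (Silverman bandwidth), fits a
Gaussian to the main peak, and integrates the rectified residual,
clipped to [0, 1]. The peak Gaussian's centre, width and height come
from a quadratic fit to the log-density over the contiguous half-maximum
region around the mode: this measures the width at the smoothed scale,
so a well with no positive cells leaves almost no residual, and it is
robust to the mode landing on the positive peak when the two populations
have similar mass. A mirror-symmetry variant (sigma from the sub-mode
half of the data) and a two-component mixture EM variant are available
behind `method`; the mirror construction is noticeably noisier because
both the mode location and the peak height carry KDE sampling error into
the rectified residual. Half of the pointwise KDE sampling SE is
subtracted before rectifying, suppressing spurious positive mass from
density wiggle; this trades a small downward bias (about 0.03–0.05 at
50–150 cells per well, under 0.01 at 2000) for a near-unbiased null.
Wells with fewer than 30 cells return a missing fraction. The estimator
is invariant under rescaling all intensities (a shift in log space).

**Clump statistics.** Clump counts fall off roughly geometrically with
size, so the sizes are modelled as geometric on support 1, 2, 3, …; the
maximum-likelihood parameter is the inverse mean clump size, reported
with a chi-square goodness-of-fit statistic (tail classes pooled below
an expected count of 5). The fraction of single cells (clumps of size 1
over cells) is reported alongside; both equal 1 in an all-singleton
well. Because the statistic the source assay's 37% single-cell figure
refers to is ambiguous, both the mean of per-well fractions and the
pooled fraction are emitted.

## Condition analysis

The well-by-feature matrix takes the transformed means and SDs of the
eight all-cell features plus log10 cell count, EdU fraction, single-cell
fraction and inverse mean clump size. Features mix units, so each column
is z-scored (the source describes no standardisation, but PCA on raw
mixed units would be dominated by the largest-variance unit); wells with
any missing feature are removed listwise with a logged count, and
constant columns are dropped. PCA is computed by SVD with a fixed sign
convention (largest-magnitude loading per component positive).

"An elliptic area representing 68% of samples" is read as the
1-σ-equivalent bivariate-normal contour: per condition, a bivariate
normal is fitted to the first two component scores and the ellipse drawn
at the χ²(2 df) quantile of 0.68. Ellipse overlap is decided by dense
boundary sampling plus centre-containment checks. The alternative
reading (convex hull of 68% of the points) is noted but not implemented;
at three to six wells per condition a hull would be extremely unstable.

## The synthetic plate simulator

No raw images are publicly deposited with the source assay, so the
package ships a generator whose defaults encode the study's stated
structure: cell counts ordered Fn25 > Fn5 > Fn1 (expected 100/75/45
attached cells per well at desk scale), a shared true EdU fraction of
0.30 across conditions, clump sizes geometric with parameter 0.85 /
0.63 / 0.55 (clumping rises with adhesion), log-normal nucleus and cell
areas, beta-distributed width-to-length (cells rounder on Fn1, larger
and more variable on Fn25), a 10% chance per well of one oversized
feeder contaminant (cell area 6500–9000 µm², above the 6000 µm²
filter), and a two-component log-normal EdU intensity mixture over a
background of 200 (negative median 300, positive median 3000,
well-separated in log space). The morphology magnitudes are engineering
choices — the source reports no quantitative distributions — and are
documented in `simulation_params()` rather than claimed from data.

A per-well log-normal multiplier (sdlog 0.15) models plating
variability; it scales both the expected cell count and the odds of
clump growth, so denser wells form proportionally fewer single cells —
the mechanism the assay describes (cells meet more often). Given the
multiplier, clump sizes are exactly geometric; with the multiplier
disabled the marginal distribution is exactly geometric with the preset
parameter.

Rendering places clump members in actual contact (tangent placement
using directional ellipse radii), keeps distinct clumps at least 8 px
apart so distance-0 clump detection is unambiguous, and keeps all
objects clear of field borders. Nuclei are filled ellipses in DAPI; the
EdU channel adds the per-cell mixture draw over the nucleus; the
membrane channel renders cell bodies; brightfield is strictly positive
background. All channels get Gaussian noise and 16-bit rounding. The
whole plate is a pure function of (layout, parameters, master seed),
with per-well and per-field seeds derived deterministically.

What the simulator does **not** emulate: optical point-spread functions,
vignetting or shading (flatfield correction is therefore near-identity
on synthetic fields and is exercised by constructed fixtures),
intensity gradients within cells, debris and apoptotic fragments,
out-of-focus fields, or non-elliptical cell shapes. Tests passing on
synthetic plates therefore validate the pipeline's logic and its
statistical estimators, not its robustness to real optical artefacts.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: fields of
480×480 px at 0.65 µm/px (320×320 px with proportionally smaller cells
in the fast unit-test preset), nine fields per well, six replicate wells
per condition (18 assay wells) for the end-to-end analyses, 2000 cells
per well for estimator-recovery studies, and 1000–5000 draws for the
distributional checks. Every stochastic step is seeded; identical seeds
give bit-identical images and tables.

## Known limitations

* The segmentation substitute is parameter-compatible with, but not
  bit-compatible with, the proprietary instrument algorithm; whether the
  vendor's splitting coefficient scales a distance, an intensity or a
  hybrid criterion is undocumented, and the distance interpretation used
  here is a declared choice.
* The EdU estimator's noise floor biases small wells slightly downward;
  fractions from wells under ~100 cells should be compared, not read as
  absolute.
* Ellipse-overlap conclusions with 6 wells per condition are sensitive
  to single wells; the package reports them but serious inference needs
  more replicates.
* Clumps are field-local by construction; a clump genuinely spanning a
  field boundary would be counted as its visible parts (mitigated by
  border-object removal).
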