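---
title: "Methods: myeloid-T-cell distance, overlap and distance signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myeloid-T-cell distance, overlap and distance signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(mtospat)
```

## The problem

In colorectal tumors, suppressive myeloid cells (monocytic CD11b+CD14+ and
granulocytic CD11b+CD15+) shape what cytotoxic CD8+ T cells can do, and
they do it locally: a T cell surrounded by myeloid cells experiences a
different microenvironment than one in a myeloid-poor region, even at
identical whole-slide densities. `mtospat` quantifies that spatial
relationship from per-cell coordinate exports (micrometre x/y plus a
phenotype call, the shape of a digital-pathology object export) and
annotated region polygons, at three scales:

1. **GAD / GAD_norm** — a cell-pair distance statistic,
2. **MTO** — a tile-level co-occupancy score on a hexagonal grid,
3. **distance signatures** — gene sets whose expression tracks GAD_norm
   across a cohort, scored per sample with a permutation null.

## GAD and its normalization

For a sample with CD8+ T cells and one myeloid compartment restricted to
the tumor ROI, each CD8+ cell is paired with its nearest myeloid cell and
the global average distance is the mean over those pairs:

$$\mathrm{GAD} = \frac{1}{|T|}\sum_{t \in T} \min_{m \in M} \lVert t - m \rVert .$$

Raw GAD confounds geometry with abundance: doubling the myeloid count
halves typical nearest-neighbour distances with no change in spatial
organization. We therefore divide by the Clark-Evans expected
nearest-neighbour distance for a random (homogeneous Poisson) pattern of
the $n$ myeloid cells in the tumor area $A$:

$$\mathrm{GAD}_{norm} = \frac{\mathrm{GAD}}{0.5\sqrt{A/n}},$$

with $A$ in µm² so the ratio is dimensionless. Under complete spatial
randomness (CSR) of the myeloid cells, the distance from an arbitrary
point to the nearest point of a Poisson process of intensity
$\lambda = n/A$ has mean $1/(2\sqrt{\lambda})$, so
$\mathrm{GAD}_{norm} \approx 1$ regardless of the CD8 pattern; values
above 1 mean myeloid cells sit farther from T cells than chance
(segregation), values below 1 mean co-localization. No edge correction is
applied — the reference value is the uncorrected expectation — which
biases $\mathrm{GAD}_{norm}$ upward by a few percent on small ROIs; the
calibration test accepts a mean in $[0.98, 1.10]$ at 500 myeloid cells in
5 mm² for that reason. Samples with zero cells on either side get a
missing GAD and are excluded from cohort medians, with a warning recorded
in the run manifest.

```{r}
cfg <- synth_config(n_samples = 1, roi_area_mm2 = 5,
                    intensity = c(CD8_Ki67neg = 40, CD11b_CD14 = 100),
                    pattern = "CSR", n_genes = 2, n_planted = 0)
sim <- simulate_sample(cfg, sample_seed = 1)
sample_distance(sim$cells, sim$regions, "CD11b_CD14")
```

## Regions, areas and the invasive margin

Annotations are polygons of class `tumor`, `normal` or `excluded`
(necrosis, artefacts). Excluded polygons are subtracted before any area or
density computation. The invasive margin is the band of all points within
`margin_half_width` (default 250 µm, i.e. a 500 µm band) of the tumor
boundary, clipped to annotated tissue. Because no polygon-offsetting
library is part of the package's dependency set, the band is represented
by its exact distance predicate (point-to-boundary distance ≤ half-width)
and its area is integrated on a regular grid, by default at
half-width/50 = 5 µm, which is accurate to well under 1% for realistic
annotation shapes; `res` is adjustable where more accuracy is wanted.

## The hexagonal grid and MTO

The tumor ROI is tessellated with pointy-top hexagons whose long
(vertex-to-vertex) diagonal is 250 µm by default, anchored at the
lower-left corner of the ROI bounding box. "Diagonal" is read as the long
diagonal — the conventional diagonal length of a hexagon — giving a
circumradius of 125 µm and a tile area of $(3\sqrt{3}/2)\,125^2 \approx
0.0406$ mm². Both the orientation and the anchor are arbitrary but fixed,
so runs are reproducible; MTO is exactly invariant to translations of a
sample (the grid moves with the bounding box) and only approximately to
rotations.

Edge tiles are handled explicitly, since the source procedure leaves them
unstated: a tile is retained when its clipped intersection with the ROI
covers at least 50% of the full hexagon area (switchable via
`min_tile_coverage`), and per-tile densities use the clipped area, which
avoids inflating densities on partially covered tiles. Cells are assigned
to the tile with the nearest center (the Voronoi cell of the hexagonal
lattice is exactly the hexagon, so this is point-in-tile assignment with a
deterministic tie-break toward the lower tile index); cells whose tile was
dropped by the coverage rule are counted nowhere and reported, so
assignment conserves every cell.

A tile $i$ is **hot** for cell type $j$ when its density $d_{ij}$ strictly
exceeds $D_j$, the cohort-wide median of the *sample-level* tumor
densities of that type (not a per-tile median). The myeloid-T-cell
overlap for CD8 ($j$) and a myeloid type ($k$) is

$$\mathrm{MTO}_{j,k} = \frac{\sum_i h_{ij} h_{ik}}{\sum_i h_{ij}},$$

the fraction of CD8-hot tiles also hot for the myeloid type; it is
undefined when the sample has no CD8-hot tile, and such samples are
excluded from downstream medians and reported.

## Stratification

Each sample is labelled `high` on an axis when its value strictly exceeds
the cohort median (values at the median are `low`, so ties resolve
deterministically). In (CD8 density, MTO) order the four categories are
low/low = 1, low/high = 2, high/high = 3, high/low = 4. Categories 2 and 3
collect tumors whose infiltrating T cells co-occupy myeloid-dense tiles;
1 and 4 collect spatially separated ones. Both myeloid compartments are
stratified side by side, since they disagree for a substantial minority of
samples.

## Gene-set scoring and distance signatures

A gene set is scored in a single sample by the rank-biserial correlation
of the set genes against all other genes of the matrix,
$r_{rb} = 2U/(n_1 n_2) - 1$, with $U$ the Mann-Whitney statistic on
within-sample expression ranks (midranks for ties; the background is the
full matrix, configurable only by subsetting the matrix). Scores are
multiplied by 10 — commensurate with log2 RPKM values — and
median-centered per signature across samples, so a positive score marks a
sample enriched relative to at least half the cohort. Scoring uses only
within-sample ranks and is therefore invariant to any monotone per-sample
transform.

A distance signature is derived by correlating every gene (Spearman,
midranks) with per-sample GAD_norm and keeping genes with $R$ strictly
above the cutoff (positive set) or strictly below its negative (negative
set); the defaults are |R| > 0.4 for the monocytic and |R| > 0.3 for the
granulocytic compartment. How the two sets combine into one score is a
design choice the source procedure leaves open; we use
positive-minus-negative centered scores, which preserves the sign
semantics of the derivation, and a one-sided signature degrades to the
single available term.

The permutation test draws `n_permutations` (default 10,000) random
signatures matching the positive/negative set sizes exactly, without
replacement from the matrix's gene universe, and reports
$p = \#\{|r_{rand}| > |r_{obs}|\}/n_{perm}$ — strict inequality, no
pseudo-count, so $p = 0$ is attainable by construction. The test is
bit-for-bit reproducible given `(seed, n_perm)`.

## The synthetic-cohort generator

Real per-cell coordinates for this kind of study are rarely shareable, so
the generator produces cohorts with known ground truth and the same file
dialects the readers consume. What it emulates:

* **ROI**: a rectangle or a smooth random blob of configurable area
  (default 5 mm², a desk-scale stand-in for whole-slide tumor ROIs).
* **Point patterns**: per-phenotype homogeneous Poisson (CSR) or Thomas
  cluster processes (Poisson parents at `parents_per_mm2`, default
  4/mm²; offspring displaced by an isotropic Gaussian with
  `cluster_sigma` = 75 µm). The offspring mean is derived as
  intensity / parent intensity so the configured per-phenotype intensity
  stays the expected density. Default intensities are the tumor-ROI
  median densities reported for treatment-naive colorectal cohorts:
  monocytic ~35, granulocytic ~122, CD8 ~77 (30% Ki67+), FOXP3 ~130,
  ARG1 ~120 cells/mm².
* **Co-localization**: a fraction `co_cluster_fraction` of CD8 parents is
  replaced by randomly chosen myeloid parents, so CD8 and myeloid
  offspring share cluster centers; 0 gives independent clustering
  (GAD_norm > 1), 1 gives strong co-clustering (GAD_norm < 1).
* **Expression**: planted genes are coupled to the per-sample GAD_norm
  ranks through a Gaussian copula at the target Spearman rho (exact in
  expectation regardless of marginals), null genes are independent, and
  values are mapped to a plausible log2 RPKM scale (baseline
  Uniform(2, 8), spread 1.5).

What it deliberately does **not** emulate: stain intensities, segmentation
and phenotyping errors, tissue-structure constraints (stroma vs
epithelium), serial-section registration error, inhomogeneous cell
intensity within the ROI, and realistic RNA-seq mean-variance structure.
Passing tests on these cohorts therefore demonstrates that the estimators
recover planted spatial and transcriptional structure under clean
conditions, not that they are robust to imaging artefacts.

## Numerical choices and degenerate inputs

* Polygon algebra (shoelace areas, even-odd membership,
  Sutherland-Hodgman clipping against the convex hexagons,
  distance-to-boundary banding) is implemented in vectorized base R; clip
  areas are exact up to floating point, band areas are grid-integrated.
* Tiles at exactly the 50% coverage threshold are retained, with a 1e-9
  relative tolerance so retention is stable under coordinate offsets.
* Ties: hot labelling and high/low stratification use strict inequality
  (ties are cold/low); rank ties anywhere use midranks; cell-to-tile
  ties go to the nearer center, then the lower tile index.
* Degenerate samples (no CD8 or no myeloid cells, no CD8-hot tile) yield
  missing GAD/MTO, are dropped from medians and contrasts, and are
  reported in warnings and the run manifest rather than erroring.
* Per-sample simulation seeds are drawn from the master seed once, so
  cohorts are reproducible and samples are independent.

## Problem sizes used in the test-suite simulations

Monte-Carlo checks run at deliberately desk-sized settings chosen to give
stable means while keeping the suite quick: 50 seeds for the CSR
calibration and regime separation (~500 myeloid / ~200 CD8 cells in
5 mm²), 20 seeds of 6-sample cohorts per co-clustering level for MTO
monotonicity, 20 seeds of 80-sample / 200-gene matrices for signature
recovery, and 200 trials of 500 permutations for the null calibration.
The demo cohort mirrors a 74-patient study cohort.

## Known limitations

* GAD_norm is not edge-corrected; very small or very elongated ROIs bias
  it upward.
* The hexagonal grid orientation/anchor is a convention; MTO on real data
  will vary slightly under rotation of the slide.
* The hot-tile threshold ties each sample's labels to the cohort
  composition; adding samples changes $D_j$ and hence every MTO.
* Rank-biserial set scores ignore gene-gene correlation; the permutation
  test inherits the same gene universe and set sizes but not the
  co-expression structure of the observed signature.
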