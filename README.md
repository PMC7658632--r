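# mtospat

Spatial analysis of suppressive myeloid cells and cytotoxic T cells in
tumor tissue, for researchers working with per-cell coordinate exports
from digital pathology (x/y in micrometres plus a phenotype call) and
polygon region annotations. The package quantifies whether CD8+ T cells
and myeloid cells (monocytic CD11b+CD14+, granulocytic CD11b+CD15+)
co-localize or segregate, stratifies a cohort on that basis, and links
the spatial phenotype to gene expression.

## What it computes

**Normalized global average distance.** Each CD8+ T cell in the tumor ROI
is paired with its nearest myeloid cell; GAD is the mean pair distance,
normalized by the Clark–Evans expected nearest-neighbour distance under
spatial randomness of the *n* myeloid cells in tumor area *A*:

    GAD_norm = GAD / (0.5 * sqrt(A / n))

GAD_norm ≈ 1 for randomly placed myeloid cells, > 1 for myeloid–T-cell
segregation, < 1 for co-localization.

**Myeloid–T-cell overlap (MTO).** The tumor ROI is tessellated with
hexagons (250 µm long diagonal). A tile is *hot* for a cell type when its
density strictly exceeds the cohort median tumor density of that type
(D_j). For CD8 (*j*) and a myeloid type (*k*):

    MTO = sum_i h_ij * h_ik / sum_i h_ij

the fraction of CD8-hot tiles that are also myeloid-hot.

**Stratification.** Samples split at cohort medians of tumor CD8 density
and MTO into four categories — (CD8, MTO) low/low = 1, low/high = 2,
high/high = 3, high/low = 4 — separately per myeloid compartment.

**Distance signatures.** Genes are correlated (Spearman) with per-sample
GAD_norm; genes with |R| strictly above a cutoff (0.4 monocytic, 0.3
granulocytic) form signed signatures, scored per sample by rank-biserial
enrichment (×10, median-centered) and tested against 10,000
size-matched random signatures (p = fraction of random |r| exceeding the
observed |r|).

A synthetic-cohort generator (Thomas cluster processes with shared
parents for planted co-localization; Gaussian-copula expression coupling
for planted gene–distance correlations) makes every stage testable
without patient data.

## Worked example

```r
library(mtospat)

cfg <- synth_config(n_samples = 20, roi_area_mm2 = 2,
                    co_cluster_fraction = seq(0, 1, length.out = 20),
                    n_genes = 120, n_planted = 12, rng_seed = 7)
cohort <- simulate_cohort(cfg)          # cells + regions + expression
fit <- analyze_cohort(cohort$cells, cohort$regions)
print(fit)
#> <tme_cohort> 20 samples
#>   median tumor densities (cells/mm^2): CD8 73.0, CD14 34.2, CD15 107.5
#>   median MTO: CD14 0.317, CD15 0.467
```

The cohort plants a gradient of CD8–myeloid co-clustering, so GAD_norm
spans segregated (> 1) to co-localized (< 1) samples and the four
categories are all populated:

```r
summary(fit)
#> Per-sample GAD_norm by myeloid compartment:
#>                 Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> CD11b_CD14 0.6583886 1.356843 1.621042 1.649354 2.030309 2.470987
#> CD11b_CD15 0.8941347 1.666050 2.174906 2.214393 2.417146 4.037407
#>
#> Stratification (category counts by myeloid compartment):
#>              1 2 3 4
#>   CD11b_CD14 5 6 4 5
#>   CD11b_CD15 4 7 2 7
```

Deriving a distance signature and testing a planted gene against it:

```r
R <- correlate_genes_with_parameter(cohort$expression, cohort$gad_norm)
sig <- derive_distance_signature(R, 0.4, source_parameter = "GAD_CD14")
print(sig)
#> <gene_signature> distance_signature [GAD_CD14]: 12 positive, 6 negative (|R| > 0.4)

permutation_test(cohort$expression, sig, "g_planted_01",
                 n_perm = 1000, seed = 11)
#> <permutation_result> observed r = 0.606, p = 0.009 (1000 permutations, seed 11)
```

The planted gene (true Spearman 0.6 with GAD_norm) correlates with the
signature scores far more strongly than size-matched random signatures
do, hence the small p.

File-based workflows go through `read_inputs()` (cell CSV, region
GeoJSON, expression TSV) or the one-call `run_pipeline(config, outdir)`,
which writes `densities.csv`, `distances.csv`, `overlap.csv` (MTO +
category), derived signatures and a JSON run manifest; reruns with the
same config and seed are byte-identical.

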