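# proximif

Spatial proximity analysis of phenotyped cells in multiplex
immunofluorescence (mIF) tissue sections.

## What it is for

After an mIF slide is scanned and segmented, each cell is a point with
micron coordinates and per-marker intensities.  A recurring question in
tissue immunology — here motivated by liver allograft biopsies — is
whether two rare immune populations are spatially co-located: do group 2
innate lymphoid cells (ILC2, tissue gate CD4− CD8− CD127+ GATA3+) sit
closer to regulatory T cells (Treg, CD4+ Foxp3+) than chance would put
them?  proximif takes the post-segmentation cell table and answers with
numbers rather than pictures:

* **Phenotyping** by ordered marker-positivity rules (first match wins),
  with strict `intensity > threshold` gating and the ILC2/Treg panel
  built in.
* **Directed nearest-neighbor distances** between the two phenotypes and
  their **median cross-distance**: for each ILC2 the distance to the
  nearest Treg, for each Treg the distance to the nearest ILC2, pooled —
  the pooled median `median(d_{A→B} ∪ d_{B→A})` is the headline summary,
  with both per-direction medians reported.
* **Neighborhood counts**: the number of partner cells within a circle
  of 15 or 25 µm *diameter* centered on each cell, plus the pairwise
  distance matrices behind the usual proximity heatmaps.
* **Null models**: closed-form complete-spatial-randomness (CSR)
  references — NN median `sqrt(ln 2 / (π λ))`, circle count `λ π r²` —
  and a within-ROI label-permutation test with add-one p-values.
* **A synthetic-tissue generator** (CSR and shared-parent Neyman–Scott
  cluster processes with ground-truth labels and marker noise) that
  makes every stage testable end to end without imaging data.

Distances are Euclidean, in microns, computed within — never across —
regions of interest (ROIs).  Nearest-neighbor queries run on a compiled
bucket grid that is bit-identical (tie rule included: smallest cell id
in radix order) to the exhaustive reference path shipped alongside.

## Worked example

Simulate one attractive tissue region (both phenotypes scatter around
shared cluster centers, σ = 8 µm), gate it, and measure proximity:

```r
library(proximif)

cfg <- synthetic_config(model = "shared_parent", sigma = 8, seed = 42)
cells <- simulate_tissue(cfg)
cells <- classify_table(binarize_markers(cells,
  c(CD4 = 5.5, CD8 = 5.5, CD127 = 5.5, GATA3 = 5.5, Foxp3 = 5.5)))
phenotype_counts(cells)
#> # A tibble: 2 × 4
#>   sample_id roi_id phenotype     n
#>   <chr>     <chr>  <chr>     <int>
#> 1 S1        R1     ILC2        107
#> 2 S1        R1     Treg         94

A <- cells[cells$phenotype == "ILC2", ]
B <- cells[cells$phenotype == "Treg", ]
median_cross_distance(A, B, type_a = "ILC2", type_b = "Treg")
#> <proximity_result> ILC2 (n=107) vs Treg (n=94), status: ok
#>   median ILC2->Treg: 10.886 um | Treg->ILC2: 10.468 um | pooled: 10.700 um

neighborhood_counts(A, B, size = 15)   # 15 um diameter circle, r = 7.5
#> <neighborhood_counts> 107 centers, circle 15 um (diameter), inclusive boundary [ok]
#>   mean count 0.393, median 0, max 5

csr_expected_nn_median(nrow(B) / 1e6)  # CSR reference at matched intensity
#> [1] 48.448
```

Reading the numbers: the pooled median ILC2–Treg distance is 10.7 µm
against a CSR reference of 48.4 µm at the same Treg density in the same
1000×1000 µm window — the two populations are strongly co-located, as
the σ = 8 µm generator dictates.  On each ILC2, on average 0.39 Tregs
fall inside the 15 µm-diameter circle.

The label-permutation test on the same table illustrates the
calibration point documented in the methods vignette: both phenotypes
cluster around the *same* parents, so their labels are exchangeable and

```r
label_permutation_test(cells, n_perm = 199, seed = 7)
#> <perm_test_result> stat = median_pooled, observed = 10.6996
#>   null: mean 10.2201 [199 permutations]; direction 'less'; p = 0.82
```

correctly declines to call the co-location label-specific; the CSR
comparison above is the null that detects it.  Real tables enter the
same way via `read_cell_table("cells.csv")` (CSV with `cell_id`, `x`,
`y`, one column per marker; a schema argument maps vendor column names),
and `summarize_sample()` produces per-ROI and pooled per-sample tables
of every statistic.  A thin command-line wrapper with `simulate`,
`analyze` and `test` subcommands lives in `inst/scripts/proximif-cli.R`.

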