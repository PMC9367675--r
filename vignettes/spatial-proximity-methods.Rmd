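---
title: "Methods: quantifying ILC2–Treg spatial proximity in multiplex immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ILC2-Treg spatial proximity in multiplex immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proximif)
```

## The analysis problem

Multiplex immunofluorescence (mIF) stains several protein markers on one
tissue section.  After segmentation, each cell is a point with micron
coordinates and per-marker intensities.  Two rare immune populations are of
interest in liver allograft sections: group 2 innate lymphoid cells (ILC2,
tissue gate CD4− CD8− CD127+ GATA3+) and regulatory T cells (Treg, tissue
gate CD4+ Foxp3+).  The scientific question is whether the two populations
are spatially co-located — whether ILC2s sit closer to Tregs than chance
arrangement would put them — which is biologically read as evidence of
interaction or mutual recruitment.

proximif implements the full desk-side pipeline: reading segmented cell
tables, gating phenotypes, measuring directed nearest-neighbor (NN)
distances and their median, counting partner cells in fixed-size circles,
exporting the matrices behind proximity heatmaps, and — beyond the
descriptive statistics — a null-model layer and a synthetic-tissue
generator that make "closer than expected" a calibrated, testable claim.

## Phenotyping model

Cells are classified by conjunctions of marker positivity rules evaluated
in a fixed order (first match wins); unmatched cells get a fallback label.
Positivity of a continuous marker is strict: intensity > threshold.
Thresholds are user-supplied per marker (instrument gates are rarely
published); `auto_thresholds()` offers a bimodal k-means split as a
starting point only.

Two deliberate choices:

* The default panel uses exactly the tissue gates above.  They are
  mutually exclusive (ILC2 requires CD4−, Treg CD4+), so the evaluation
  order cannot matter for the default panel; it is still fixed — ILC2
  first — so that overlapping *user* panels classify reproducibly, with
  the number of multi-matching cells logged.
* The tissue Treg gate carries no CD25 or CD127-low condition.  Flow
  cytometry defines Tregs as CD4+CD25+CD127low (or with Foxp3), but the
  five-marker imaging panel has no CD25 channel; CD4+Foxp3+ is the
  operative imaging definition and the two should not be conflated.

Published legends of 4-plex ILC2 panels leave open whether CD8− is also
enforced when co-staining with Foxp3 in a 5-plex; the default panel
applies the full CD4−CD8−CD127+GATA3+ conjunction uniformly, the
strictest form of the gate.

## Spatial statistics

All distances are Euclidean, in microns, and **never cross ROI
boundaries** — cells in different scanned regions are never neighbors.
Three statistics are computed per ROI and pooled per sample:

* **Directed NN distances.**  For each ILC2 the distance to the nearest
  Treg, and for each Treg the distance to the nearest ILC2.  The two
  directions differ in general and are both kept.
* **Median cross-distance.**  The headline summary is the *pooled* median
  — the median of the two concatenated directed vectors — which is the
  single number consistent with "measure both directions, then take the
  median".  Per-direction medians are always reported alongside.  The
  median of an even-length vector is the midpoint of the two central
  order statistics.
* **Neighborhood counts.**  For each center cell, the number of
  partner-type cells within a circle of stated size.  The operational
  description of the assay speaks of a circle with a *diameter* of 15 or
  25 microns, so the size is interpreted as a diameter by default
  (r = size/2), with `size_is_diameter = FALSE` available where a radius
  convention is wanted.  The boundary is inclusive (d ≤ r) by default.
  All four (center, neighbor) combinations are summarised.

Numerical conventions, chosen once and tested:

* **Tie rule.**  Exact-distance ties in NN queries resolve to the
  smallest `cell_id` in C-locale (radix) order — deterministic across
  platforms and locales.
* **Self-exclusion.**  A cell appearing in both roles (same id) never
  counts or matches itself; coincident *distinct* cells legitimately
  yield distance 0.
* **Dual code paths.**  Neighbor queries run on a compiled bucket-grid
  (`method = "grid"`) or an exhaustive scan (`method = "exhaustive"`).
  Both use identical floating-point expressions, so their results are
  *bit-identical*, tie rule included; the test suite asserts this on 100
  random instances per run and additionally against an independent
  double-loop oracle.
* **Edge effects.**  The analysis path applies no edge correction,
  matching how such measurements are made in practice on bounded ROIs.
  Simulation-based calibration uses toroidal (periodic) distances
  instead, which makes the closed-form Poisson results below exact and
  keeps "no correction" out of the calibration error budget.
* **Pooling.**  Samples comprise several ROIs.  By default ROI-level
  distance vectors are concatenated before the sample median is taken
  (`pooling = "per_sample"`); the median-of-ROI-medians alternative is
  available.  ROIs missing either phenotype are flagged `insufficient`,
  excluded from pooled medians, and logged.
* **Degenerate inputs.**  An empty phenotype yields a result flagged
  `undefined` with `NA` medians — never a silent zero.  An empty
  neighbor set yields all-zero counts with a status flag (a valid
  observation, not an error).

Whether published proximity heatmaps display raw pairwise distances or
nearest-neighbor distances is not always determinate; both matrices are
therefore exported (`pairwise_distances()`, `directed_nn()`), ordered by
cell id, and the rendering layer (`plot_distance_heatmap()`) carries no
tested semantics.

## Null models

Two complementary references turn description into inference:

* **Closed-form CSR.**  For a homogeneous Poisson process of intensity
  λ (µm⁻²), the NN distance has CDF 1 − exp(−λπd²), so its median is
  √(ln 2 / (πλ)) and the expected count in a circle of radius r is λπr².
  At λ = 0.01 µm⁻² these give 4.697 µm and (r = 7.5 µm) 1.767 — the
  yardsticks the test suite checks the spatial engine against on
  toroidal CSR simulations.
* **Label-permutation test.**  Within each ROI, labels are shuffled
  among the union of the two phenotypes' cells only, keeping both counts
  fixed and every position fixed; the statistic (pooled median
  cross-distance, or mean circle count) is recomputed through the same
  spatial code path, and the add-one p-value
  (1 + #extreme)/(1 + n_perm) is returned.  Conditioning on abundance
  and geometry isolates *co-location* from the separately-reported
  abundance differences.

**A calibration subtlety worth stating plainly.**  The permutation null
is *label exchangeability*, not spatial randomness.  A process in which
both phenotypes cluster identically around common hotspots — exactly the
shared-parent generator below with equal intensities — produces
exchangeable labels: every relabeling is distributionally equivalent to
the observed one, so the permutation test has nominal size against such
data and, by the same token, **no power** against it, for any statistic.
The package's validation quantifies this honestly: under shared-parent
attraction the permutation rejection rate stays at the α level.
Detecting that kind of joint clustering requires a *positional* null —
comparing the observed median against the CSR closed form or simulated
CSR at matched intensities — which the package provides alongside.  The
permutation test earns its keep where one type's placement is special
*relative to* the joint pattern (e.g. one phenotype tracks the other
more tightly than it tracks itself), and as a size-correct guard against
over-reading density artifacts.

## Synthetic tissue generator

The generator produces marked point patterns with known ground truth so
the whole pipeline is testable without any imaging data:

* **CSR**: each phenotype an independent Poisson process (counts Poisson
  with mean λ·area, positions uniform).
* **Shared-parent cluster process** (Neyman–Scott): latent parents are
  Poisson; both phenotypes' cells pick a uniform parent and scatter with
  isotropic Gaussian sd σ.  Sharing parents induces cross-type
  co-location with a single interpretable knob — smaller σ, tighter
  co-location; σ at the window scale recovers CSR behaviour.  Exact
  simulation, no MCMC.  On the plane, parents are laid in a 4σ-buffered
  window and offspring outside the target window dropped, keeping the
  interior intensity unbiased; on the torus, coordinates wrap.

Marker intensities are then drawn per cell: Normal(mean_pos, sd) for
markers positive in the cell's ground-truth phenotype, Normal(mean_neg,
sd) otherwise, truncated at zero.  Defaults mean_pos = 10, mean_neg = 1,
sd = 0.5 give well-separated channels (the noiseless limit recovers
labels perfectly; heavy overlap degrades gracefully and is exercised as
a smoke test).  The ground-truth column never enters the analysis path —
classification sees only coordinates and markers, which the tests assert
at the schema level.

Default conditions are conventions chosen to be tissue-realistic, since
no cell densities are published for these populations: a 1000×1000 µm
window (comparable to a scanned 200× region), per-type intensity
10⁻⁴ µm⁻² (≈100 cells of each rare type per region, in the
10⁻⁵–10⁻⁴ µm⁻² range plausible for infiltrating lymphocyte subsets),
parent intensity 5×10⁻⁵ µm⁻², and five ROIs per sample (matching the
5–7 regions a pathologist typically scans).  The three-group cohort
generator (`make_cohort()`) encodes the study design it emulates:
"rejection" σ = 5 µm, "non-rejection" σ = 15 µm, "control" CSR, equal
intensities — co-location strength, not abundance, separates the groups.

What the generator deliberately does **not** model: lobular/portal
anatomy (real infiltrates concentrate around portal tracts),
segmentation errors and doublets, intensity drift across slides, and
abundance differences between groups.  Passing tests therefore validate
the *measurement machinery*, not any claim about real allograft tissue.

## Validation problem sizes

The shipped test suite and `scripts/acceptance.R` validate at these
scales, chosen to make Monte-Carlo tolerances meaningful on a laptop:
100 random instances (≤200 points/set) for exhaustive-search
equivalence; 50 toroidal CSR replicates at λ_B = 0.01 µm⁻² (tolerance 3%
on the NN median, 5% on the circle count); 50 replicates per σ ∈ {5, 10,
20, 40} for attraction recovery, plus 50 at σ = 1000 vs 50 CSR for the
large-σ equivalence; 150–200 CSR tables (n_perm = 199) for type-I
calibration against binomial bounds; ≈1000 cells for the ≥99% phenotype
recovery contract; and 20 cohorts of 3+3+3 samples × 5 ROIs for the
group-ordering check.

## Known limitations

* No edge correction on the plane: bounded-window NN distances are
  biased slightly upward near borders, identically so across groups
  compared at equal geometry.
* The permutation test cannot detect symmetric joint clustering (see
  above); use the CSR references for that question.
* Single-sample inference only: aggregating p-values across a cohort,
  and any multiple-testing control, is left to the caller.
* Intensity normalisation, spillover, and segmentation QC are upstream
  of this package's contract, which starts at a trustworthy cell table.
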