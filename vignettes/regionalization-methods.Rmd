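---
title: "Delimiting phytogeographic districts from occurrence records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting phytogeographic districts from occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phytodistricts delimits biogeographic districts — subdivisions of a floristic
province characterized by their own species assemblages — from nothing more
than a table of species occurrence records, and then asks which environmental
gradients drive the compositional break. This vignette explains each model
choice, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical conventions adopted
where the underlying methods leave room.

## The analysis chain

### Gridding and curation

Records with missing or invalid coordinates, or falling outside an optional
study-region polygon, are rejected with a per-cause report. Retained records
are binned into square cells of `cell_size` degrees (default 0.25°, a common
compromise between spatial resolution and per-cell sample size at regional
extents). Cells are half-open, `[edge, edge + size)`, indexed from the
lower-left origin; the convention matters only for records exactly on a cell
edge and is stated so results are reproducible across implementations.
Point-in-polygon containment is closed: a record on the region boundary is
kept.

Dissimilarity estimates from tiny samples are unstable, so cells with fewer
than `min_records` records (default 5) are excluded — but their records are
not discarded. Each excluded cell's records transfer to exactly one retained
neighbour: the queen-adjacent retained cell with the highest original record
count, ties broken by lowest cell id, searching outward ring by ring up to
`max_ring` Chebyshev rings (default 2). Excluded cells are processed in
ascending record-count order against the *original* retained set, so the
outcome does not depend on transfer order and a cell can never be promoted
mid-pass. The rule is a design choice — any local, deterministic assignment
would do — and every transfer is logged so record totals can be audited:
the sum of cell counts is conserved exactly, up to orphans (excluded cells
with no retained neighbour in range) which are dropped with a warning and
listed.

### Species turnover

Composition is compared between cells with the beta-Simpson index

$$\beta_{sim}(i, j) = 1 - \frac{a}{a + \min(b, c)}$$

where $a$ is the number of shared species and $b$, $c$ the numbers unique to
each cell. Because the denominator uses $\min(b, c)$, a cell whose species
are a strict subset of another's scores 0 however large the richness gap;
the index therefore measures spatial *replacement* of species, not richness
difference — essential when sampling effort varies between cells, as it
always does in herbarium data. Values near 1 mean almost nothing is shared.
The matrix is computed by incidence linear algebra ($a$ from a
cross-product, $b$ and $c$ from row sums), which is exactly the set
definition; the test suite keeps a literal set-based oracle and checks
equality on a thousand random pairs.

### Clustering and districts

The turnover matrix is clustered by WPGMA (McQuitty linkage): the distance
from a merged cluster to anything else is the plain average of its two
parents' distances, so each parent group contributes equally regardless of
size — appropriate when cell clusters of very different sizes should still
be compared on composition, not membership count. The implementation
delegates to `stats::hclust(method = "mcquitty")`; a naive cubic
re-implementation in the test suite confirms merge orders and heights on
hundreds of random matrices.

The tree is cut into `k_groups` compositional groups (default 8, a
resolution at which sub-structure within districts is typically visible)
and consolidated to `k_final` districts (default 2): the `k_final` largest
groups become districts, and every cell of a minor group is reassigned to
the district it joins at the lowest cophenetic height. The assignment
provenance (`"cluster"` vs `"reassigned"`) is retained so reassigned cells
can be displayed or excluded downstream. Neither `k_groups` nor `k_final`
is selected automatically; they are scientific inputs.

The final districts are validated with a multi-response permutation
procedure. The statistic is the weighted mean within-district dissimilarity
$\delta = \sum_g (n_g/N)\,\xi_g$ with $\xi_g$ the mean pairwise
dissimilarity inside group $g$; weights $n_g/N$ are the common default. The
null permutes labels holding group sizes fixed, the test is one-sided
towards small $\delta$ (compositionally homogeneous districts), and the
chance-corrected agreement is $A = 1 - \delta_{obs}/\bar\delta_{perm}$.
P-values use the add-one convention $p = (\#\{\delta_{perm} \le
\delta_{obs}\} + 1)/(P + 1)$, so with the default $P = 999$ the smallest
attainable p is 0.001.

### Ordination

Non-metric multidimensional scaling embeds the cells in `k = 2` dimensions
by minimizing Kruskal's stress-1,
$\sqrt{\sum(d - \hat d)^2 / \sum d^2}$, where $d$ are configuration
distances and $\hat d$ monotone disparities fitted by isotonic regression on
the dissimilarity ranks. Ties (including zero dissimilarities) receive the
primary treatment: a tie block is ordered by current configuration distance
before the monotone fit, equivalent to an infinitesimal rank-space jitter.
Each restart alternates the isotonic fit with a Guttman (SMACOF) coordinate
update and backtracks if a step would increase stress, so the per-iteration
stress trace is non-increasing by construction — a property the tests assert
on every run. Convergence is a relative stress change below `tol = 1e-7`
within `max_iter = 500`; the reported fit is the best of `restarts = 20`
random starts plus one classical-scaling (metric) start, which alone
recovers any exactly embeddable configuration. Final scores are centred,
rotated to principal axes, and — in `axis_maps()` — sign-fixed per axis so
the first district has a non-negative mean, making exports invariant to the
arbitrary reflections of NMDS.

Stress is read qualitatively on the usual scale: ≤ 0.1 excellent, ≤ 0.2
good, < 0.3 fair, ≥ 0.3 poor. On realistic turnover matrices of ~150 cells
a 2-D stress around 0.2 is typical and acceptable for mapping broad
gradients.

### Environmental drivers

Per-pixel environmental values are averaged to the analysis grid with the
same half-open rule. Candidate variables then pass a greedy Pearson pruning:
while any pair exceeds `|r| = 0.8` (exposed as
`collinearity_threshold`), the member of the worst pair with the larger
mean absolute correlation to everything else is dropped, constants first,
every drop reported with its triggering pair. Survivors are z-scored
(sample sd, invertibly, with the means and sds stored).

Redundancy analysis regresses the z-scored incidence matrix on the z-scored
predictors; the proportion of compositional variance explained is the trace
ratio $\mathrm{tr}(\hat Y^\top\hat Y)/\mathrm{tr}(Y^\top Y)$ on centred
matrices. Z-scoring a binary incidence matrix is unusual but deliberate
here: it gives every species equal leverage in the response regardless of
prevalence, matching the equal-weight philosophy of the turnover index.

Forward selection builds the most parsimonious model stepwise. Candidates
are ranked by a Gaussian-likelihood AIC over the total residual sum of
squares, $n\ln(\mathrm{RSS}/n) + 2(p+1)$ — a *ranking* statistic, not an
absolute likelihood — which for a fixed step is equivalent to ranking by
marginal pseudo-F. The best candidate is admitted if its permutation
p-value is at most `alpha` (default 0.05). The permutation scheme is the
package's one deliberate departure from textbook practice: response rows
are permuted without restriction and the null statistic is the **maximum**
pseudo-F over all remaining candidates, not the F of the chosen one. This
makes the step p-value selection-aware — under a pure-noise candidate set
the probability of admitting anything at `alpha` is exactly `alpha`, a
calibration the acceptance tests verify by simulation. An AIC-only stopping
mode (`stop_rule = "aic"`) is available and yields a monotone
non-increasing AIC path.

### Relative environmental turnover and tracks

Each (standardized) environmental variable is regressed on the ordination
axes; the unit coefficient vector gives its direction, $r^2$ its strength,
and significance comes from permuting the variable's values across cells
(999 permutations by default) — the variable is permuted, not the scores,
matching standard vector-fitting practice. $r^2$ is invariant to rotations
of the ordination, and directions rotate with it.

Species whose every occupied cell lies in one district are that district's
exclusive (restricted) species; species recorded in both districts belong
to neither list. Per district, the collecting points of exclusive species
are linked by a minimum spanning tree — the classical summary of a shared
distribution pattern — over great-circle (haversine) distances on a
spherical Earth of radius 6371 km. Duplicate coordinates are collapsed,
points ordered lexicographically, and Prim's algorithm breaks ties towards
low indices, so the tree is deterministic. Connecting records rather than
cell centroids is a choice: the track should reflect where the plants were
actually collected.

## The synthetic study

The generator plants exactly the structure the analysis assumes, so every
claim the pipeline makes can be checked against a known truth.

* **Landscape.** A 12 × 12 grid of 0.25° cells over a 3° × 3° extent. The
  elevation surface is a west–east linear ramp (0–1500 m) plus a smoothed
  Gaussian field (sd 120 m, correlation length 2 cells); cells at or above
  750 m form district A, the rest district B. The ramp guarantees two
  contiguous districts, as real districts on an altitudinal gradient are;
  the noise field roughens the boundary so it does not fall on a grid line.
* **Community.** 50 species exclusive to the highland district, 10 to the
  lowland, 40 shared — an asymmetric pool mimicking the common situation
  where one district is far richer in restricted species. Sampling effort
  is Poisson with mean 60 records per cell (the intensity of a
  well-collected regional herbarium database; negative-binomial
  overdispersion is available), each record drawing a species uniformly
  from the cell's district pool, thinned by a detection probability. The
  per-cell record-count distribution of real databases is unknown;
  Poisson/NB is an explicit assumption, not an estimate.
* **Environment.** District-conditional Gaussian layers: soil Ca
  0.93 ± 0.49 (highland) vs 0.40 ± 0.16 mg, soil Mg 0.29 ± 0.08 vs
  0.32 ± 0.07 mg, precipitation seasonality 78 vs 88 (± 6) CV%, and
  driest-quarter precipitation 40 vs 25 (± 8) mm. The Mg contrast is
  deliberately weak — a driver near the detection limit — while Ca and the
  precipitation proxies are strong. Optional spatial autocorrelation
  smooths a layer over a configurable length.

What the generator does **not** emulate: taxonomic misidentification and
synonymy, georeferencing error, spatially aggregated species ranges within
a district, collector bias towards roads and towns, and environmental
layers with shared spatial trends. Passing the planted-recovery tests
therefore shows the chain of methods is implemented correctly and is
sensitive at realistic signal strengths — not that real herbarium data meet
the generator's assumptions.

A `full_scale` preset (571 species: 292/32 exclusive plus 247 shared, on a
13 × 12 grid) exercises the pipeline at the scale of a full regional
flora; it completes in well under a minute on one CPU.

## Problem sizes and numerical conventions

The test suite runs the full pipeline on the default 144-cell landscape and
checks: district recovery with adjusted Rand index > 0.9; MRPP calibration
(1,000 null replicates at 199 permutations inside the exact binomial 99%
band); NMDS recovery of planar configurations to stress < 10⁻³ and
Procrustes error < 10⁻⁶; RDA against its closed form to 10⁻¹⁰; forward
selection admitting a perfect predictor at the minimal p and staying at the
nominal level on 200 pure-noise replicates; envfit null p-values uniform
over 500 replicates; WPGMA against a naive oracle on 200 random matrices;
and MST minimality against exhaustive enumeration of all 16,807 spanning
trees on 100 random 7-point sets. These sizes were chosen so the whole
suite completes in a few minutes while keeping each check statistically
meaningful.

Degenerate inputs are errors, not silent results: two empty species sets
(the index is 0/0), a cell with no species, NaN dissimilarities, constant
variables reaching standardization or vector fitting, rank-deficient
predictor matrices (the dependent columns are named), fewer groups than
districts requested, and a single-district landscape.

## Limitations

* `k_groups` and `k_final` are inputs; the package deliberately does not
  select the number of districts.
* Only the turnover component of beta diversity is implemented; nestedness
  decompositions are a natural extension.
* The merge rule for under-sampled cells is one defensible convention among
  several; with other rules the retained-cell set can differ near the
  threshold.
* MRPP weights, the AIC form, and the selection-aware permutation are
  documented conventions; alternatives exist in the literature and would
  change p-values at the margin, not the scientific picture on strong
  signals.
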