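---
title: "Multi-scale spatial statistics for the tumor microenvironment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale spatial statistics for the tumor microenvironment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTME)
```

## The model

spatialTME treats each imaged tissue region as a *marked point pattern*: a
set of cell centroids in a rectangular observation window (coordinates in
micrometers), each cell carrying a set of cell-type marks. Marks come from
a two-layer vocabulary: ten raw phenotype labels assigned by the upstream
image-analysis classifier (combinations of PAX5, CD163, CD3, CD8, PD-1 and
PD-L1 positivity, plus "other") and thirteen analysis cell types organized
as three lineages — Tumor, Tcell, Macrophage — with marker-defined
subtypes. The hierarchy is multiplicative: a `CD3+CD8+PD-1+` cell is
simultaneously a `Tcell`, a `CD8+ Tcell` and a `CD3+CD8+PD1+ Tcell`, and
contributes to the statistics of all three. "Other" cells carry no marks
but count toward the region total, so normalized counts use the full
denominator.

Per region, four families of statistics are computed.

**Non-spatial.** Normalized count `N_i / N_total` and density
`lambda_i = N_i / area` per type, where the area is that of the observation
window.

**Local.** For an ordered type pair (i, j): the median of the distances
from each type-i cell to its nearest type-j cell (MMD), and the median
absolute deviation of that set (MADMD). For i = j the nearest *other* cell
is used, so distances are strictly positive. The *spatial score* chains the
three lineages: per tumor cell, the distance to its nearest T cell divided
by the distance from that T cell to its nearest macrophage; the region
summary is the median (MSS) and MAD (MADSS) over tumor cells. Scores whose
denominator is zero (a T cell coincident with a macrophage) are excluded;
if all are excluded the statistic is missing.

**Radius-based.** At each radius r (default 5, 10, 25, 50, 75, 100 um;
5–25 "small", 50–100 "large"):

* `F_i(r)` — empty-space function: the fraction of points of an evenly
  spaced lattice whose nearest type-i cell lies within r;
* `G_ij(r)` — nearest-neighbour function: the fraction of type-i cells
  with a type-j cell within r;
* `K_ij(r)` — Ripley's K: the mean number of type-j cells at distance
  strictly less than r from a type-i cell, divided by `lambda_j`;
* `L_ij(r) = sqrt(K_ij(r) / pi)` — the variance-stabilized form, whose
  null expectation is the radius itself.

Each raw value is standardized into a z-value against complete spatial
randomness (CSR):

    z = (raw - baseline) / sigma_null

The baselines are the closed forms `F_theo = 1 - exp(-lambda_i pi r^2)`,
`G_theo = 1 - exp(-lambda_j pi r^2)`, `K_theo = pi r^2`, `L_theo = r`.
Besides explicit pairs, each type gets the `"*"` variants `G_i*`, `K_i*`,
`L_i*` against "all cells of a type unequal to i", which here includes
unmarked "other" cells.

**Global.** A chi-squared inhomogeneity statistic over a 5 x 5 equal-area
partition of the window, `sum_R (lambda_i(R) - lambda_i)^2 / lambda_i`,
and the median (MD) plus MAD (MADD) of *all* pairwise i–j distances, with
the zero diagonal excluded when i = j.

## The Monte-Carlo null

The standardization sigma is not given in closed form by the source
methodology (it defers to external results that are not reproduced), so
spatialTME estimates the null distribution by simulation: `n_null`
(default 199) placements of the observed counts uniformly in the observed
window (a binomial process — counts fixed, positions uniform), evaluating
the raw statistic on each. The sample mean and standard deviation per
radius define the null. Seeds for each null model are derived
deterministically from the configuration seed and the (statistic, window,
counts) triple, so identical configurations give identical features, and a
cache environment can be shared across regions with the same window.

Two consequences are worth stating plainly:

* **Edge effects.** The raw estimators apply no edge correction, exactly
  as defined. Near the boundary, neighbourhoods are truncated, biasing raw
  K (for example) downward. Because the null is simulated in the *same*
  window with the *same* counts, the null mean carries the same bias.
  `null_config(center = "null")` standardizes against the null mean and is
  what the calibration tests use: under CSR the resulting z-values have
  mean ~0 and variance ~1. The default `center = "theoretical"` uses the
  printed closed forms, faithful to the defining formulas but retaining an
  edge-bias offset of a fraction of a standard deviation — a constant
  offset per (window, counts, radius), harmless for cohort-level contrasts
  computed at matched windows.
* **Undefined statistics.** When a replicate (or the observed pattern)
  has insufficient counts, the value is missing, never an error; a null
  model undefined in more than half its replicates is flagged unreliable.

The F-function lattice is the set of cell centres of an `nx x ny`
partition of the window, default 100 x 100 (10,000 points keeps the
discretization error well below the null sigma); tests use coarser grids.

MADs are plain medians of absolute deviations — no 1.4826 consistency
constant — matching the defining formulas; the constant is a parameter for
users who want the R convention. Medians of even-length sets are the mean
of the two central order statistics throughout.

## Feature schema and patient aggregation

`feature_schema()` enumerates a deterministic, reversible key per
statistic: per type the normalized count, density, chi-squared, F at each
radius and the `"*"`-variant G/K/L at each radius; per configured ordered
pair MMD/MADMD and G/K/L at each radius; per unordered pair MD/MADD; plus
MSS/MADSS once. This realizes the "4 functions x 6 radii = 24 features per
cell type (pair)" accounting with F attributed to types and G/K/L to
pairs. Directional statistics are emitted per ordered pair exactly as
listed; MD/MADD, being symmetric, once per unordered pair.

The default pair list is the nine ordered pairs among the three lineages.
The source study evaluated a larger hand-curated pair set (58 pairs) that
was never published as a list; the default here is a documented
approximation, and `cell_type_hierarchy()` accepts any pair list.

Patient-level aggregation is the unweighted mean over a patient's regions
of one class (tumor and border are kept as separate matrices end to end),
ignoring missing values; a patient with no regions of a class has a fully
missing row. Features observed in half the patients or fewer are dropped
(the "> 50% observed" rule evaluated per region class); the remaining
missing entries are imputed with the per-feature median over observed
patients.

## Synthetic data: what it emulates, and what a green test means

The simulators generate the *spatial regimes* the statistics are designed
to distinguish, not tissue realism:

* `simulate_csr()` — homogeneous Poisson cells per phenotype (optionally
  with fixed counts, the conditioning used by the null);
* `simulate_clustered()` — a Thomas process (Poisson parents, Poisson
  offspring counts, Gaussian displacement with spread `sigma`). Offspring
  falling outside the window are re-drawn rather than clipped, preserving
  intensity at the cost of slightly compressing clusters near edges;
* `simulate_hardcore()` — sequential inhibition with a minimum
  inter-point distance;
* `simulate_cross_pair()` — attraction by shared cluster parents between
  two phenotypes (`shared_fraction` controls coupling; 0 is independence)
  or repulsion by an exclusion distance around the first type. Repulsion
  re-samples excluded candidates by default so counts stay matched across
  cohort arms; plain thinning is available.
* `simulate_cohort()` — a two-arm cohort in which both arms share all
  per-phenotype intensities (counts uninformative by construction) and the
  effect arm adds T cell–macrophage attraction; survival is exponential
  with a group hazard ratio and administrative censoring. Exponential
  survival is deliberate minimalism: only rank-based tests consume it.

A green structure-recovery test therefore establishes that the
standardized statistics *detect the regime they target at the radii near
its scale*, under matched windows and intensities. It does not establish
robustness to irregular window geometry, within-region intensity
gradients, segmentation noise, or phenotype misclassification — none of
which the generators produce.

Cohort defaults for the acceptance properties were fixed once: 40 patients
(about half the motivating cohort), hazard ratio 6 against a 36-month
control median — giving 12-month poor-outcome probabilities of roughly
0.21 vs 0.75 — and attraction with `shared_fraction = 0.9`,
`sigma = 15` um. These sizes give the downstream contrasts (full-feature
vs counts-only forests; consensus clustering vs planted groups) stable
power at desk scale.

## Downstream analyses

**Hierarchical clustering** of patient profiles uses distance
`1 - Pearson correlation` with Ward linkage (`ward.D2`), erroring on
constant profiles, for which correlation is undefined.

**Consensus NMF.** Standardized features are signed, so each feature is
shifted by its minimum and scaled to [0, 1] before factorization (the
source methodology is silent on this; min-max is the package's documented
choice, and constant features are dropped). Factorization uses
multiplicative Kullback-Leibler (Brunet) updates with uniform random
initialization; the divergence is checked every ten iterations and must be
non-increasing; iteration stops at a relative change below 1e-5 or 2,000
iterations. "20 iterations" of consensus is read as 20 random restarts per
K in 2..5: each restart assigns samples to their argmax coefficient
cluster (ties to the lowest index), the consensus matrix is the fraction
of restarts co-clustering each pair, final labels cut an average-linkage
tree of `1 - consensus`, and the cophenetic correlation summarizes
stability. Top features per basis column are those within 0.8 of the
column maximum.

**Supervised analysis.** Outcome is dichotomized at 12 months of
event-free survival: event before the cutoff is poor, event-free follow-up
past it is good, and patients censored before the cutoff are excluded
(their class is undetermined; the count is logged — the source does not
state its handling). Classification uses a bagged CART forest (gini
splits, bootstrap with replacement, `floor(sqrt(p))` candidate features
per node, nodes grown to purity) with 100,000 trees by default per the
source settings; ~1,000 trees give stable out-of-bag AUC at cohort sizes
of tens to hundreds and are used in tests. Performance is the AUC (midrank
statistic) of out-of-bag probabilities: a patient's prediction only ever
uses trees whose bootstrap excluded that patient. Importance is the mean
drop in out-of-bag AUC over 10 joint permutations of a feature group (one
shared row permutation per draw, preserving within-group dependence), with
a sign attached from the poor-vs-good mean contrast. Note that out-of-bag
evaluation is *pessimistic* on signal-free data: a sample's own class is
underrepresented by ~1/n in its out-of-bag trees, which anti-ranks classes
and pushes the no-signal AUC below 0.5 — a property of the out-of-bag
construction itself, visible in any faithful implementation.

**Survival.** Kaplan-Meier curves, the standard log-rank chi-squared test
and number-at-risk tables come from the survival package.

## Numerical and degenerate-input choices

* K counts neighbours at distance strictly less than r; F and G use
  "within r" — as the defining formulas are written. All four are
  non-decreasing in r.
* A cell is never its own neighbour: same-cell pairs are excluded by cell
  identity, which also covers overlapping hierarchy marks (for example a
  `Tcell`–`CD8+ Tcell` pair statistic never counts a cell against itself).
* Coincident cells of *different* types legitimately yield zero distances.
* Observation windows default to the per-region bounding box (configurable
  padding, default 0) because exported tables carry no window metadata; a
  declared window from configuration takes precedence. The matched-window
  null absorbs the mild dependence this induces.
* `chi_squared_inhomogeneity` bins boundary cells into the last rectangle
  (right-closed binning); the statistic is translation invariant.
* Empty regions yield an all-missing feature vector of full schema length;
  zero-count types yield zero counts and densities but missing spatial
  statistics.

## Known limitations

* No inhomogeneous-intensity variants of F/G/K/L: a within-region density
  gradient reads as positive clustering, which is by design (the
  chi-squared statistic reports it) but should be kept in mind.
* The Monte-Carlo null is the only sigma backend; closed-form sigmas
  could be added as an alternative but are not recoverable from the source
  text.
* The exact published feature totals (4,494 extracted / 2,980 retained)
  are not reproducible without the unpublished pair list and the original
  cohort's missingness pattern, and are out of scope.
* Memory for the forest grows linearly in trees; the 100,000-tree default
  is faithful to the source but a few thousand trees are statistically
  sufficient at these cohort sizes.
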