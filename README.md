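# spatialTME

Multi-scale spatial statistics for the tumor microenvironment (TME) from
multiplex-immunofluorescence cell tables.

Modern multiplex imaging reduces a tissue section to a table of cell
centroids with phenotype labels. The open question for a translational
analyst is whether the *arrangement* of immune and tumor cells — not just
their abundance — carries prognostic information. spatialTME implements a
complete pipeline for that question, developed around primary CNS lymphoma
cohorts but applicable to any cohort of phenotyped cell coordinates:

1. **Feature extraction per imaged region**, treating each region as a
   marked point pattern in a rectangular window:
   - non-spatial: normalized counts `N_i / N_total`, densities
     `lambda_i = N_i / area`;
   - local: median minimal distance MMD and its MAD per cell-type pair,
     and the tumor -> nearest T cell -> nearest macrophage *spatial score*;
   - radius-based: the empty-space function `F_i(r)`, nearest-neighbour
     function `G_ij(r)`, Ripley's `K_ij(r)` and `L_ij(r) = sqrt(K/pi)` at
     radii 5–100 um, each standardized into a z-value
     `(raw - baseline) / sigma` against a seeded Monte-Carlo
     complete-spatial-randomness null matched to the region's window and
     observed counts;
   - global: a 5 x 5 chi-squared inhomogeneity statistic and the
     median/MAD of all pairwise distances (MD/MADD).
2. **Patient-level matrices**: mean over regions per region class (tumor /
   border) ignoring missing values, a "> 50% observed" missingness filter,
   median imputation.
3. **Unsupervised analysis**: hierarchical clustering (Pearson distance,
   Ward linkage) and consensus non-negative matrix factorization (Brunet
   multiplicative KL updates, 20 seeded restarts, K = 2..5, cophenetic
   stability, top features at 0.8 relative basis contribution).
4. **Supervised analysis**: 12-month event-free-survival dichotomization,
   a random-forest classifier (bagged CART, sqrt-mtry, grown to purity,
   out-of-bag AUC) with joint permutation importance and outcome-direction
   signs, and Kaplan-Meier / log-rank survival comparisons.
5. **Simulators** for CSR, Thomas-clustered, hard-core, and cross-type
   attraction/repulsion patterns, plus two-arm synthetic cohorts with
   matched counts and survival, so the whole stack is testable without
   external data.

The cell-type vocabulary is the two-layer hierarchy used in PCNSL studies:
ten raw phenotypes (PAX5/CD163/CD3/CD8/PD-1/PD-L1 combinations plus
"other") expanding into thirteen analysis types across the Tumor, Tcell
and Macrophage lineages; a `CD3+CD8+PD-1+` cell counts as `Tcell`,
`CD8+ Tcell` and `CD3+CD8+PD1+ Tcell` simultaneously.

See `vignettes/spatialTME-methods.Rmd` for the statistical details and
design decisions.

## Worked example

A 12-patient synthetic cohort in which both arms share all cell-type
intensities (counts are uninformative by construction) and the
poor-outcome arm has T cell–macrophage attraction:

```r
library(spatialTME)
h <- lineage_hierarchy()

cohort <- simulate_cohort(n_patients = 12, regions_per_patient = 2,
                          hazard_ratio = 6, seed = 7, hierarchy = h)
cfg <- null_config(n_null = 49, grid_dim = c(25, 25), seed = 7,
                   center = "null", cache = new.env(parent = emptyenv()))
features <- lapply(cohort$patterns, extract_region_features,
                   hierarchy = h, radii = c(10, 25, 50), null_cfg = cfg)
fm <- filter_and_impute(aggregate_patient_features(features)$tumor)
dim(fm)
#> [1]  12 158
```

The standardized cross-type K function separates the arms by more than
thirty null standard deviations, while counts cannot:

```r
round(tapply(fm[, "K|Tcell|Macrophage|r25"], cohort$groups[rownames(fm)], mean), 2)
#> control  effect
#>   -0.31   33.81
```

Outcome classification and unsupervised structure:

```r
labels <- dichotomize_outcome(cohort$survival)   # 12-month EFS: poor/good
rf <- rf_oob_classify(fm, labels, n_trees = 2000, seed = 7)
rf
#> tme_rf: 2000 trees, mtry 12, 12 patients, OOB AUC 0.750

cc <- consensus_cluster(nmf_preprocess(t(fm)), k_range = 2:3,
                        n_runs = 10, seed = 7)
round(sapply(cc, `[[`, "cophenetic"), 3)
#>     2     3
#> 1.000 0.985
adjusted_rand_index(cc[["2"]]$labels[rownames(fm)], cohort$groups[rownames(fm)])
#> [1] 1

km <- km_logrank(cohort$groups, cohort$survival)
c(chisq = round(km$chisq, 2), p = signif(km$p_value, 3))
#>  chisq      p
#> 6.4400 0.0111
```

The consensus clusters recover the planted arms exactly (adjusted Rand
index 1), the out-of-bag AUC of 0.75 reflects the noisy link between arm
and 12-month outcome at this cohort size, and the log-rank test confirms
the survival split.

## Command line

Every stage is also a subcommand of the bundled CLI
(`system.file("cli", "tme.R", package = "spatialTME")`):

```sh
Rscript tme.R simulate         --config cfg.json   # writes cell CSVs + survival.tsv
Rscript tme.R extract-features --config cfg.json   # features_<class>.tsv + sidecars
Rscript tme.R cluster          --config cfg.json
Rscript tme.R classify         --config cfg.json
Rscript tme.R survival         --config cfg.json
Rscript tme.R run-all          --config cfg.json
```

The JSON config holds paths (`cell_tables_dir`, `survival_table`,
`output_dir`, `hierarchy_file`), the radius set, null-model settings
(`n_null`, `grid_dim`, `center`), analysis settings (`k_min`/`k_max`,
`n_runs`, `n_trees`, `n_perm`, `efs_cutoff`) and one global `seed` that
determines every stochastic stage. Flags of the form `--key value`
override config entries. Cell tables are delimited text with columns
`x, y, phenotype, region_id, region_class, patient_id` (header names
remappable); survival tables are TSV with
`patient_id, time_months, event`.

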