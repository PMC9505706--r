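# taxrisk

Microbiome-based colorectal-disease risk modelling from 16S rRNA genus
abundance profiles. The package turns QIIME-classic OTU count tables into
genus-level feature matrices by **hierarchical taxonomic accumulation**,
trains gradient-boosted tree models that score inflammatory bowel disease
(IBD) or colorectal cancer (CRC) risk from stool microbiome composition,
and transfers a trained model onto external cohorts (e.g. diet-intervention
animal arms) to rank their disease risk. It is aimed at microbiome
researchers who want a tested, seeded, end-to-end pipeline from OTU table
to cross-validated risk scores.

## The feature encoding

16S reference databases assign many OTUs only loosely at genus level; the
usual choice is to discard those reads or lump them into an "unclassified"
bin. Taxonomic accumulation instead keeps every genus-level feature (with
parenthesised fallback labels such as `(Lachnospiraceae)` for taxa resolved
only to family) and encodes each genus together with its clade context. For
each sample, after collapsing OTUs to genera, transforming counts with
log2(c + 1) and normalising each sample to sum to one (V_G), the feature
value of genus *g* is

```
V_ACC(g) = V_G(g) + k1·V_F + k2·V_O + k3·V_C + k4·V_P + k5·V_K,   ki = 10^-(1+i)
```

where V_F … V_K are the within-sample sums of V_G over all genera sharing
*g*'s family, order, class, phylum and kingdom. The geometric weights keep
each clade term below any genus-level signal while letting imprecisely
classified genera contribute weight through their verified upper taxonomy,
and the log2 transform damps the influence of zero inflation.

Around this encoding the package provides:

- **I/O** — QIIME-classic OTU tables (SILVA `D_0__` / Greengenes `k__`
  lineage dialects), sample metadata, lossless feature-matrix TSVs.
- **Diversity** — seeded rarefaction, observed/Chao1/Shannon/Gini-Simpson,
  Bray-Curtis dissimilarity, PCoA, PERMANOVA.
- **Group statistics** — F-test-gated t tests, exact tie-aware
  Mann-Whitney U, Kruskal-Wallis, chi-squared, Benjamini-Hochberg
  correction, fold-change tables.
- **Risk model** — least-squares gradient boosting (500 trees, depth 3,
  learning rate 0.1) on 0/1 labels, repeated stratified 7:3 random splits
  (30 iterations by default), ROC/AUC, Youden operating points, impurity
  and permutation feature importance, model persistence, and
  feature-aligned scoring of external cohorts against the conventional 0.5
  risk threshold.
- **Simulator** — zero-inflated compositional cohorts with planted
  fold-change effects and a host-shifted four-arm transfer cohort
  (Normal / HFD / NFE / NFW), so the whole pipeline is testable without
  any data download.

Everything user-facing takes a data frame (tibble) first and returns a
tibble, chains with the pipe, and has `tidy()`/`glance()`/`autoplot()`
methods for the fitted objects.

## Worked example

Simulate a clinical-style cohort (60 controls vs 60 cases with the seven
planted fold changes 23, 13, 7, 0.17, 0.27, 0.32, 0.34), preprocess it,
and cross-validate the risk model:

```r
library(taxrisk)

spec <- synthetic_spec(n_control = 60, n_case = 60)
sim <- simulate_cohort(spec, seed = 42)

features <- preprocess_otu(sim$otu) |> select_features()
cv <- cross_validate_risk(features, sim$metadata$group,
                          n_iter = 10, base_seed = 42)
cv
#> <taxrisk CV> 10 iterations at 70:30
#>   AUC mean 0.9988, sd 0.0022, min 0.9938, max 1.0000

head(feature_importance(cv, "impurity"), 5)
#> # A tibble: 5 x 4
#>   feature  importance     sd method
#>   <chr>         <dbl>  <dbl> <chr>
#> 1 Genus001    0.403   0.246  impurity
#> 2 Genus005    0.361   0.217  impurity
#> 3 Genus003    0.130   0.0874 impurity
#> 4 Genus012    0.0901  0.179  impurity
#> 5 Genus010    0.00731 0.0129 impurity

sim$truth   # the planted genera: Genus001 (23x), Genus003 (13x), Genus005 (7x), ...
```

The mean AUC is the average over ten independent stratified 70/30
train/test splits; the importance table shows that the top-ranked features
are exactly the genera carrying the planted effects (Genus001, Genus005,
Genus003 are the 23x, 7x and 13x markers). `autoplot(cv)` draws the AUC
box plot, `plot_roc_curves(cv)` the per-iteration ROC curves.

Scoring an external cohort with a trained model:

```r
rat <- simulate_transfer_groups(spec, seed = 99,
                                taxonomy = build_taxonomy(spec, seed = 42))
model <- fit_risk_model(features, sim$metadata$group, seed = 42)
scores <- score_cohort(model, preprocess_otu(rat$otu), rat$metadata)
autoplot(scores)   # per-arm risk boxplots against the 0.5 threshold
```

A thin command-line wrapper over these functions ships in
`inst/scripts/taxrisk` (subcommands `simulate`, `preprocess`, `run`).

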