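# rarebef

Tools for asking whether the diversity of **rare** or of **abundant** soil
taxa drives **ecosystem multifunctionality**, and how the **stochasticity of
community assembly** modulates that relationship — the analysis chain of a
multitrophic soil survey (archaea, bacteria, fungi, protists across
hundreds of fields on a latitude gradient, with a 16-function panel),
re-implemented as a tested, reusable R package with a synthetic-data
generator standing in for field data.

## What it computes

* **Abundance partitioning** — phylotypes classified *abundant*
  (dataset-level relative abundance > 0.5%), *rare* (< 0.05%) or
  *intermediate* within each organism group; alternative sensitivity schemes
  (1%/0.1%, 0.1%/0.01%) included.
* **Multidiversity** — per-sample mean of min–max standardized richness,
  `STD = (X − X_min)/(X_max − X_min)`, across the four organism groups,
  computed per subcommunity.
* **Multifunctionality (EMF)** — averaging, service-weighted, and
  principal-coordinate indices of 16 standardized functions (the fungal
  plant-pathogen function inverted before standardization).
* **BEF regressions** — OLS of EMF on multidiversity with standardized
  slopes; Spearman matrices of group diversities vs single functions.
* **Supporting phylotypes** — taxa positively rank-correlated with a
  function at raw P < 0.01, aggregated by abundance class and ecosystem
  service; Wilcoxon rank-sum comparison of support breadth.
* **Co-occurrence networks** — cross-kingdom Spearman networks at
  |ρ| > 0.6 and BH-FDR q < 0.001, node support scores (Pearson r vs EMF),
  degree–support regressions, GraphML/GEXF export.
* **Stochasticity ratio (ST)** — abundance-weighted Bray–Curtis null model
  (fixed per-sample richness, occurrence-frequency membership, regional
  proportional abundances, 1,000 randomizations), two-branch bounded ratio
  in [0, 1]; ST across 19 rank bins of EMF or multidiversity with
  polynomial trends.
* **Moving windows** — BEF slope and ST in windows of 30/40 consecutive
  samples along the latitude gradient (199/189 windows for 228 samples)
  and the slope-vs-ST polynomial relationship.
* **Synthetic survey generator** — seeded, with tunable rare/abundant
  diversity–function coupling (`beta_rare`, `beta_abundant`) and
  environmental filtering strength (`beta_env`); defaults emulate the
  228-field survey design and its fixed depths.

See `vignettes/rare-taxa-multifunctionality.Rmd` for the model details and
every declared design choice.

## Worked example

```r
library(rarebef)

ds <- generate_dataset(simulation_config(seed = 7))   # 228 fields, 4 groups
classes <- lapply(ds$tables, classify_phylotypes)
div <- diversity_table(ds$tables, classes)
mf  <- multifunctionality(ds$functions)

bef_regression(div$multidiversity[, "rare"],     mf$averaging)
bef_regression(div$multidiversity[, "abundant"], mf$averaging)
```

```
<regression_result> slope = 0.4202 (std 0.927), R2 = 0.860, P = 2.56e-98, n = 228
<regression_result> slope = 0.0805 (std 0.083), R2 = 0.007, P = 0.214, n = 228
```

The rare-subcommunity multidiversity predicts averaging multifunctionality
strongly and positively (standardized slope 0.93, recovering the
generator's `beta_rare = 0.8` coupling), while abundant-taxa diversity
shows no relationship — the asymmetry the analysis is designed to detect.

Stochasticity of assembly, on the rare subcommunity pooled across groups
(9,341 phylotypes here; a few minutes at 100 randomizations):

```r
pooled <- pool_class_matrix(ds$tables, classes, "rare")
stochasticity_ratio(pooled, n_null = 100, seed = 1)
#> <stochasticity_result> 228 samples, 100 nulls: ST = 0.708
```

ST near 1 means pairwise community similarity is indistinguishable from
the null expectation (stochastic assembly); lower values indicate
deterministic structuring.

Full pipeline with every stage written to disk:

```r
cfg <- pipeline_config(simulation = simulation_config(seed = 7),
                       n_null = 1000, seed = 7)
run_pipeline(cfg, "out/")
```

or from the command line (`inst/cli/rarebef`):

```sh
Rscript inst/cli/rarebef all --config config.yml --out out/
```

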