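---
title: "Rare-taxa diversity, multifunctionality and assembly stochasticity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-taxa diversity, multifunctionality and assembly stochasticity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarebef)
```

## The scientific question

Soil communities are dominated, in species number, by taxa that are
individually very scarce — the "rare biosphere" — while a handful of
abundant taxa carry most of the biomass. Whether ecosystem functioning
tracks the diversity of the many rare taxa or of the few abundant ones, and
whether the *assembly regime* of a community (stochastic drift and dispersal
versus deterministic environmental filtering) modulates that
biodiversity–ecosystem-function (BEF) relationship, are the questions this
package operationalizes. It provides the full analysis chain for a
multitrophic survey design — archaea, bacteria, fungi and protists sampled
across hundreds of fields along a latitude gradient, with a panel of 16
measured ecosystem functions — plus a synthetic-data generator so every
stage is testable without access to field data.

## Abundance partitioning

Within each organism group, a phylotype's dataset-level relative abundance
is its total count divided by the group's grand total, computed after
rarefaction to the group's fixed depth. The default scheme labels
phylotypes **abundant** above 0.5%, **rare** below 0.05%, and
**intermediate** otherwise; two alternative sensitivity schemes (1%/0.1% and
0.1%/0.01%) are available via `alternative_schemes()`. Inequalities are
strict, so a phylotype sitting exactly on a threshold is intermediate.
Classification is computed once per dataset and held fixed; per-sample
quantities (e.g. the share of reads in rare taxa) derive from that single
labeling. We read "total sequences" as the within-group pool so that the
four groups' very different sequencing depths never mix.

## Diversity and multidiversity

Richness (number of phylotypes with count > 0) is the biodiversity metric.
For each organism group and each subcommunity (rare, abundant, whole),
richness is min–max standardized across samples,
`STD = (X - Xmin) / (Xmax - Xmin)`, and **multidiversity** is the
per-sample mean of the four groups' standardized richness. Standardization
is done within each group × subcommunity combination, so the rare index is
scaled against the rare richness range only; this makes the rare and
abundant indices parallel constructions rather than shares of a common
scale. Samples with zero richness in a group participate (they set the
minimum); a constant richness vector is an error, because min–max
standardization is undefined without contrast.

An open design point was whether richness should be computed on rarefied
counts or on raw presence; we compute it on the rarefied tables, matching
the even-depth rationale of rarefaction, and keep all-zero columns after
rarefaction so classification sets remain stable across stages.

## Multifunctionality

The 16 functions span four ecosystem services: nutrient provisioning (9
functions), element cycling (5), pathogen control (1) and plant–microbe
symbiosis (1). The pathogen function is the relative abundance of fungal
plant pathogens and enters with sign −1 (multiplied by −1 before
standardization), so *reduced* pathogen load counts as higher functioning.
After inversion, every function is min–max standardized to [0, 1]. Three
indices are computed:

* **averaging** — the per-sample mean of the 16 standardized functions;
* **weighted** — the mean of the four service-group means, so each service
  contributes equally despite the unequal function counts (9/5/1/1); it
  coincides with averaging exactly when groups have equal sizes;
* **multidimensional** — axis-1 scores of a principal coordinate analysis
  (classical scaling) of the Euclidean distance matrix of the standardized
  functions. The choice of distance is open here;
  Euclidean distance makes classical scaling equivalent to a PCA of the
  standardized matrix, which we consider the most defensible reading of a
  "principal coordinate multifunctionality index". Because ordination sign
  is arbitrary, the axis is oriented to correlate non-negatively with the
  averaging index. Only the first axis is used as the index; further axes
  and all eigenvalues are exposed but unused.

## BEF regressions and the supporting-phylotype screen

BEF strength is the OLS slope of multifunctionality on multidiversity; both
the raw slope and the standardized slope (z-scored variables; equal to the
Pearson correlation in simple regression) are reported with the two-sided
slope p-value. A phylotype **supports** a function when its per-sample
relative abundance is positively Spearman-correlated with that function at
raw two-sided p < 0.01 — uncorrected by design (the screen is defined on raw p-values); the FDR
machinery exists in the package but is deliberately off here. Correlations use relative abundance within each group's rarefied
table, which is depth-robust. A prevalence filter (default: present in
≥ 10% of samples) is applied first; this filter is a declared choice of this package, logged and configurable —
zero-inflated rank statistics on near-absent taxa are otherwise dominated
by ties. Summaries aggregate supporters by abundance class, by ecosystem
service, and per subcommunity, and a two-sided Wilcoxon rank-sum test
(normal approximation with tie correction) compares the number of functions
supported between abundant and rare supporters. If every supporter supports
the same number of functions the test is degenerate and p = 1 is returned.

## Co-occurrence networks

Candidate nodes are the phylotypes of one abundance class from all four
groups passing a 20% prevalence filter (declared: rank correlations at
|ρ| > 0.6 need a reasonably dense matrix). Counts are converted to
within-group relative abundances before pooling so depth differences
between groups cannot fabricate edges. All pairwise Spearman correlations
are tested, Benjamini–Hochberg correction is applied across all tested
pairs within one network (BH is the standard choice where a procedure is
not otherwise pinned down), and edges require |ρ| > 0.6 and
q < 0.001, both strict. Node support scores are Pearson correlations with
a multifunctionality index; nodes with r > 0 carry a display flag, and the
degree–support OLS regression runs over displayed nodes. Networks export to
GraphML (igraph) and GEXF 1.2 (built-in writer) plus TSV tables.

## The stochasticity ratio

Community assembly stochasticity is quantified with a null-model ratio on
abundance-weighted Bray–Curtis similarity, `C = 1 - BC`. Null communities
preserve each sample's observed richness, draw phylotype membership with
probability proportional to occurrence frequency across samples, and fill
abundances proportionally to the regional (dataset-level) relative
abundances, rescaled to the sample's read total (left real-valued; BC is
defined for continuous abundances). The expected similarity `E` is the mean
over `n_null` randomizations (default 1,000). The one-line definition of the
statistic — the ratio of mean expected to observed similarity — is
unbounded whenever `C < E`, so, following the normalized-stochasticity
framework, the per-pair ratio is two-branched: `E/C` when
`C >= E` (determinism drives similarity) and `(1-E)/(1-C)` when `C < E`
(determinism drives dissimilarity). Both branches lie in [0, 1]; a pair
with `C = E` (including the degenerate `C = E = 1`) is fully stochastic,
ratio 1. `ST` is the mean over pairs; the plain unbounded ratio is also
reported for reference. The frequency-proportional fixed-richness scheme
implemented here is the abundance-weighted default of that framework's
family of null algorithms, exposed behind a single function so it can be
swapped; the membership draw uses exponential sort keys
(Efraimidis–Spirakis),
which is equivalent in distribution to successive weighted draws without
replacement but runs in `O(N log N)`.

`st_by_category()` ranks samples by multifunctionality or multidiversity,
splits them into 19 equal contiguous rank bins (228/19 = 12; any remainder
goes to the last bins, deterministically), computes ST per bin and fits a
second-order polynomial of ST on the bin means. The bin count of 19 divides the
228-sample design evenly and is configurable.

## Moving windows

Samples are sorted by latitude (ties broken by sample id) and contiguous
windows of 30 or 40 samples advance one sample at a time — 199 and 189
windows for 228 samples. Per window we compute the standardized BEF slope
(z-scored within the window, so windows of different variance are
comparable; whether the original slopes were standardized is unstated, and
both raw and standardized slopes are emitted) and the ST of the window's
subtable of the same subcommunity (default rare). Window seeds derive
deterministically from the master seed. The slope–ST trend is a
second-order polynomial by default; degree 1 is available for the
abundant-taxa sensitivity analyses that used linear fits.

## The synthetic world

`generate_dataset()` draws the survey the analysis assumes:

* **Design constants** — 228 fields (114 maize, 114 rice alternating along
  the gradient), latitudes uniform on 18.30–48.35°N and sorted, group
  depths 36,880 / 27,712 / 30,369 / 5,393 reads, 16 functions in the
  9/5/1/1 service layout with the pathogen function inverted.
* **Communities** — per group, a lognormal regional pool (σ_log = 2.2;
  pool sizes 2,000/4,000/2,500/2,000) makes most phylotypes rare: with
  these defaults > 80% of observed phylotypes fall below the 0.05%
  threshold and < 2% above 0.5% in every group, matching the premise that
  rare taxa dominate richness. Each phylotype has a latitude optimum;
  per-sample compositions weight the pool by a Gaussian niche response
  (width 10°) whose strength is `beta_env`; counts are multinomial at the
  group depth. Regional taxa above 0.5% are treated as habitat generalists
  whose filter is damped to 15% strength — abundant soil taxa are
  broad-occupancy generalists, and this keeps abundant richness
  environmentally unstructured (its variance comes from a latitude-free
  Bernoulli occupancy thinning at 0.95 and lognormal overdispersion,
  σ = 0.25). Two implementation subtleties matter here. First, a
  fully-exempt-generalist design fails the stochasticity calibration:
  abundance-weighted Bray–Curtis is dominated by the generalists, so a
  filter they escape entirely is invisible to ST; damping rather than
  exempting restores the monotone response of ST to `beta_env`. Second,
  occupancy dropout must redistribute the dropped mass *within its own
  block* (generalists among generalists, the tail among the tail): letting
  a dropped generalist's percent-level share flow into the rare tail
  couples abundant richness negatively to rare richness — a compositional
  artifact that would make abundant diversity a spurious (inverse)
  predictor of functioning even with `beta_abundant = 0`.
* **Functions** — the latent functioning level is
  `beta_rare * MD_rare + beta_abundant * MD_abund + env_function_effect * STD(latitude)`
  plus N(0, `noise_sd`) per function, where the multidiversity terms are the
  *realized* standardized richness of the generated subcommunities, so
  recovery targets are exact in expectation rather than referencing a
  hidden variable. Defaults `beta_rare = 0.8`, `beta_abundant = 0`,
  `noise_sd = 0.3` encode the headline asymmetry (rare diversity drives
  functioning, abundant does not); `env_function_effect = 0` by default so
  the environment reaches functions only through diversity — the
  deconfounding analyses (SEM, random forest) are out of scope, and a
  direct environmental path would confound the simple OLS recovery checks.
  Functions are mapped affinely onto plausible natural scales (enzyme
  activities, nutrient pools, pathogen/mycorrhizal relative abundances);
  min–max standardization is invariant to this styling.

What a green test does **not** establish: the generator has no phylogenetic
structure, no taxon interactions, no compositional spatial autocorrelation
beyond the latitude filter, and multinomial (not overdispersed-count)
sampling noise at fixed depth; real surveys violate all of these, so the
tests validate the machinery and its calibration, not field conclusions.

## Numerical choices

* Rarefaction is a seeded multivariate-hypergeometric draw (without
  replacement), the standard reading of "resampled to a minimum number".
* Spearman p-values use the asymptotic t approximation (the same as
  `cor.test(..., exact = FALSE)`), vectorized over matrices; ties get
  midranks. Undefined correlations (constant vectors) propagate as NA and
  never count as support or as edges.
* All randomized operations take explicit seeds and run under
  `withr::with_seed`, leaving the global RNG untouched; stage and window
  seeds derive from one master seed by a fixed keyed scheme, so stages are
  independently reproducible and two runs with the same seed are
  byte-identical.
* Equal-size rank bins break ties by original order (stable sort);
  degenerate orderings are flagged rather than fit.

## Known limitations

BIOM output is written in the JSON 1.0 dialect (the HDF5 2.x dialect is
binary; reading both is supported). The support screen's prevalence filter
and the network prevalence filter are declared defaults of this package. The stochasticity ratio is sensitive to the null
algorithm; the implemented scheme is one member of the cited framework's
family and is swappable in code. SEM path modelling, random-forest
importance, sequence processing and figure reproduction are out of scope.
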