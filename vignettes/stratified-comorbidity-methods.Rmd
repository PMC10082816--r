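---
title: "Methods: stratified comorbidity analysis of Alzheimer's dementia EMR cohorts"
author: "adcomorbid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified comorbidity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcomorbid)
```

## Overview

`adcomorbid` implements a deep-phenotyping workflow for Alzheimer's dementia
(AD) comorbidities in OMOP-style electronic medical record (EMR) data,
stratified by identified race and ethnicity (R&E): Asian, Non-Latine Black,
Latine, and Non-Latine White, here labelled Asian/Black/Latine/White. Real
AD EMR cohorts of this kind are not publicly sharable, so the package pairs
every analysis stage with a synthetic OMOP-lite generator whose effect sizes
are known ground truth; every statistical claim the test suite makes is a
claim about recovering those injected effects.

The stages are:

1. **Cohort construction** — AD cases aged 65+ and a candidate-control pool,
   with 1:2 propensity-score (PS) nearest-neighbor matching on sex,
   estimated age, and death status, stratified by R&E, with optional common
   support and size equalization across strata.
2. **Phecode phenotyping** — ICD-9-CM/ICD-10-CM diagnoses joined to a
   phecode map; phecodes without a category are excluded; the result is a
   binary patient × phenotype matrix.
3. **Embedding** — 2-D UMAP of one-hot phenotype profiles (AD phenotype
   excluded), with Mann–Whitney U (2 groups) or Kruskal–Wallis + Dunn
   (&gt;2 groups) comparisons of the two components.
4. **Differential analysis** — per-stratum 2×2 tests per phenotype:
   Fisher's exact when any cell &lt; 5, otherwise Pearson chi-squared
   (no continuity correction); Bonferroni family = phenotypes tested in the
   stratum; odds ratios with Haldane–Anscombe correction; exact-subset
   (UpSet) intersection of the per-stratum significant sets.
5. **Disease networks** — per stratum × AD status, nodes are phenotypes
   carried by strictly more than 5% of the cohort and edges are pairs
   jointly carried by strictly more than 5%; ten node-topology metrics;
   Kruskal–Wallis + Dunn across AD (or control) networks and Mann–Whitney U
   between each AD network and its control; a 25% threshold rebuild for
   visualization (GraphML export).
6. **Two-site validation** — replication of discovery-significant
   phenotypes at a second site, Spearman concordance of log odds ratios,
   and Spearman concordance of standard-normalized network metrics.

## The synthetic cohort model

`sim_config()` / `generate_cohort()` / `generate_diagnoses()` define the
data-generating process:

* Four equal strata; each stratum holds `n_cases_per_stratum` cases and
  `control_pool_multiplier` times as many candidate controls (default 5×,
  so 1:2 matching always has slack; the lower bound of 3 guarantees it).
* Covariates: sex (60% female, reflecting the female predominance of
  AD-age cohorts), integer estimated age truncated to [65, 100] around a
  mean of 80 (SD 7), death status (30% deceased), and a care site drawn
  uniformly from `sites`.
* Case assignment: with `confounding_strength` $\gamma$, patients are
  sampled into the case set with weight
  $\exp\{\gamma(0.08(\mathrm{age}-80) + 0.5\,[\mathrm{female}] +
  0.7\,[\mathrm{deceased}])\}$. At $\gamma = 0$ assignment is uniform and
  the pool is exchangeable with the cases; at the default $\gamma = 1$ the
  pre-match standardized mean differences are ≈ 0.25–0.6, so matching is
  demonstrably non-trivial.
* Phenotypes: each patient acquires each phenotype independently with
  probability $\mathrm{logit}^{-1}(\mathrm{logit}(p_0) +
  [\mathrm{case}]\log\mathrm{OR} + \gamma c(x))$, where $p_0$ is the
  stratum-specific baseline prevalence and $c(x)$ a covariate term with
  half the case-assignment coefficients. Simulating on the logit scale
  makes the injected OR exactly the estimand of the downstream 2×2
  analysis in a matched (covariate-balanced) cohort, and the covariate
  term biases the *unmatched* contrast, which is what the balance tests
  exploit. Default baseline prevalences are uniform on [0.05, 0.4] and
  non-null ORs uniform on [1.5, 4] — the range of effects the field
  reports for AD comorbidities at this scale; `fraction_null` (default
  0.5) of phenotypes get OR = 1.
* Carriers emit 1–3 of the phenotype's ICD codes from the bundled map
  (both ICD-9-CM and ICD-10-CM), deliberately duplicating information so
  that the mapping stage's de-duplication is exercised; AD cases always
  emit one of G30.1/G30.8/G30.9.
* A second ("validation") site reuses the effect table; phenotypes with
  `shared_across_sites = FALSE` revert to OR = 1 there, which is how the
  site-specific-noise analyses are constructed.
* One global integer seed; every stochastic stage derives a child seed
  deterministically (`child_seed()`), so a run is reproducible end to end
  while stages remain independently re-runnable.

What the generator does **not** emulate: visit timelines and coding
intensity, correlated phenotype blocks (phenotypes are independent given
case status, matching the marginal 2×2 tests downstream), mortality
processes, or realistic ICD code frequencies within a phenotype. Passing
tests therefore demonstrate correctness of the statistical machinery and
calibration under the stated model — not robustness to the dependence
structures of real EMR data.

## Matching

PS is a main-effects maximum-likelihood logistic regression (no
interactions, no regularization); categorical covariates are one-hot
expanded against the first level. Matching is greedy nearest-neighbor
without replacement at ratio 1:2: cases are processed in descending PS
order, one round per ratio unit, so every case receives its first control
before any case receives its second — the conventional behavior of the
nearest-neighbor method. Ties in |PS difference| break by (control score,
stable input order), making the procedure deterministic. Common support,
when enabled, trims both groups to
$[\max(\min \mathrm{PS}_g), \min(\max \mathrm{PS}_g)]$ before matching and
records the discard counts; density-based trimming is out of scope.
By default trimming may remove patients from either group; with
`common_support_discard = "control"` only controls are removed, the policy
to use when the full case series must be preserved — note that with any
finite exchangeable pool the single most extreme propensity value belongs
to a case with probability $1/(1+m)$ for a pool of $m$ controls per case,
so two-sided trimming removes an occasional case even from a perfectly
overlapping design, while the control-only policy keeps case counts exact.
Stratum equalization subsamples each stratum's fully matched cases
(seeded) to the minimum complete-match count, so all strata end with equal
case and control counts — the published cohorts report equal strata but
not the mechanism, so seeded subsampling is this package's own choice.

Balance is summarized as standardized mean differences:
$|\bar x_1 - \bar x_2| / \sqrt{(s_1^2 + s_2^2)/2}$ for continuous
covariates and the maximum level-wise SMD over indicator variables for
categoricals; SMD is defined as 0 when both groups have zero variance.
The conventional |SMD| &lt; 0.1 threshold is used throughout.

## Test statistics

All test statistics used by the comparisons are implemented from their
defining formulas and cross-checked in the test suite against independent
references:

* **Fisher's exact (two-sided)**: full enumeration over the feasible range
  of the top-left cell; p is the sum of hypergeometric point
  probabilities not exceeding the observed one, with a 1e-7 relative
  guard against floating-point ties; a zero margin gives p = 1.
* **Chi-squared**: Pearson statistic, 1 df, no Yates correction — the
  &lt; 5 rule already routes small cells to Fisher, and the uncorrected
  statistic matches the reference implementations used in this field.
* **Mann–Whitney U**: midranks, tie-corrected normal approximation with a
  0.5 continuity correction. The cohort sizes here are hundreds, where
  the approximation is accurate to several digits.
* **Kruskal–Wallis**: tie-corrected H against $\chi^2_{k-1}$.
* **Dunn's post hoc**: $z_{ij} = (\bar R_i - \bar R_j)/\sqrt{(N(N+1)/12 -
  \sum(t^3-t)/(12(N-1)))(1/n_i + 1/n_j)}$ with Bonferroni correction over
  the $\binom{k}{2}$ pairs.
* **Spearman**: midrank Pearson correlation, two-sided p from the t
  approximation on n − 2 df; undefined (NA) for constant vectors.

The "&lt; 5 patients in any category" rule is read as: any of the four 2×2
cells below 5 routes the table to Fisher. The Bonferroni family is the set
of phenotypes tested within one stratum (phenotypes with at least one
carrier in the stratum cohort, minus the AD-defining exclusion); the
family size is therefore data-dependent and reported with the results.
The AD phenotype is excluded from testing and from the embedding features
because it would encode case status tautologically; dementia phenotypes
other than AD are retained.

## Network metrics and conventions

Networks are simple, unweighted graphs; prevalences are attributes.
Thresholds are strict inequalities (a phenotype at exactly 5.0% is
excluded). The ten node metrics follow the conventions of the widely used
GUI network-analysis tool this field reports, which leaves several
degenerate cases unstated; the conventions adopted here are:

* path metrics (average shortest-path length, closeness = 1/aspl,
  eccentricity, radiality $= (\Delta + 1 - \mathrm{aspl})/\Delta$ with
  $\Delta$ the component diameter) are computed within each connected
  component;
* isolated nodes: aspl 0, closeness 0, eccentricity 0, radiality 1;
* stress counts, over unordered pairs of *other* nodes in the component,
  every distinct shortest path passing through the node; betweenness is
  the Brandes ratio sum normalized by $(N_c-1)(N_c-2)/2$;
* clustering and topological coefficients are 0 for degree ≤ 1; the
  topological coefficient averages (shared neighbors + adjacency)/degree
  over nodes sharing at least one neighbor.

All ten metrics are verified against a brute-force oracle (independent
BFS plus explicit shortest-path enumeration) on the complete census of
connected graphs with up to 7 vertices and on random graphs up to 40
nodes.

## Cross-site concordance choices

Replication restricts to phenotypes tested (≥ 1 carrier) at both sites.
For network-metric concordance each network must reduce to one value per
metric before z-scoring within site; the reduction is the **median over
nodes** (mean available via `summary_fn`) — the original analyses do not
state their reduction, so this is a documented package choice, selected
for robustness to the skew of path-based metrics. z-scores are computed
per (site, metric) across the 8 networks; a zero-variance metric
contributes zeros rather than NAs so the 80-cell correlation remains
defined.

## Numerical and design notes

* The embedding is consumed from uwot's UMAP implementation, pinned to
  single-threaded SGD with a fixed seed so coordinates are reproducible;
  the package's own contribution is the feature construction and the
  comparison statistics. Hyperparameters (15 neighbors, min_dist 0.1) are
  recorded in the result; they are library defaults, not values recovered
  from the original analyses.
* ICD codes are matched to the phecode map by exact string equality after
  trimming — the published maps enumerate codes explicitly, so no prefix
  rollup is performed. Multiple phecodes per ICD code are all retained.
* An ICD code may support several phenotypes and several codes may support
  one phenotype; assignments collapse to one row per (person, phenotype).
* Row/column orderings are sorted lexicographically wherever a matrix or
  table is serialized, so byte-identical reruns are possible.
* Degenerate inputs are given explicit conventions rather than NAs
  wherever a downstream stage consumes the value (SMD 0 for zero
  variance, p = 1 for zero-margin Fisher tables, radiality 1 for
  single-node components); they are errors where they indicate a broken
  precondition (chi-squared with a zero expected count, overlapping
  case/control ids, assignments referencing unknown patients).

## Problem sizes used by the checks

The test suite and the acceptance script run at the study's stated scale
where the design is about scale — 422 cases / 844 matched controls per
stratum (discovery) and 994 / 1988 (validation analogue), 200 null
replicates at 200 phenotypes for the family-wise error check, and 20
seeds for the two-site analyses — and at reduced sizes (60–120 cases per
stratum, 16–24 phenotypes) for the structural checks where counts, not
power, are under test. The bundled phecode map is a ~60-row synthetic
fixture covering 24 phenotypes plus the AD codes and an intentionally
category-less phecode; analyses against the full published phecode maps
are supported by pointing `load_phecode_map()` at those files with a
column mapping.

## Known limitations

* Phenotype independence in the generator means multiplicity behavior
  under strong phenotype correlation is untested.
* Greedy matching is order-dependent by design; optimal or caliper
  matching is out of scope.
* The Fisher enumeration is exact but O(min(row margin, column margin))
  per table — fine for cohort-scale tables, not meant for margins in the
  millions.
* Exact small-sample Mann–Whitney p-values are not implemented; with
  group sizes below ~20 the normal approximation is rough.
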