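# adcomorbid

Race/ethnicity-stratified deep phenotyping of Alzheimer's dementia (AD)
comorbidities from OMOP-style electronic medical records (EMR).

Large EMR studies of AD comorbidity compare matched case–control cohorts
within racialized strata, but the underlying patient data cannot be shared.
`adcomorbid` implements the complete analysis pipeline as a tested R package
driven by a synthetic OMOP-lite cohort generator with *known* injected
effects, so every stage — matching, phenotyping, testing, networks,
cross-site validation — is verifiable against ground truth without access
to patient data, and can be pointed at real OMOP-lite extracts when those
are available.

## What it computes

For four identified race-and-ethnicity strata (Asian, Black, Latine, White),
each with AD cases aged 65+ and matched controls:

* **Propensity-score matching** — within-stratum logistic propensity scores
  on sex, estimated age, and death status (plus care site for multi-site
  cohorts); greedy 1:2 nearest-neighbor matching without replacement,
  optional common-support trimming, seeded equalization of stratum sizes,
  and standardized-mean-difference (SMD) balance diagnostics.
* **Phecode phenotyping** — exact join of ICD-9-CM/ICD-10-CM codes to a
  phecode map (a ~60-row synthetic map is bundled; the published map files
  load via a column mapping); phecodes without a category are excluded; the
  result is a binary patient × phenotype matrix.
* **Differential comorbidity analysis** — per stratum and phenotype, the
  2×2 case/control table is tested with a two-sided Fisher's exact test if
  any cell < 5 and a Pearson chi-squared test otherwise; odds ratio
  OR = ad/bc with Haldane–Anscombe correction; Bonferroni correction over
  the stratum's tested phenotypes (significant ⇔ corrected p < 0.05); and
  an UpSet-style exact-subset intersection of the per-stratum significant
  sets.
* **Embedding comparisons** — 2-D UMAP of one-hot phenotype profiles (AD
  phenotype excluded), components compared by Mann–Whitney U (2 groups) or
  Kruskal–Wallis with two-sided Dunn post hoc tests (>2 groups).
* **Disease co-occurrence networks** — per stratum × AD status (8
  networks), nodes = phenotypes shared by > 5% of the cohort, edges =
  pairs shared by > 5%; ten node-topology metrics (degree, average
  shortest-path length, closeness, eccentricity, radiality, stress,
  betweenness, clustering coefficient, neighborhood connectivity,
  topological coefficient); metric comparisons across networks and between
  each AD network and its control; > 25% threshold rebuilds exported as
  GraphML for visualization.
* **Two-site validation** — replication of discovery-significant
  phenotypes at a second site, Spearman rank concordance of log odds
  ratios, and Spearman concordance of standard-normalized network metrics
  (8 networks × 10 metrics per site).

All test statistics (Fisher enumeration, chi-squared, Mann–Whitney U,
Kruskal–Wallis, Dunn's z, Spearman) are implemented from their defining
formulas and cross-checked in the test suite against independent oracles,
including an exhaustive sweep of every connected graph on ≤ 7 vertices for
the network metrics.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
discovery cohort of 422 AD cases per stratum with a 5× candidate-control
pool (24 phenotypes, half with injected odds ratios in [1.5, 4]):

```sh
Rscript analysis/01_simulate.R      # generate OMOP-lite cohort + ground truth
Rscript analysis/02_map_and_match.R # phecode mapping + stratified 1:2 matching
Rscript analysis/03_differential.R  # per-stratum case/control testing
Rscript analysis/04_embedding.R     # UMAP + rank-test comparisons
Rscript analysis/05_networks.R      # 8 networks, 10 metrics, comparisons
Rscript analysis/06_cross_site.R    # second-site replication + concordance
```

`02_map_and_match.R` prints the matched-cohort arithmetic and balance:

```
       cases controls
Asian    422      844
Black    422      844
Latine   422      844
White    422      844
Covariate balance (SMD before -> after matching):
      covariate smd_before smd_after
1           sex      0.278    0.0111
2 estimated_age      0.577    0.0659
3  death_status      0.325    0.0554
```

Each stratum keeps all 422 cases matched 1:2 (844 controls, 3376 total),
and matching pulls every covariate SMD from 0.28–0.58 (the injected
confounding) to below the conventional 0.1 balance threshold.

`03_differential.R` then reports, per stratum, how many phenotypes were
tested (the Bonferroni family) and how many are significant, plus the
cross-stratum intersection:

```
Asian: 24 phenotypes tested, 11 significant (Bonferroni < 0.05)
Black: 24 phenotypes tested, 13 significant (Bonferroni < 0.05)
Latine: 24 phenotypes tested, 12 significant (Bonferroni < 0.05)
White: 24 phenotypes tested, 12 significant (Bonferroni < 0.05)
significant comorbidities shared by all four strata: 11
```

and `06_cross_site.R` validates them at a second synthetic site sharing
the same effects:

```
  stratum n_sig_discovery n_replicated replication_fraction
1   Asian              11           11                1.000
2   Black              13           11                0.846
3  Latine              12           12                1.000
4   White              12           12                1.000

Log-OR Spearman concordance (replicated subset):
  stratum  n   rho  p_value
1   Asian 11 0.873 0.000455
2   Black 11 0.682 0.020843
3  Latine 12 0.881 0.000153
4   White 12 0.860 0.000332

Network metric concordance over 8 networks x 10 metrics: rho = 0.789 (p = 3.42e-18)
```

Most discovery-significant comorbidities replicate, their odds ratios are
strongly rank-correlated between sites, and the 80 standard-normalized
network-metric cells agree across sites — the qualitative signature of
effects that are genuinely shared rather than site-specific noise.

The same pipeline runs from files (`run_full(list(input_mode =
"omop_lite_files", input_dir = ...))`) on any person/condition table pair
in the documented OMOP-lite schema.

## Package layout

* `R/` — generator, phecode mapping, matching, statistics, embedding,
  networks, cross-site, pipeline orchestration (`run_full()`).
* `analysis/` — the numbered study drivers shown above.
* `inst/extdata/phecode_map_synthetic.csv` — bundled synthetic phecode map.
* `vignettes/stratified-comorbidity-methods.Rmd` — the model, conventions,
  and design decisions in full.
* `tests/testthat/` — unit, property, and acceptance suites with
  independent brute-force oracles.
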