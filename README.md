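# pdbiome

Gut-microbiome community analysis and nutrient-stratified prediction of
Parkinson's disease (PD) from 16S amplicon sequence variant (ASV) count
tables.

Gastrointestinal dysfunction precedes the motor symptoms of PD by years, and
case-control studies repeatedly find compositional differences between the
gut microbiomes of PD patients and household controls (HC). pdbiome
implements the full analysis such a study needs once reads have been
denoised into an ASV table:

* **Pre-processing** — strict TSV ingest, a prevalence filter (feature
  detected in ≥ `floor(0.10 · n)` samples; 18 of 184 at the default),
  taxonomic rank aggregation with exact conservation of per-sample totals.
* **Community ecology** — Shannon (nats), Gini-Simpson and richness;
  Bray-Curtis, unweighted and weighted UniFrac distance matrices; PCoA;
  permutation PERMANOVA (marginal terms, *p* = (1 + #{F\* ≥ F})/(1 + 9999)),
  with an exact-enumeration mode for small designs.
* **Differential abundance** — Monte-Carlo Dirichlet instances
  (128 draws from Dirichlet(counts + 0.5) per sample), centred log-ratio
  transform in base 2 over all features, per-instance Welch t and
  Benjamini-Hochberg adjustment, expected p over instances, and
  volcano-style flags at −log₁₀ *p* > 3 and |fold change| > 1.2.
* **Association screens** — Spearman correlations (average ranks,
  t-approximation) between covariates and taxa, partial Spearman adjusting
  for age, sex and BMI by rank-residualisation, and the weak/moderate/strong
  bands (|ρ| ∈ [0.2, 0.4), [0.4, 0.6), ≥ 0.6).
* **Prediction** — a single-stage probability random forest
  (500 trees, √p variables per split) with leave-one-out cross-validated
  AUC (Mann-Whitney statistic, ties ½), and the **two-stage model**: a
  decision stump on a macronutrient (maximum information gain in bits,
  refit inside every LOOCV fold) partitions the cohort, a separate forest
  is trained per stratum, and all held-out scores are pooled into one
  ROC/AUC with sensitivity/specificity at the Youden point.
  `survey_macronutrients()` ranks candidate partition nutrients by AUC.
* **Cohort statistics** — pooled-variance t from printed (mean, SD, n)
  pairs and Pearson χ² from printed (percentage, n) pairs, with a Welch
  diagnostic and honest flagging of rows the printed summaries cannot
  reproduce.
* **Synthetic cohort generator** — log-normal baseline abundances,
  Dirichlet-multinomial counts, hierarchical taxonomy, random rooted
  phylogeny, and cohort-matched metadata, with planted group effects and an
  optional carbohydrate-stratified effect (different informative taxa above
  and below 163.07 g/day) so the two-stage model has a provable advantage.

## Worked example

```r
library(pdbiome)

co <- generate_cohort(cohort_config(
  n_group_a = 60, n_group_b = 60, n_asv = 100, n_differential = 6,
  effect_log2 = 0.6, stratum_effect = TRUE, seed = 401))
ft <- filter_by_prevalence(co$counts, 0.10)
X  <- t(relative_abundance(ft))

sv <- survey_macronutrients(X, co$metadata, co$metadata$group,
                            candidates = c("protein_g", "fat_g", "sugar_g",
                                           "fiber_g", "carbohydrate_g"),
                            seed = 1, num_trees = 200)
head(sv[, c("variable", "threshold", "auc")], 3)
#>         variable threshold       auc
#> 6 carbohydrate_g   173.095 0.8644444
#> 2      protein_g    26.910 0.7477778
#> 1 (single-stage)        NA 0.7461111
```

The survey ranks every candidate macronutrient as the stage-one partition
against the single-stage baseline (AUC 0.746): partitioning on
carbohydrate — the variable the stratified effect was planted on, with its
true boundary at 163.07 g/day — lifts the LOOCV-AUC from 0.746 to 0.864,
while partitions on nutrients without planted structure stay at the
baseline.

The numbered drivers under `analysis/` run the whole study in order
(simulate → filter/aggregate → diversity + PERMANOVA → differential
abundance → associations → prediction → cohort statistics), each writing
its tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_aggregate.R
# ... through 07_cohort_stats.R
```

`run_pipeline()` performs the same staging from a single plain-text
`key = value` config file and writes a JSON run manifest (config echo,
seeds, input digests, per-stage outputs).

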